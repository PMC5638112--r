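# Shared statistical engines: row-wise Wilcoxon rank-sum, Benjamini-Hochberg
# FDR, D'Agostino skewness, Fisher's exact test.

#' Row-wise Wilcoxon rank-sum (Mann-Whitney) tests
#'
#' For every row of a matrix, tests the `focal` columns against the
#' `background` columns. P-values are exact (via the null distribution of
#' the Mann-Whitney U statistic) when the combined sample size is at most
#' `exact_max_n` and the row has no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used -- matching the
#' conventions of stats::wilcox.test. Rows with fewer than 2 non-missing
#' observations on either side get NA.
#'
#' @param mat numeric matrix (features x samples).
#' @param focal,background column indices or names.
#' @param alternative "two.sided", "greater" (focal > background) or "less".
#' @param exact_max_n switch to the normal approximation above this combined
#'   sample size (default 25, covering an 8 vs 16 design exactly).
#' @return data.frame(statistic = U, p_value, n_focal, n_background).
#' @export
row_wilcoxon <- function(mat, focal, background,
                         alternative = c("two.sided", "greater", "less"),
                         exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  X <- mat[, focal, drop = FALSE]
  Y <- mat[, background, drop = FALSE]
  nr <- nrow(mat)
  U <- rep(NA_real_, nr)
  p <- rep(NA_real_, nr)
  nx <- rowSums(!is.na(X))
  ny <- rowSums(!is.na(Y))
  usable <- nx >= 2 & ny >= 2
  cb <- cbind(X, Y)
  m <- ncol(X)
  for (i in which(usable)) {
    v <- cb[i, ]
    ok <- !is.na(v)
    r <- rank(v[ok])
    is_x <- seq_along(v)[ok] <= m
    mi <- sum(is_x)
    ni <- sum(!is_x)
    u <- sum(r[is_x]) - mi * (mi + 1) / 2
    U[i] <- u
    has_ties <- anyDuplicated(v[ok]) > 0
    if (!has_ties && (mi + ni) <= exact_max_n) {
      p[i] <- switch(alternative,
        greater = stats::pwilcox(u - 1, mi, ni, lower.tail = FALSE),
        less = stats::pwilcox(u, mi, ni),
        two.sided = {
          if (u > mi * ni / 2)
            min(1, 2 * stats::pwilcox(u - 1, mi, ni, lower.tail = FALSE))
          else if (u < mi * ni / 2)
            min(1, 2 * stats::pwilcox(u, mi, ni))
          else 1
        })
    } else {
      tie_len <- rle(sort(r))$lengths
      tie_term <- sum(tie_len^3 - tie_len)
      mu <- mi * ni / 2
      sigma2 <- mi * ni / 12 *
        ((mi + ni + 1) - tie_term / ((mi + ni) * (mi + ni - 1)))
      if (sigma2 <= 0) { p[i] <- 1; next }
      z <- u - mu
      cc <- switch(alternative, two.sided = sign(z) * 0.5,
                   greater = 0.5, less = -0.5)
      z <- (z - cc) / sqrt(sigma2)
      p[i] <- switch(alternative,
        two.sided = min(1, 2 * stats::pnorm(-abs(z))),
        greater = stats::pnorm(z, lower.tail = FALSE),
        less = stats::pnorm(z))
    }
  }
  data.frame(statistic = U, p_value = p, n_focal = nx, n_background = ny)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_i = min over j >= rank(i) of p_(j) * m / j,
#' capped at 1 and order-preserving. NAs are passed through and do not count
#' toward m.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' D'Agostino test of skewness
#'
#' Sample skewness g1 = m3 / m2^(3/2) with the D'Agostino (1970)
#' transformation to an approximately standard normal deviate, and a
#' two-sided p-value. Requires n >= 8 for the transformation to be valid.
#'
#' @param values numeric vector, n >= 8.
#' @return list(skew, z, p) of class `skewness_result`.
#' @export
skewness_test <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 8)
    stop("input error: skewness test requires n >= 8 observations",
         call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * asinh(y / alpha)
  out <- list(skew = g1, z = z, p = 2 * stats::pnorm(-abs(z)))
  class(out) <- "skewness_result"
  out
}

#' @export
print.skewness_result <- function(x, ...) {
  cat(sprintf("skewness test: skew = %.4f; z = %.4f; p = %.4g\n",
              x$skew, x$z, x$p))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Exact hypergeometric enumeration at fixed margins: the p-value is the sum
#' of the probabilities of all tables no more probable than the observed one.
#' A table with a zero margin admits only one configuration, so p = 1.
#'
#' @param table 2x2 integer matrix (or something coercible).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == c(2, 2)), all(tb >= 0))
  a <- tb[1, 1]
  r1 <- sum(tb[1, ])
  r2 <- sum(tb[2, ])
  c1 <- sum(tb[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tb[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  d <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(d[d <= p_obs * (1 + 1e-12)])
}

row_ids <- function(mat) {
  if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat)
}
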