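#' Group design for a two-group contrast
#'
#' @param samples data.frame(sample_id, group, ...).
#' @param focal focal group label (e.g. "admixed").
#' @param background one or more background group labels (combined).
#' @return list of class `group_design` with the focal/background sample ids.
#' @export
group_design <- function(samples, focal, background) {
  stopifnot(all(c(focal, background) %in% samples$group))
  if (length(intersect(focal, background)) > 0)
    stop("focal and background groups must be disjoint", call. = FALSE)
  out <- list(
    focal = samples$sample_id[samples$group %in% focal],
    background = samples$sample_id[samples$group %in% background],
    focal_label = paste(focal, collapse = "+"),
    background_label = paste(background, collapse = "+")
  )
  class(out) <- "group_design"
  out
}

#' Per-probe rank-sum tests between groups of a normalized matrix
#'
#' Runs a Wilcoxon rank-sum test per probe (focal vs combined background),
#' adjusts p-values across all tested probes with Benjamini-Hochberg, and
#' labels the direction of significant probes from the sign of the group
#' mean difference. Probes with fewer than two observations on either side
#' are excluded from testing (and from the BH family) but kept in the table
#' with NA results.
#'
#' @param mat probes x samples matrix (e.g. [normalize_arrays()] output).
#' @param design a [group_design()].
#' @param tails "two", "one_greater" (focal > background) or "one_less".
#' @param alpha significance level on the adjusted values (default 0.05).
#' @return data.frame of class `cnv_call_table`: probe_id, statistic, p, q,
#'   mean_diff, direction.
#' @export
test_group_difference <- function(mat, design,
                                  tails = c("two", "one_greater", "one_less"),
                                  alpha = 0.05) {
  tails <- match.arg(tails)
  alt <- c(two = "two.sided", one_greater = "greater", one_less = "less")[tails]
  fi <- match(design$focal, colnames(mat))
  bi <- match(design$background, colnames(mat))
  if (anyNA(fi) || anyNA(bi))
    stop("design samples absent from matrix columns", call. = FALSE)
  res <- row_wilcoxon(mat, fi, bi, alternative = alt)
  q <- bh_fdr(res$p_value)
  mean_diff <- rowMeans(mat[, fi, drop = FALSE], na.rm = TRUE) -
    rowMeans(mat[, bi, drop = FALSE], na.rm = TRUE)
  direction <- rep("none", nrow(mat))
  sig <- !is.na(q) & q < alpha
  direction[sig & mean_diff > 0] <- "increase"
  direction[sig & mean_diff < 0] <- "decrease"
  out <- data.frame(
    probe_id = row_ids(mat), statistic = res$statistic, p = res$p_value,
    q = q, mean_diff = mean_diff, direction = direction,
    n_focal = res$n_focal, n_background = res$n_background,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "n_excluded") <- sum(is.na(res$p_value))
  class(out) <- c("cnv_call_table", "data.frame")
  out
}

#' @export
print.cnv_call_table <- function(x, ...) {
  alpha <- attr(x, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  cat("CNV call table:", nrow(x), "probes;",
      sum(x$direction == "increase"), "increased and",
      sum(x$direction == "decrease"), "decreased at q <", alpha, "\n")
  n_excl <- attr(x, "n_excluded")
  if (!is.null(n_excl) && n_excl > 0)
    cat("  (", n_excl, "probes excluded: too few observations )\n")
  invisible(x)
}

#' Per-individual log2-ratio threshold calls
#'
#' A gene is a putative duplication at threshold t when ANY individual's
#' normalized log2 ratio exceeds t (strict inequality), a putative deletion
#' when any individual falls below -t; a gene can be both.
#'
#' @param mat probes x samples matrix of normalized log2 ratios; pass only
#'   the columns whose individuals should drive the calls.
#' @param thresholds positive log2 cutoffs (default c(0.5, 0.4)).
#' @return data.frame(probe_id, threshold, n_dup_individuals,
#'   n_del_individuals, class) with class in dup/del/both/none.
#' @export
call_thresholds <- function(mat, thresholds = c(0.5, 0.4)) {
  stopifnot(all(thresholds > 0))
  out <- lapply(thresholds, function(t) {
    ndup <- rowSums(mat > t, na.rm = TRUE)
    ndel <- rowSums(mat < -t, na.rm = TRUE)
    cls <- ifelse(ndup > 0 & ndel > 0, "both",
                  ifelse(ndup > 0, "dup", ifelse(ndel > 0, "del", "none")))
    data.frame(probe_id = row_ids(mat), threshold = t,
               n_dup_individuals = ndup, n_del_individuals = ndel,
               class = cls, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Number of distinct copy-number-variable genes
#'
#' Size of the union of the duplication and deletion sets.
#'
#' @param dup_set,del_set character vectors of gene/probe ids.
#' @return integer count.
#' @export
count_variable_genes <- function(dup_set, del_set) {
  length(union(dup_set, del_set))
}

#' Per-probe group mean differences (skewness input)
#'
#' The default input vector of the skewness analysis: for each probe, the
#' mean normalized log2 ratio of the focal group minus that of the
#' background group.
#'
#' @param mat probes x samples matrix.
#' @param design a [group_design()].
#' @return numeric vector, one value per probe.
#' @export
group_mean_difference <- function(mat, design) {
  fi <- match(design$focal, colnames(mat))
  bi <- match(design$background, colnames(mat))
  rowMeans(mat[, fi, drop = FALSE], na.rm = TRUE) -
    rowMeans(mat[, bi, drop = FALSE], na.rm = TRUE)
}

#' Per-probe one-sided variance comparison between two groups
#'
#' Tests var(group A) > var(group B) per probe, BH-adjusts across probes and
#' counts significant probes. Engines: `"f"` (default), the one-sided F-test
#' of the variance ratio; `"levene"`, a one-sided Welch t-test on absolute
#' deviations from the group median (robust to non-normality). A probe with
#' zero variance in both groups is a ratio of 1 by convention.
#'
#' @param mat probes x samples matrix.
#' @param groupA,groupB sample id vectors (ordered contrast: A's variance
#'   tested as the larger).
#' @param engine "f" or "levene".
#' @param alpha significance level on adjusted values.
#' @return data.frame(probe_id, statistic, p, q, significant) with the count
#'   in attribute `n_significant`.
#' @export
variance_comparison <- function(mat, groupA, groupB,
                                engine = c("f", "levene"), alpha = 0.05) {
  engine <- match.arg(engine)
  ai <- match(groupA, colnames(mat))
  bi <- match(groupB, colnames(mat))
  A <- mat[, ai, drop = FALSE]
  B <- mat[, bi, drop = FALSE]
  nA <- rowSums(!is.na(A))
  nB <- rowSums(!is.na(B))
  if (engine == "f") {
    vA <- apply(A, 1, stats::var, na.rm = TRUE)
    vB <- apply(B, 1, stats::var, na.rm = TRUE)
    stat <- ifelse(vA == 0 & vB == 0, 1, vA / vB)
    p <- stats::pf(stat, nA - 1, nB - 1, lower.tail = FALSE)
  } else {
    devA <- abs(A - apply(A, 1, stats::median, na.rm = TRUE))
    devB <- abs(B - apply(B, 1, stats::median, na.rm = TRUE))
    mA <- rowMeans(devA, na.rm = TRUE)
    mB <- rowMeans(devB, na.rm = TRUE)
    sA <- apply(devA, 1, stats::var, na.rm = TRUE) / nA
    sB <- apply(devB, 1, stats::var, na.rm = TRUE) / nB
    se <- sqrt(sA + sB)
    stat <- ifelse(se > 0, (mA - mB) / se, 0)
    df <- (sA + sB)^2 / (sA^2 / (nA - 1) + sB^2 / (nB - 1))
    df[!is.finite(df)] <- nA + nB - 2
    p <- stats::pt(stat, df, lower.tail = FALSE)
    p[se == 0] <- 0.5
  }
  q <- bh_fdr(p)
  out <- data.frame(probe_id = row_ids(mat), statistic = stat, p = p, q = q,
                    significant = !is.na(q) & q < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_significant") <- sum(out$significant)
  out
}
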