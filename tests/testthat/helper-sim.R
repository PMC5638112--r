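# Shared fixtures: all synthetic, generated in code at test time.

small_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed, n_genes = 120,
    group_sizes = c(parentA = 4L, parentB = 4L, admixed = 4L),
    n_elements = 60
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# Clean response config: no defects, no noise, no artifacts -- exact
# arithmetic end to end.
noiseless_config <- function(seed = 1, ...) {
  small_config(seed = seed, noise_sd = 0, fraction_nonlinear = 0,
               fraction_unresponsive = 0, dye_bias_coefficients = 0,
               n_bubble_arrays = 0L, locus_representation_sdlog = 0, ...)
}

# Independent point-in-polygon oracle: winding number (the implementation
# uses ray casting).
winding_number_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(k) {
    wn <- 0
    x <- px[k]; y <- py[k]
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      cross <- (vx[j] - vx[i]) * (y - vy[i]) - (vy[j] - vy[i]) * (x - vx[i])
      on_seg <- abs(cross) < 1e-9 &&
        x >= min(vx[i], vx[j]) - 1e-9 && x <= max(vx[i], vx[j]) + 1e-9 &&
        y >= min(vy[i], vy[j]) - 1e-9 && y <= max(vy[i], vy[j]) + 1e-9
      if (on_seg) return(TRUE)
      if (vy[i] <= y) {
        if (vy[j] > y && cross > 0) wn <- wn + 1
      } else {
        if (vy[j] <= y && cross < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# Exact null distribution of the Mann-Whitney U statistic by full
# enumeration of which ranks the focal group occupies.
enumerate_u_distribution <- function(m, n) {
  N <- m + n
  combos <- utils::combn(N, m)
  u <- colSums(combos) - m * (m + 1) / 2
  table(factor(u, levels = 0:(m * n))) / ncol(combos)
}

enum_wilcox_p <- function(x, y, alternative) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  d <- enumerate_u_distribution(m, n)
  uu <- as.numeric(names(d))
  switch(alternative,
    greater = sum(d[uu >= u]),
    less = sum(d[uu <= u]),
    two.sided = {
      if (u > m * n / 2) min(1, 2 * sum(d[uu >= u]))
      else if (u < m * n / 2) min(1, 2 * sum(d[uu <= u]))
      else 1
    })
}

# Direct BH step-up transcription, independent of p.adjust.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher p by direct enumeration with choose() arithmetic.
fisher_enum_p <- function(tb) {
  a <- tb[1, 1]; r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tb[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, support) * choose(r2, c1 - support) / choose(r1 + r2, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(r1 + r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}
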