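#' Poisson-corrected template concentration from droplet counts
#'
#' With droplets of volume V and a positive fraction f, the mean template
#' load per droplet is lambda = -ln(1 - f) and the concentration lambda / V.
#'
#' @param n_pos positive droplets (0 <= n_pos < n_total).
#' @param n_total total accepted droplets (> 0).
#' @param volume droplet volume (nL).
#' @return concentration in copies per nL.
#' @export
poisson_concentration <- function(n_pos, n_total, volume) {
  if (any(n_total <= 0)) stop("input error: n_total must be > 0", call. = FALSE)
  if (any(n_pos < 0) || any(n_pos > n_total))
    stop("input error: need 0 <= n_pos <= n_total", call. = FALSE)
  if (any(n_pos == n_total))
    stop("saturation error: all droplets positive; concentration undefined",
         call. = FALSE)
  if (any(volume <= 0)) stop("input error: volume must be > 0", call. = FALSE)
  -log(1 - n_pos / n_total) / volume
}

#' Copy number from target and reference concentrations
#'
#' cn = reference_copies * target_conc / ref_conc; the droplet volume cancels
#' in the ratio.
#'
#' @param target_conc,ref_conc concentrations (same units).
#' @param reference_copies copies of the reference locus per genome
#'   (default 2, a single-copy gene in a diploid).
#' @return estimated copies per diploid genome.
#' @export
copy_number <- function(target_conc, ref_conc, reference_copies = 2) {
  if (any(ref_conc == 0))
    stop("estimation error: reference concentration is 0", call. = FALSE)
  reference_copies * target_conc / ref_conc
}

#' Copy-number estimates for a table of ddPCR reactions
#'
#' @param reactions data.frame(sample_id, assay_id, droplets_total,
#'   pos_target, pos_reference, droplet_volume).
#' @param reference_copies copies of the reference locus (default 2).
#' @return data.frame with target/reference concentrations (copies/nL) and
#'   the copy-number estimate `cn` per reaction.
#' @export
estimate_copy_numbers <- function(reactions, reference_copies = 2) {
  tc <- poisson_concentration(reactions$pos_target, reactions$droplets_total,
                              reactions$droplet_volume)
  rc <- poisson_concentration(reactions$pos_reference,
                              reactions$droplets_total,
                              reactions$droplet_volume)
  data.frame(
    sample_id = reactions$sample_id, assay_id = reactions$assay_id,
    target_conc = tc, ref_conc = rc,
    cn = copy_number(tc, rc, reference_copies),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' One-way ANOVA with Tukey HSD over copy-number estimates
#'
#' @param estimates data.frame with a `cn` column.
#' @param group factor/vector of group labels per row.
#' @param alpha significance level for flagging pairs.
#' @return list(anova_f, anova_p, tukey = pairwise table with adjusted p and
#'   significance flags).
#' @export
group_comparison <- function(estimates, group, alpha = 0.05) {
  d <- data.frame(cn = estimates$cn, group = factor(group))
  fit <- stats::aov(cn ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(
    pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(anova_f = an["group", "F value"], anova_p = an["group", "Pr(>F)"],
       tukey = tukey)
}

#' Screen F2 individuals for de novo copy-number changes
#'
#' Flags an F2 individual when its estimated copy number falls outside the
#' parental range widened by `margin` copies on each side -- an
#' operationalization of "outside anything seen in the parents" for
#' integer-like copy-number assays.
#'
#' @param f2_estimates data.frame(sample_id, assay_id, cn[, family]).
#' @param parental_estimates data.frame(assay_id, cn) over parental
#'   individuals.
#' @param margin copies added to each end of the parental range (default 1).
#' @return data.frame per F2 reaction with the parental range and the
#'   de novo flag; attribute `by_family` summarizes flag counts per family
#'   when a `family` column is present.
#' @export
de_novo_screen <- function(f2_estimates, parental_estimates, margin = 1) {
  if (nrow(f2_estimates) == 0L) {
    out <- cbind(f2_estimates,
                 data.frame(parental_min = numeric(0),
                            parental_max = numeric(0),
                            de_novo = logical(0)))
    attr(out, "by_family") <- data.frame()
    return(out)
  }
  rng <- tapply(parental_estimates$cn, parental_estimates$assay_id, range)
  lo <- vapply(rng, `[`, numeric(1), 1)[f2_estimates$assay_id]
  hi <- vapply(rng, `[`, numeric(1), 2)[f2_estimates$assay_id]
  if (anyNA(lo))
    stop("assay without parental estimates: ",
         paste(unique(f2_estimates$assay_id[is.na(lo)]), collapse = ", "),
         call. = FALSE)
  out <- f2_estimates
  out$parental_min <- unname(lo)
  out$parental_max <- unname(hi)
  out$de_novo <- out$cn < lo - margin | out$cn > hi + margin
  if (!is.null(out$family)) {
    agg <- stats::aggregate(de_novo ~ family, data = out, FUN = sum)
    names(agg)[2] <- "n_flagged"
    attr(out, "by_family") <- agg
  }
  out
}
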