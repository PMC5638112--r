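#' Sample metadata for a simulated cohort
#'
#' @param config a [sim_config()]; `group_sizes` defines the cohort.
#' @param group_sizes optional named counts overriding the config (e.g. the
#'   13/7/10 sequencing design instead of the 8/8/8 array design).
#' @return data.frame(sample_id, group, sex, population).
#' @export
simulate_samples <- function(config, group_sizes = NULL) {
  validate_sim_config(config)
  gs <- if (is.null(group_sizes)) config$group_sizes else group_sizes
  if (is.null(names(gs)) ||
      !all(names(gs) %in% c("parentA", "parentB", "admixed", "F2")))
    stop("metadata error: sample group must be one of parentA, parentB, admixed, F2",
         call. = FALSE)
  grp <- rep(names(gs), times = gs)
  n <- length(grp)
  pops <- c(parentA = "brook_A", parentB = "brook_B",
            admixed = "river_main", F2 = "lab_cross")
  data.frame(
    sample_id = sprintf("%s_%02d", grp, unlist(lapply(gs, seq_len))),
    group = grp,
    sex = rep_len(c("m", "f"), n),
    population = pops[grp],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' True gene copy-number structure of the three-group design
#'
#' Draws the ground-truth copy-number table: both parental species start at
#' the diploid state (CN 2); a configurable fraction of genes diverges
#' between the parents (parent B gains or loses one copy with equal
#' probability). Admixed individuals are ancestry mosaics: each individual
#' inherits each gene's state from parent B with probability
#' `ancestry_bias`, independently across individuals and genes (drawn at
#' array-simulation time); `cn_admixed` records the expected admixed copy
#' number. The `cn_effects` sets are lineage-fixed admixed-specific states
#' shared by every admixed individual (drawn from the non-divergent genes so
#' the injected effects are unambiguous).
#'
#' @param config a [sim_config()].
#' @return data.frame of class `gene_truth` with per-gene true copy numbers
#'   per group (`cn_admixed` = expected value for mosaic genes, the fixed
#'   state for de novo genes), the divergence flag and the de novo label.
#' @export
simulate_gene_truth <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "gene_truth", {
    n <- config$n_genes
    cn_A <- rep(2, n)
    cn_B <- rep(2, n)
    divergent <- stats::runif(n) < config$divergence_fraction
    cn_B[divergent] <- 2 + sample(c(-1, 1), sum(divergent), replace = TRUE)
    cn_adm <- config$ancestry_bias * cn_B + (1 - config$ancestry_bias) * cn_A
    de_novo <- rep("none", n)
    pool <- which(!divergent)
    for (eff in config$cn_effects) {
      if (eff$n < 1L) next
      pick <- pool[seq_len(eff$n)]
      pool <- setdiff(pool, pick)
      cn_adm[pick] <- eff$cn
      de_novo[pick] <- if (eff$cn > 2) "increase" else "decrease"
    }
    out <- data.frame(
      gene_id = gene_ids(n),
      cn_parentA = cn_A, cn_parentB = cn_B, cn_admixed = cn_adm,
      divergent = divergent, de_novo = de_novo,
      stringsAsFactors = FALSE
    )
    class(out) <- c("gene_truth", "data.frame")
    out
  })
}

draw_probe_params <- function(n, config) {
  sd_ <- config$slope_distribution
  id_ <- config$intercept_distribution
  draw_slope <- function() stats::rlnorm(n, sd_$meanlog, sd_$sdlog)
  draw_icpt <- function() pmax(1, stats::rnorm(n, id_$mean, id_$sd))
  list(slope_green = draw_slope(), intercept_green = draw_icpt(),
       slope_red = draw_slope(), intercept_red = draw_icpt())
}

grid_dims <- function(config, n_spots) {
  rows <- config$array_rows
  cols <- config$array_cols
  if (rows * cols < n_spots) rows <- ceiling(n_spots / cols)
  c(rows = rows, cols = cols)
}

# Random distinct grid positions for n_spots features on one array.
draw_positions <- function(dims, n_spots) {
  idx <- sample.int(dims[["rows"]] * dims[["cols"]], n_spots)
  list(row = ((idx - 1L) %% dims[["rows"]]) + 1L,
       col = ((idx - 1L) %/% dims[["rows"]]) + 1L)
}

# Saturating response used for probes labelled nonlinear: initial slope equals
# the probe's linear slope, but the signal plateaus (half-saturation 150 ng),
# which drives the OLS coefficient of determination well below 0.95.
saturating_dna <- function(dna, k = 150) k * dna / (k + dna)

#' Simulate the calibration dilution-series arrays
#'
#' One array per dilution level; both channels carry the same DNA amount
#' (each channel is one parental individual's dilution series). Per probe and
#' channel the expected signal is intercept + slope * DNA for responsive
#' probes, a saturating curve for probes labelled nonlinear, and flat
#' background for unresponsive probes; additive Gaussian noise (sd
#' `noise_sd`) is clamped at zero.
#'
#' @param config a [sim_config()].
#' @return list(features = feature table, truth = list(probe_params)).
#'   `probe_params` records each probe's true slope/intercept per channel and
#'   its defect label (`none`, `nonlinear`, `unresponsive`).
#' @export
simulate_calibration_arrays <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "calibration_arrays", {
    n_probes <- config$n_genes * config$n_probes_per_gene
    gid <- rep(gene_ids(config$n_genes), each = config$n_probes_per_gene)
    pid <- paste0(gid, "_p", rep(seq_len(config$n_probes_per_gene),
                                 times = config$n_genes))
    pars <- draw_probe_params(n_probes, config)
    n_bad_nl <- round(config$fraction_nonlinear * n_probes)
    n_bad_ur <- round(config$fraction_unresponsive * n_probes)
    defect <- rep("none", n_probes)
    bad <- sample.int(n_probes, n_bad_nl + n_bad_ur)
    defect[bad[seq_len(n_bad_nl)]] <- "nonlinear"
    if (n_bad_ur > 0) defect[bad[n_bad_nl + seq_len(n_bad_ur)]] <- "unresponsive"

    reps <- config$n_replicates_calibration
    dims <- grid_dims(config, n_probes * reps)
    levels <- config$dilution_levels_ng
    tabs <- vector("list", length(levels))
    for (li in seq_along(levels)) {
      dna <- levels[li]
      eff_dna <- rep(dna, n_probes)
      eff_dna[defect == "nonlinear"] <- saturating_dna(dna)
      eff_dna[defect == "unresponsive"] <- 0
      mu_g <- pars$intercept_green + pars$slope_green * eff_dna
      mu_r <- pars$intercept_red + pars$slope_red * eff_dna
      pos <- draw_positions(dims, n_probes * reps)
      nf <- n_probes * reps
      sig_g <- rep(mu_g, reps)
      sig_r <- rep(mu_r, reps)
      if (config$noise_sd > 0) {
        sig_g <- pmax(0, sig_g + stats::rnorm(nf, 0, config$noise_sd))
        sig_r <- pmax(0, sig_r + stats::rnorm(nf, 0, config$noise_sd))
      }
      tabs[[li]] <- data.table::data.table(
        array_id = sprintf("cal_L%02d", li),
        probe_id = rep(pid, reps),
        replicate = rep(seq_len(reps), each = n_probes),
        row = pos$row, col = pos$col,
        signal_green = sig_g, signal_red = sig_r,
        masked = FALSE
      )
    }
    features <- data.table::rbindlist(tabs)
    truth <- list(probe_params = data.frame(
      probe_id = pid, gene_id = gid,
      slope_green = pars$slope_green, intercept_green = pars$intercept_green,
      slope_red = pars$slope_red, intercept_red = pars$intercept_red,
      defect = defect, stringsAsFactors = FALSE
    ))
    list(features = features, truth = truth)
  })
}

# Default bubble artifact: an octagon centred on the array covering roughly
# 30% of its area, placed on the first n_bubble_arrays arrays (so that with
# the 24-array design about 11% of all features fall inside a bubble).
make_bubble_polygons <- function(config, array_ids, dims) {
  ids <- utils::head(array_ids, config$n_bubble_arrays)
  if (length(ids) == 0L) {
    return(data.frame(array_id = character(), vertex_index = integer(),
                      row = numeric(), col = numeric(),
                      stringsAsFactors = FALSE))
  }
  r <- sqrt(0.30 * dims[["rows"]] * dims[["cols"]] / (2 * sqrt(2)))
  ang <- (seq_len(8) - 0.5) * pi / 4
  vr <- dims[["rows"]] / 2 + r * sin(ang)
  vc <- dims[["cols"]] / 2 + r * cos(ang)
  do.call(rbind, lapply(ids, function(a) {
    data.frame(array_id = a, vertex_index = seq_len(8), row = vr, col = vc,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate the experimental common-reference arrays
#'
#' One array per test sample; the test sample is in the red (Cy5) channel and
#' a shared diploid reference in the green (Cy3) channel. The expected test
#' signal of a probe is intercept + slope * (starting DNA * CN/2); an
#' intensity-dependent log2-ratio bias (polynomial in the average log2
#' expected intensity) is injected symmetrically into the two channels so
#' LOESS normalization has real work to do; features falling inside bubble
#' polygons are attenuated multiplicatively; additive Gaussian noise is then
#' applied per channel and clamped at zero.
#'
#' @param config a [sim_config()].
#' @param samples data.frame from [simulate_samples()].
#' @param truth a `gene_truth` table from [simulate_gene_truth()].
#' @param probe_params one row per printed probe (subset of the calibration
#'   truth `probe_params`, e.g. the selected probe per gene); when NULL a
#'   fresh set of one probe per gene is drawn.
#' @return feature table (one row per feature) with attributes
#'   `bubble_polygons` (the polygon table used) and `feature_truth`
#'   (per-feature in-bubble flag and noiseless expected log2 ratio).
#' @export
simulate_experiment_arrays <- function(config, samples, truth,
                                       probe_params = NULL) {
  validate_sim_config(config)
  if (!all(samples$group %in% c("parentA", "parentB", "admixed", "F2")))
    stop("metadata error: sample group must be one of parentA, parentB, admixed, F2",
         call. = FALSE)
  with_substream(config$seed, "experiment_arrays", {
    if (is.null(probe_params)) {
      pp <- draw_probe_params(config$n_genes, config)
      probe_params <- data.frame(
        probe_id = paste0(gene_ids(config$n_genes), "_p1"),
        gene_id = gene_ids(config$n_genes),
        slope_green = pp$slope_green, intercept_green = pp$intercept_green,
        slope_red = pp$slope_red, intercept_red = pp$intercept_red,
        stringsAsFactors = FALSE
      )
    }
    gi <- match(probe_params$gene_id, truth$gene_id)
    if (anyNA(gi)) stop("probe_params reference genes absent from truth", call. = FALSE)
    n_probes <- nrow(probe_params)
    # per-locus representation multiplier: scales the effective DNA of both
    # channels equally, spreading A without touching M
    locus_eff <- stats::rlnorm(n_probes, 0, config$locus_representation_sdlog)
    reps <- config$n_replicates_experiment
    dims <- grid_dims(config, n_probes * reps)
    polys <- config$bubble_polygons
    if (is.null(polys)) polys <- make_bubble_polygons(config, samples$sample_id, dims)

    cn_A <- truth$cn_parentA[gi]
    cn_B <- truth$cn_parentB[gi]
    is_dn <- truth$de_novo[gi] != "none"
    tabs <- vector("list", nrow(samples))
    for (si in seq_len(nrow(samples))) {
      grp <- samples$group[si]
      cn <- switch(grp,
        parentA = cn_A,
        parentB = cn_B,
        # each admixed individual is its own ancestry mosaic; de novo
        # effects are lineage-fixed and shared by all admixed individuals
        admixed = ifelse(is_dn, truth$cn_admixed[gi],
                         ifelse(stats::runif(n_probes) < config$ancestry_bias,
                                cn_B, cn_A)),
        F2 = ifelse(stats::runif(n_probes) < 0.5, cn_A, cn_B))
      mu_r <- probe_params$intercept_red +
        probe_params$slope_red *
          (config$starting_dna_ng * locus_eff * cn / 2)
      mu_g <- probe_params$intercept_green +
        probe_params$slope_green *
          (config$starting_dna_ng * locus_eff * config$reference_cn / 2)
      a0 <- 0.5 * (log2(mu_r) + log2(mu_g))
      bias <- outer(a0, seq_along(config$dye_bias_coefficients) - 1, `^`) %*%
        config$dye_bias_coefficients
      bias <- as.numeric(bias)
      mu_r <- mu_r * 2^(bias / 2)
      mu_g <- mu_g * 2^(-bias / 2)

      pos <- draw_positions(dims, n_probes * reps)
      nf <- n_probes * reps
      sig_r <- rep(mu_r, reps)
      sig_g <- rep(mu_g, reps)
      aid <- samples$sample_id[si]
      in_bub <- rep(FALSE, nf)
      ap <- polys[polys$array_id == aid, , drop = FALSE]
      if (nrow(ap) > 0) {
        in_bub <- points_in_polygon(pos$row, pos$col,
                                    ap$row[order(ap$vertex_index)],
                                    ap$col[order(ap$vertex_index)])
        sig_r[in_bub] <- sig_r[in_bub] * config$bubble_attenuation
        sig_g[in_bub] <- sig_g[in_bub] * config$bubble_attenuation
      }
      if (config$noise_sd > 0) {
        sig_r <- pmax(0, sig_r + stats::rnorm(nf, 0, config$noise_sd))
        sig_g <- pmax(0, sig_g + stats::rnorm(nf, 0, config$noise_sd))
      }
      tabs[[si]] <- data.table::data.table(
        array_id = aid,
        probe_id = rep(probe_params$probe_id, reps),
        replicate = rep(seq_len(reps), each = n_probes),
        row = pos$row, col = pos$col,
        signal_green = sig_g, signal_red = sig_r,
        masked = FALSE, in_bubble = in_bub
      )
    }
    features <- data.table::rbindlist(tabs)
    truth_feat <- data.frame(in_bubble = features$in_bubble)
    features[, "in_bubble" := NULL]
    data.table::setattr(features, "bubble_polygons", polys)
    data.table::setattr(features, "feature_truth", truth_feat)
    features[]
  })
}

element_ids <- function(n) sprintf("te%04d", seq_len(n))

# Repeat-library annotation emulating the composition of a de novo assembly
# classified with a Wicker-style hierarchy: roughly 31% Class I
# (retrotransposons), 12% Class II (DNA transposons), 2% host genes and 55%
# unclassified.
draw_element_annotation <- function(n) {
  class_p <- c(I = 312, II = 119, host_gene = 21, unclassified = 553) / 1005
  te_class <- sample(names(class_p), n, replace = TRUE, prob = class_p)
  orders_I <- c(LTR = 60, DIRS = 10, PLE = 15, LARD = 5, TRIM = 20,
                LINE = 170, SINE = 32)
  orders_II <- c(TIR = 90, MITE = 15, Crypton = 8, Helitron = 6)
  te_order <- rep("undetermined", n)
  iI <- te_class == "I"
  te_order[iI] <- sample(names(orders_I), sum(iI), TRUE, prob = orders_I)
  iII <- te_class == "II"
  te_order[iII] <- sample(names(orders_II), sum(iII), TRUE, prob = orders_II)
  data.frame(
    element_id = element_ids(n), te_class = te_class, te_order = te_order,
    length = round(stats::runif(n, 500, 8000)),
    complete = te_class %in% c("I", "II") & stats::runif(n) < 0.15,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-individual mapped-read counts over a repeat library
#'
#' Element baseline abundances (CPM) are lognormal across the library; a
#' configurable fraction of elements is increased in the admixed group by a
#' configurable mean relative effect (per-element effects uniform within
#' +/-50% of the mean effect); a further small fraction is decreased; among
#' the increased elements a configurable majority is more abundant in parent
#' B than parent A (the ancestry-biased amplification pattern). Counts are
#' negative binomial with mean CPM * depth / 1e6 and the configured
#' dispersion; dispersion 0 gives Poisson counts.
#'
#' @param config a [sim_config()].
#' @param samples data.frame of samples (groups among parentA, parentB,
#'   admixed).
#' @return list(counts = count_matrix object, truth = element truth table).
#' @export
simulate_repeat_counts <- function(config, samples) {
  validate_sim_config(config)
  if (!all(samples$group %in% c("parentA", "parentB", "admixed")))
    stop("metadata error: repeat-count samples must be parentA, parentB or admixed",
         call. = FALSE)
  with_substream(config$seed, "repeat_counts", {
    n <- config$n_elements
    ann <- draw_element_annotation(n)
    base_cpm <- stats::rlnorm(n, meanlog = 4, sdlog = 1.2)

    n_inc <- round(config$element_effect_fraction * n)
    n_dec <- round(config$element_decrease_fraction * n)
    lab <- rep("none", n)
    pick <- sample.int(n, n_inc + n_dec)
    inc <- pick[seq_len(n_inc)]
    dec <- if (n_dec > 0) pick[n_inc + seq_len(n_dec)] else integer()
    lab[inc] <- "increase"
    lab[dec] <- "decrease"

    eff <- rep(1, n)
    eff[inc] <- stats::runif(n_inc, 0.75 * config$element_effect_size,
                             1.25 * config$element_effect_size) + 1
    eff[dec] <- 1 - config$element_decrease_size

    # parental bias applies mostly within the increased set
    bias <- rep("none", n)
    if (n_inc > 0) {
      nB <- round(config$element_parentB_high_fraction * n_inc)
      nA <- round(config$element_parentA_high_fraction * n_inc)
      ord <- sample(inc)
      bias[ord[seq_len(nB)]] <- "B"
      if (nA > 0) bias[ord[nB + seq_len(nA)]] <- "A"
    }
    r <- config$parental_bias_ratio
    cpm_A <- base_cpm * ifelse(bias == "A", r, 1)
    cpm_B <- base_cpm * ifelse(bias == "B", r, 1)
    cpm_adm <- 0.5 * (cpm_A + cpm_B) * eff

    exp_cpm <- cbind(parentA = cpm_A, parentB = cpm_B, admixed = cpm_adm)
    td <- config$total_reads_distribution
    totals <- round(stats::rlnorm(nrow(samples), td$meanlog, td$sdlog))
    names(totals) <- samples$sample_id
    mu <- exp_cpm[, samples$group, drop = FALSE] *
      rep(totals / 1e6, each = n)
    counts <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
             nrow = n)
    } else {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = n)
    }
    counts <- pmin(counts, rep(totals, each = n))
    dimnames(counts) <- list(ann$element_id, samples$sample_id)

    truth <- data.frame(
      element_id = ann$element_id, effect = lab, parental_bias = bias,
      cpm_parentA = cpm_A, cpm_parentB = cpm_B, cpm_admixed = cpm_adm,
      stringsAsFactors = FALSE
    )
    list(counts = count_matrix(counts, totals, annotation = ann), truth = truth)
  })
}

#' Simulate droplet digital PCR reactions
#'
#' Droplets are partitioned at the configured count and volume; positives for
#' target and reference are independent binomial draws with success
#' probability 1 - exp(-c * V), where the reference concentration is the
#' configured copies/nL and the target concentration scales with the true
#' copy number over the diploid reference state.
#'
#' @param config a [sim_config()].
#' @param true_cn_pairs data.frame(sample_id, assay_id, true_cn).
#' @return data.frame of reactions: sample_id, assay_id, droplets_total,
#'   pos_target, pos_reference, droplet_volume.
#' @export
simulate_ddpcr <- function(config, true_cn_pairs) {
  validate_sim_config(config)
  stopifnot(all(c("sample_id", "assay_id", "true_cn") %in% names(true_cn_pairs)))
  if (any(true_cn_pairs$true_cn < 0))
    stop("true_cn must be non-negative", call. = FALSE)
  with_substream(config$seed, "ddpcr", {
    n <- nrow(true_cn_pairs)
    v <- config$droplet_volume_nl
    c_ref <- config$reference_conc_per_nl
    c_tgt <- c_ref * true_cn_pairs$true_cn / 2
    p_pos <- function(conc) 1 - exp(-conc * v)
    data.frame(
      sample_id = true_cn_pairs$sample_id,
      assay_id = true_cn_pairs$assay_id,
      droplets_total = config$droplet_count,
      pos_target = stats::rbinom(n, config$droplet_count, p_pos(c_tgt)),
      pos_reference = stats::rbinom(n, config$droplet_count, p_pos(c_ref)),
      droplet_volume = v,
      stringsAsFactors = FALSE
    )
  })
}
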