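#' Pipeline configuration
#'
#' A single serializable configuration for all stages: output directory,
#' seed, the simulation settings, and the analysis thresholds and engine
#' switches. Unknown keys are rejected, and `load_config(save_config(c))`
#' round-trips.
#'
#' @param out_dir directory for all stage artifacts.
#' @param seed master seed (drives the simulation config).
#' @param sim named list of [sim_config()] overrides.
#' @param thresholds log2-ratio cutoffs for per-individual calls.
#' @param alpha significance level on BH-adjusted values.
#' @param span,iterations LOESS normalization parameters.
#' @param iqr_multiplier Tukey fence width for replicate filtering.
#' @param variance_engine "f" or "levene".
#' @param wilcoxon_exact_max combined sample size up to which exact rank-sum
#'   p-values are used.
#' @param repeat_group_sizes named group sizes of the sequencing cohort.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "pipeline_out", seed = 1L,
                            sim = list(), thresholds = c(0.5, 0.4),
                            alpha = 0.05, span = 0.3, iterations = 4L,
                            iqr_multiplier = 1.5,
                            variance_engine = "f",
                            wilcoxon_exact_max = 25L,
                            repeat_group_sizes = c(parentA = 13L,
                                                   parentB = 7L,
                                                   admixed = 10L)) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              thresholds = as.numeric(thresholds), alpha = as.numeric(alpha),
              span = as.numeric(span), iterations = as.integer(iterations),
              iqr_multiplier = as.numeric(iqr_multiplier),
              variance_engine = variance_engine,
              wilcoxon_exact_max = as.integer(wilcoxon_exact_max),
              repeat_group_sizes = repeat_group_sizes)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_config_fields <- c(
  "out_dir", "seed", "sim", "thresholds", "alpha", "span", "iterations",
  "iqr_multiplier", "variance_engine", "wilcoxon_exact_max",
  "repeat_group_sizes")

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_config_fields)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!(cfg$variance_engine %in% c("f", "levene")))
    stop("variance_engine must be 'f' or 'levene'", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(cfg$thresholds <= 0))
    stop("thresholds must be positive log2 cutoffs", call. = FALSE)
  invisible(cfg)
}

#' Save / load a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- unclass(cfg)
  # yaml drops names of atomic vectors; named counts go out as maps
  out$repeat_group_sizes <- as.list(out$repeat_group_sizes)
  if (!is.null(out$sim$group_sizes))
    out$sim$group_sizes <- as.list(out$sim$group_sizes)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_config_fields)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw$repeat_group_sizes <- vapply(raw$repeat_group_sizes, as.integer,
                                   integer(1))
  raw$seed <- as.integer(raw$seed)
  raw$iterations <- as.integer(raw$iterations)
  raw$wilcoxon_exact_max <- as.integer(raw$wilcoxon_exact_max)
  if (is.null(raw$sim)) raw$sim <- list()
  if (!is.null(raw$sim$group_sizes))
    raw$sim$group_sizes <- vapply(raw$sim$group_sizes, as.integer, integer(1))
  do.call(pipeline_config, raw)
}

sim_config_of <- function(cfg) {
  do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

write_manifest <- function(cfg, stage, inputs) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), tmp)
  manifest <- list(
    stage = stage, seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  file.remove(tmp)
  yaml::write_yaml(manifest,
                   stage_path(cfg, sprintf("manifest_%s.yaml", stage)))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate every input), `calibrate` (probe response
#' fits, QC, probe selection), `normalize` (mask, summarize, DNAcal, LOESS),
#' `genes` (rank-sum CNV tests, threshold calls, skewness, variance
#' comparisons), `repeats` (CPM tests, parental bias, composition), `ddpcr`
#' (copy-number estimation, ANOVA, de novo screen) and `report` (assemble the
#' summary). All outputs are TSV/YAML under `cfg$out_dir`, written
#' atomically; a manifest per stage records the config hash and input
#' checksums.
#'
#' @param stage stage name.
#' @param cfg a [pipeline_config()].
#' @return invisibly, the stage's main artifact path(s).
#' @export
run_stage <- function(stage, cfg) {
  stages <- c("simulate", "calibrate", "normalize", "genes", "repeats",
              "ddpcr", "report")
  if (!(stage %in% stages))
    stop("unknown stage '", stage, "'; expected one of ",
         paste(stages, collapse = ", "), call. = FALSE)
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- get(paste0("stage_", stage), envir = asNamespace("hybridCNV"))
  fn(cfg)
}

stage_simulate <- function(cfg) {
  sc <- sim_config_of(cfg)
  samples <- simulate_samples(sc)
  truth <- simulate_gene_truth(sc)
  cal <- simulate_calibration_arrays(sc)
  # the experimental array is printed with the probe per gene selected from
  # the calibration analysis, exactly as the design workflow dictates
  fits <- calibrate_probes(summarize_replicates(cal$features),
                           sc$dilution_levels_ng)
  selection <- select_probe_per_gene(
    fits, cal$truth$probe_params[, c("probe_id", "gene_id")])
  pp <- cal$truth$probe_params
  sel_pp <- pp[match(selection$probe_id, pp$probe_id), , drop = FALSE]
  expt <- simulate_experiment_arrays(sc, samples, truth, sel_pp)
  polys <- attr(expt, "bubble_polygons")

  rep_samples <- simulate_samples(sc, cfg$repeat_group_sizes)
  rep_sim <- simulate_repeat_counts(sc, rep_samples)

  # ddPCR: three validated increase loci over the array cohort plus two
  # F2 families screened at the same assays
  inc_genes <- utils::head(truth$gene_id[truth$de_novo == "increase"], 3)
  cn_of <- function(grp, gid) {
    i <- match(gid, truth$gene_id)
    switch(grp, parentA = truth$cn_parentA[i], parentB = truth$cn_parentB[i],
           admixed = truth$cn_admixed[i])
  }
  pairs <- do.call(rbind, lapply(inc_genes, function(gid) {
    data.frame(sample_id = samples$sample_id, assay_id = gid,
               true_cn = vapply(samples$group, cn_of, numeric(1), gid = gid),
               stringsAsFactors = FALSE)
  }))
  f2 <- expand.grid(indiv = seq_len(32), family = c("fam1", "fam2"),
                    assay_id = inc_genes, stringsAsFactors = FALSE)
  f2_pairs <- data.frame(
    sample_id = sprintf("F2_%s_%02d", f2$family, f2$indiv),
    assay_id = f2$assay_id,
    true_cn = ifelse(stats::runif(nrow(f2)) < 0.5,
                     vapply(f2$assay_id, function(g) cn_of("parentA", g),
                            numeric(1)),
                     vapply(f2$assay_id, function(g) cn_of("parentB", g),
                            numeric(1))),
    stringsAsFactors = FALSE)
  reactions <- simulate_ddpcr(sc, rbind(pairs, f2_pairs))
  reactions$family <- ifelse(grepl("^F2_fam1", reactions$sample_id), "fam1",
                      ifelse(grepl("^F2_fam2", reactions$sample_id), "fam2",
                             NA))

  write_tsv_atomic(samples, stage_path(cfg, "samples.tsv"))
  write_tsv_atomic(rep_samples, stage_path(cfg, "repeat_samples.tsv"))
  write_tsv_atomic(truth, stage_path(cfg, "gene_truth.tsv"))
  write_feature_table(cal$features, stage_path(cfg, "calibration_features.tsv"))
  write_tsv_atomic(cal$truth$probe_params, stage_path(cfg, "probe_truth.tsv"))
  write_feature_table(expt, stage_path(cfg, "experiment_features.tsv"))
  write_tsv_atomic(polys, stage_path(cfg, "bubble_polygons.tsv"))
  write_count_matrix(rep_sim$counts, stage_path(cfg, "repeat_counts.tsv"))
  write_tsv_atomic(rep_sim$truth, stage_path(cfg, "repeat_truth.tsv"))
  write_tsv_atomic(reactions, stage_path(cfg, "ddpcr_reactions.tsv"))
  write_manifest(cfg, "simulate", character())
  invisible(stage_path(cfg, "samples.tsv"))
}

stage_calibrate <- function(cfg) {
  sc <- sim_config_of(cfg)
  feats <- read_feature_table(stage_path(cfg, "calibration_features.tsv"))
  summ <- summarize_replicates(feats)
  fits <- calibrate_probes(summ, sc$dilution_levels_ng)
  pg <- data.frame(probe_id = unique(fits$probe_id), stringsAsFactors = FALSE)
  pg$gene_id <- sub("_p[0-9]+$", "", pg$probe_id)
  selection <- select_probe_per_gene(fits, pg)
  write_tsv_atomic(as.data.frame(fits), stage_path(cfg, "calibration_report.tsv"))
  write_tsv_atomic(selection, stage_path(cfg, "probe_selection.tsv"))
  write_manifest(cfg, "calibrate",
                 stage_path(cfg, "calibration_features.tsv"))
  invisible(stage_path(cfg, "calibration_report.tsv"))
}

stage_normalize <- function(cfg) {
  feats <- read_feature_table(stage_path(cfg, "experiment_features.tsv"))
  polys <- as.data.frame(read_tsv(stage_path(cfg, "bubble_polygons.tsv")))
  samples <- as.data.frame(read_tsv(stage_path(cfg, "samples.tsv")))
  fits <- as.data.frame(read_tsv(stage_path(cfg, "calibration_report.tsv")))
  class(fits) <- c("probe_calibration", "data.frame")
  selection <- as.data.frame(read_tsv(stage_path(cfg, "probe_selection.tsv")))

  feats <- mask_features(feats, polys)
  summ <- summarize_replicates(feats, iqr_multiplier = cfg$iqr_multiplier)
  # the printed probes are the calibration-selected ones: their fits apply
  fits_sel <- fits[fits$probe_id %in% selection$probe_id, , drop = FALSE]
  cal <- calibrate_intensities(summ, fits_sel)
  mat <- normalize_arrays(cal, samples, span = cfg$span,
                          iterations = cfg$iterations)
  write_normalized_matrix(mat, stage_path(cfg, "normalized_matrix.tsv"))
  write_manifest(cfg, "normalize",
                 c(stage_path(cfg, "experiment_features.tsv"),
                   stage_path(cfg, "calibration_report.tsv")))
  invisible(stage_path(cfg, "normalized_matrix.tsv"))
}

stage_genes <- function(cfg) {
  mat <- read_normalized_matrix(stage_path(cfg, "normalized_matrix.tsv"))
  samples <- as.data.frame(read_tsv(stage_path(cfg, "samples.tsv")))
  design <- group_design(samples, "admixed", c("parentA", "parentB"))
  calls <- test_group_difference(mat, design, tails = "two",
                                 alpha = cfg$alpha)
  adm <- mat[, design$focal, drop = FALSE]
  thr <- call_thresholds(adm, cfg$thresholds)
  sk <- skewness_test(group_mean_difference(mat, design))
  pairs <- list(c("admixed", "parentA"), c("admixed", "parentB"),
                c("parentA", "parentB"), c("parentB", "parentA"))
  var_counts <- lapply(pairs, function(pr) {
    va <- variance_comparison(
      mat, samples$sample_id[samples$group == pr[1]],
      samples$sample_id[samples$group == pr[2]],
      engine = cfg$variance_engine, alpha = cfg$alpha)
    list(pair = paste(pr[1], ">", pr[2]),
         n_significant = attr(va, "n_significant"))
  })
  write_tsv_atomic(as.data.frame(calls), stage_path(cfg, "gene_cnv_calls.tsv"))
  write_tsv_atomic(thr, stage_path(cfg, "gene_threshold_calls.tsv"))
  summary <- list(
    n_tested = sum(!is.na(calls$p)),
    n_increase = sum(calls$direction == "increase"),
    n_decrease = sum(calls$direction == "decrease"),
    skewness = list(skew = sk$skew, z = sk$z, p = sk$p),
    variance_pairs = var_counts,
    thresholds = lapply(cfg$thresholds, function(t) {
      sub <- thr[thr$threshold == t, ]
      dup <- sub$probe_id[sub$n_dup_individuals > 0]
      del <- sub$probe_id[sub$n_del_individuals > 0]
      list(threshold = t, n_dup = length(dup), n_del = length(del),
           n_both = length(intersect(dup, del)),
           n_variable = count_variable_genes(dup, del))
    })
  )
  yaml::write_yaml(summary, stage_path(cfg, "gene_summary.yaml"))
  write_manifest(cfg, "genes", stage_path(cfg, "normalized_matrix.tsv"))
  invisible(stage_path(cfg, "gene_summary.yaml"))
}

stage_repeats <- function(cfg) {
  cm <- read_count_matrix(stage_path(cfg, "repeat_counts.tsv"))
  samples <- as.data.frame(read_tsv(stage_path(cfg, "repeat_samples.tsv")))
  design <- group_design(samples, "admixed", c("parentA", "parentB"))
  cpm_mat <- cpm(cm)
  tests <- test_element_increase(cpm_mat, design, alpha = cfg$alpha)
  bias <- parental_bias(cpm_mat, tests$increase_candidates,
                        samples$sample_id[samples$group == "parentA"],
                        samples$sample_id[samples$group == "parentB"],
                        alpha = cfg$alpha)
  mri <- mean_relative_increase(cpm_mat, tests$increase_candidates, design)
  comp <- classification_summary(cm$annotation, tests$increase_candidates)
  write_tsv_atomic(tests$increase, stage_path(cfg, "repeat_increase_tests.tsv"))
  write_tsv_atomic(tests$decrease, stage_path(cfg, "repeat_decrease_tests.tsv"))
  share <- data.table::as.data.table(cpm_share_table(cpm_mat),
                                     keep.rownames = "element_id")
  write_tsv_atomic(share, stage_path(cfg, "repeat_cpm_share.tsv"))
  summary <- list(
    n_elements = nrow(cpm_mat),
    n_increase_candidates = length(tests$increase_candidates),
    pct_increase_candidates = report_percent(
      length(tests$increase_candidates), nrow(cpm_mat)),
    n_decrease_candidates = length(tests$decrease_candidates),
    mean_relative_increase_pct = mri$mean_percent,
    parental_bias = list(n_higher_in_B = bias$n_higher_in_B,
                         n_higher_in_A = bias$n_higher_in_A,
                         pct_higher_in_B = bias$pct_higher_in_B,
                         pct_higher_in_A = bias$pct_higher_in_A),
    n_classified_candidates = comp$n_classified_candidates,
    pct_classified_candidates = comp$pct_classified_candidates
  )
  yaml::write_yaml(summary, stage_path(cfg, "repeat_summary.yaml"))
  write_manifest(cfg, "repeats", stage_path(cfg, "repeat_counts.tsv"))
  invisible(stage_path(cfg, "repeat_summary.yaml"))
}

stage_ddpcr <- function(cfg) {
  reactions <- as.data.frame(read_tsv(stage_path(cfg, "ddpcr_reactions.tsv")))
  samples <- as.data.frame(read_tsv(stage_path(cfg, "samples.tsv")))
  est <- estimate_copy_numbers(reactions)
  est$family <- reactions$family[match(paste(est$sample_id, est$assay_id),
                                       paste(reactions$sample_id,
                                             reactions$assay_id))]
  grp <- samples$group[match(est$sample_id, samples$sample_id)]
  cohort <- est[!is.na(grp), , drop = FALSE]
  cohort$group <- grp[!is.na(grp)]
  comparisons <- lapply(split(cohort, cohort$assay_id), function(d) {
    gc <- group_comparison(d, d$group, alpha = cfg$alpha)
    list(assay_id = d$assay_id[1], anova_f = gc$anova_f,
         anova_p = gc$anova_p,
         significant_pairs = gc$tukey$pair[gc$tukey$significant])
  })
  f2 <- est[grepl("^F2_", est$sample_id), , drop = FALSE]
  parental <- cohort[cohort$group %in% c("parentA", "parentB"), , drop = FALSE]
  screen <- de_novo_screen(f2, parental)
  write_tsv_atomic(est[, setdiff(names(est), "family")],
                   stage_path(cfg, "ddpcr_estimates.tsv"))
  write_tsv_atomic(screen, stage_path(cfg, "ddpcr_de_novo_screen.tsv"))
  yaml::write_yaml(
    list(comparisons = unname(comparisons),
         n_f2_flagged = sum(screen$de_novo)),
    stage_path(cfg, "ddpcr_summary.yaml"))
  write_manifest(cfg, "ddpcr", stage_path(cfg, "ddpcr_reactions.tsv"))
  invisible(stage_path(cfg, "ddpcr_summary.yaml"))
}

stage_report <- function(cfg) {
  report <- summarize_results(cfg$out_dir)
  yaml::write_yaml(report, stage_path(cfg, "report.yaml"))
  write_manifest(cfg, "report",
                 c(stage_path(cfg, "gene_summary.yaml"),
                   stage_path(cfg, "repeat_summary.yaml"),
                   stage_path(cfg, "ddpcr_summary.yaml")))
  invisible(stage_path(cfg, "report.yaml"))
}

#' Assemble the cross-stage results report
#'
#' Reads the per-stage summaries from disk and assembles one report; every
#' number is recomputable from the on-disk stage artifacts.
#'
#' @param out_dir directory holding the stage outputs.
#' @return nested list (gene, repeat, ddpcr sections).
#' @export
summarize_results <- function(out_dir) {
  pick <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) yaml::read_yaml(p) else NULL
  }
  list(gene_cnv = pick("gene_summary.yaml"),
       repeat_cnv = pick("repeat_summary.yaml"),
       ddpcr = pick("ddpcr_summary.yaml"))
}

#' Derived summary arithmetic from printed result counts
#'
#' Recomputes the quantities that are pure arithmetic on the headline counts
#' of an experiment of this design: the array feature total (probes x
#' replicates x arrays), the distinct variable-gene union, and the report
#' percentages (half-up, one decimal).
#'
#' @param counts named list: n_probes, n_replicates, n_arrays, n_dup, n_del,
#'   n_both, n_candidates, n_classified, n_retro_total, n_retro_increased,
#'   n_order_total, n_order_increased, n_unclassified_total,
#'   n_unclassified_increased, n_blastx_total, n_blastx_increased,
#'   n_elements, n_bias_B, n_bias_A.
#' @return named list of derived values.
#' @export
summary_arithmetic <- function(counts) {
  with(counts, list(
    n_features = n_probes * n_replicates * n_arrays,
    n_variable_genes = n_dup + n_del - n_both,
    pct_variable_genes = report_percent(n_dup + n_del - n_both, n_probes),
    pct_classified_candidates = report_percent(n_classified, n_candidates),
    pct_retro_increased = report_percent(n_retro_increased, n_retro_total),
    pct_order_increased = report_percent(n_order_increased, n_order_total),
    pct_unclassified_increased = report_percent(n_unclassified_increased,
                                                n_unclassified_total),
    pct_blastx_increased = report_percent(n_blastx_increased, n_blastx_total),
    pct_candidates = report_percent(n_candidates, n_elements),
    pct_bias_B = report_percent(n_bias_B, n_candidates),
    pct_bias_A = report_percent(n_bias_A, n_candidates)
  ))
}

#' Run the array arm in memory on simulated data
#'
#' Convenience composition of the whole aCGH arm: simulate gene truth,
#' calibration arrays and experimental arrays, fit and filter probe
#' responses, select one probe per gene, mask bubbles, summarize replicates,
#' calibrate to DNA-equivalents and LOESS-normalize -- returning the
#' normalized probes x samples matrix with the ground truth attached.
#'
#' @param config a [sim_config()].
#' @param samples optional sample metadata (default: [simulate_samples()]).
#' @return list(mat, truth, samples, fits, selection).
#' @export
acgh_pipeline <- function(config, samples = NULL) {
  if (is.null(samples)) samples <- simulate_samples(config)
  truth <- simulate_gene_truth(config)
  cal <- simulate_calibration_arrays(config)
  fits <- calibrate_probes(summarize_replicates(cal$features),
                           config$dilution_levels_ng)
  selection <- select_probe_per_gene(
    fits, cal$truth$probe_params[, c("probe_id", "gene_id")])
  pp <- cal$truth$probe_params
  sel_pp <- pp[match(selection$probe_id, pp$probe_id), , drop = FALSE]
  expt <- simulate_experiment_arrays(config, samples, truth, sel_pp)
  expt <- mask_features(expt, attr(expt, "bubble_polygons"))
  summ <- summarize_replicates(expt)
  calint <- calibrate_intensities(
    summ, fits[fits$probe_id %in% selection$probe_id, , drop = FALSE])
  mat <- normalize_arrays(calint, samples)
  list(mat = mat, truth = truth, samples = samples, fits = fits,
       selection = selection)
}
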