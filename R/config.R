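#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every simulator
#' in the package. Defaults reproduce the study conditions of the motivating
#' experiment: an 8-level dilution series (25--1,600 ng) hybridized with two
#' replicate features per probe for calibration; an experimental two-colour
#' array with five replicate features per probe, 400 ng starting DNA and a
#' diploid common reference; three sample groups (two parental species and an
#' admixed lineage, 8 individuals each on arrays); a parental copy-number
#' divergence fraction of 0.159 with the admixed genome drawn from parent B
#' with probability 0.6; a 12-gene admixed-specific increase set (copy number
#' 3 vs 2, log2 ratio 0.585) and a 13-gene decrease set; a library of 1,005
#' repetitive elements of which 20.7% are increased in the admixed group by
#' 30.5% on average; and a 20,000-droplet, 0.85 nL partition model for ddPCR.
#'
#' @param seed integer master seed; all simulators derive named substreams
#'   from it so outputs are bit-reproducible and mutually independent.
#' @param n_genes number of genes on the experimental array (one selected
#'   probe per gene); the calibration design carries
#'   `n_probes_per_gene` candidate probes per gene.
#' @param n_probes_per_gene candidate probes per gene on the calibration
#'   array (default 3).
#' @param dilution_levels_ng strictly increasing DNA amounts (ng) of the
#'   calibration dilution series.
#' @param n_replicates_calibration,n_replicates_experiment replicate features
#'   per probe per array on the calibration and experimental designs.
#' @param array_rows,array_cols grid dimensions of one array; enlarged
#'   automatically when a design needs more spots.
#' @param slope_distribution list(meanlog, sdlog) of the lognormal per-probe
#'   response slope (signal a.u. per ng).
#' @param intercept_distribution list(mean, sd) of the per-probe background
#'   intercept (signal a.u.); draws are truncated at 1.
#' @param noise_sd additive Gaussian noise sd on linear-scale intensities
#'   (a.u.); negative draws are clamped to 0. See [noise_sd_for_m_sd()] to
#'   derive it from a target log2-ratio noise level.
#' @param fraction_nonlinear,fraction_unresponsive proportions of calibration
#'   probes given a saturating, resp. flat, response.
#' @param group_sizes named counts per species group for array samples
#'   (names among parentA, parentB, admixed, F2).
#' @param ancestry_bias probability that the admixed lineage inherits a
#'   gene's state from parent B (default 0.6).
#' @param divergence_fraction fraction of genes whose copy number differs
#'   between the parental species (default 0.159).
#' @param cn_effects list of admixed-specific copy-number effects, each a
#'   list(n = set size, cn = admixed copy number); defaults inject 12 genes
#'   at CN 3 and 13 genes at CN 1.
#' @param starting_dna_ng test/reference starting DNA on experimental arrays.
#' @param reference_cn copy number of the common reference sample.
#' @param locus_representation_sdlog sdlog of the per-locus lognormal
#'   hybridization-representation multiplier on experimental arrays; it
#'   scales the effective DNA of both channels equally (so log2 ratios are
#'   untouched) and gives the average log2 intensity A its realistic spread.
#' @param dye_bias_coefficients polynomial coefficients (intercept first) of
#'   the intensity-dependent log2-ratio bias as a function of average log2
#'   intensity A, injected so LOESS normalization is exercised.
#' @param n_bubble_arrays number of experimental arrays given a central
#'   bubble artifact (default 9).
#' @param bubble_polygons optional data.frame(array_id, vertex_index, row,
#'   col); when NULL, a central octagon is placed on the first
#'   `n_bubble_arrays` experimental arrays.
#' @param bubble_attenuation multiplicative intensity attenuation inside
#'   bubbles (default 0.2).
#' @param n_elements repeat-library size (default 1,005).
#' @param total_reads_distribution list(meanlog, sdlog) of per-individual
#'   sequencing depth (default centred on 2e6 reads).
#' @param element_effect_fraction fraction of elements increased in the
#'   admixed group (default 0.207).
#' @param element_effect_size mean relative CPM increase of affected elements
#'   in the admixed group (default 0.305).
#' @param element_decrease_fraction,element_decrease_size fraction and
#'   relative size of admixed-specific decreases (rare by default).
#' @param element_parentB_high_fraction among increased elements, fraction
#'   with higher parental abundance in parent B (default 0.54); a further
#'   `element_parentA_high_fraction` (default 0.014) is higher in parent A.
#' @param element_parentA_high_fraction see above.
#' @param parental_bias_ratio CPM ratio of the high over the low parent for
#'   parentally biased elements.
#' @param nb_dispersion negative-binomial dispersion of read counts
#'   (variance = mu + dispersion * mu^2).
#' @param droplet_count,droplet_volume_nl ddPCR partition model: droplets per
#'   reaction and droplet volume in nL.
#' @param reference_conc_per_nl concentration of the single-copy reference
#'   amplicon in copies per nL (sets the Poisson load of the assay).
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 12105L,
                       n_probes_per_gene = 3L,
                       dilution_levels_ng = c(25, 50, 100, 200, 400, 800, 1200, 1600),
                       n_replicates_calibration = 2L,
                       n_replicates_experiment = 5L,
                       array_rows = 267L,
                       array_cols = 228L,
                       slope_distribution = list(meanlog = 0, sdlog = 0.25),
                       intercept_distribution = list(mean = 50, sd = 10),
                       noise_sd = 30,
                       fraction_nonlinear = 0.02,
                       fraction_unresponsive = 0.02,
                       group_sizes = c(parentA = 8L, parentB = 8L, admixed = 8L),
                       ancestry_bias = 0.6,
                       divergence_fraction = 0.159,
                       cn_effects = list(list(n = 12L, cn = 3),
                                         list(n = 13L, cn = 1)),
                       starting_dna_ng = 400,
                       reference_cn = 2,
                       locus_representation_sdlog = 0.6,
                       dye_bias_coefficients = c(0.6, -0.12, 0.005),
                       n_bubble_arrays = 9L,
                       bubble_polygons = NULL,
                       bubble_attenuation = 0.2,
                       n_elements = 1005L,
                       total_reads_distribution = list(meanlog = log(2e6), sdlog = 0.15),
                       element_effect_fraction = 0.207,
                       element_effect_size = 0.305,
                       element_decrease_fraction = 0.012,
                       element_decrease_size = 0.25,
                       element_parentB_high_fraction = 0.54,
                       element_parentA_high_fraction = 0.014,
                       parental_bias_ratio = 1.5,
                       nb_dispersion = 0.05,
                       droplet_count = 20000L,
                       droplet_volume_nl = 0.85,
                       reference_conc_per_nl = 1.0) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_probes_per_gene = as.integer(n_probes_per_gene),
    dilution_levels_ng = as.numeric(dilution_levels_ng),
    n_replicates_calibration = as.integer(n_replicates_calibration),
    n_replicates_experiment = as.integer(n_replicates_experiment),
    array_rows = as.integer(array_rows),
    array_cols = as.integer(array_cols),
    slope_distribution = slope_distribution,
    intercept_distribution = intercept_distribution,
    noise_sd = as.numeric(noise_sd),
    fraction_nonlinear = as.numeric(fraction_nonlinear),
    fraction_unresponsive = as.numeric(fraction_unresponsive),
    group_sizes = group_sizes,
    ancestry_bias = as.numeric(ancestry_bias),
    divergence_fraction = as.numeric(divergence_fraction),
    cn_effects = cn_effects,
    starting_dna_ng = as.numeric(starting_dna_ng),
    reference_cn = as.numeric(reference_cn),
    locus_representation_sdlog = as.numeric(locus_representation_sdlog),
    dye_bias_coefficients = as.numeric(dye_bias_coefficients),
    n_bubble_arrays = as.integer(n_bubble_arrays),
    bubble_polygons = bubble_polygons,
    bubble_attenuation = as.numeric(bubble_attenuation),
    n_elements = as.integer(n_elements),
    total_reads_distribution = total_reads_distribution,
    element_effect_fraction = as.numeric(element_effect_fraction),
    element_effect_size = as.numeric(element_effect_size),
    element_decrease_fraction = as.numeric(element_decrease_fraction),
    element_decrease_size = as.numeric(element_decrease_size),
    element_parentB_high_fraction = as.numeric(element_parentB_high_fraction),
    element_parentA_high_fraction = as.numeric(element_parentA_high_fraction),
    parental_bias_ratio = as.numeric(parental_bias_ratio),
    nb_dispersion = as.numeric(nb_dispersion),
    droplet_count = as.integer(droplet_count),
    droplet_volume_nl = as.numeric(droplet_volume_nl),
    reference_conc_per_nl = as.numeric(reference_conc_per_nl)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_genes", "n_probes_per_gene", "n_replicates_calibration",
              "n_replicates_experiment", "array_rows", "array_cols",
              "n_elements", "droplet_count")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      config_error(f, "must be a count >= 1")
  }
  props <- c("fraction_nonlinear", "fraction_unresponsive", "ancestry_bias",
             "divergence_fraction", "element_effect_fraction",
             "element_decrease_fraction", "element_parentB_high_fraction",
             "element_parentA_high_fraction")
  for (f in props) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      config_error(f, "must be a proportion in [0, 1]")
  }
  d <- cfg$dilution_levels_ng
  if (length(d) < 3L || any(d <= 0) || any(diff(d) <= 0))
    config_error("dilution_levels_ng",
                 "must be >= 3 strictly increasing positive amounts")
  if (cfg$noise_sd < 0) config_error("noise_sd", "must be non-negative")
  if (is.null(names(cfg$group_sizes)) ||
      !all(names(cfg$group_sizes) %in% c("parentA", "parentB", "admixed", "F2")))
    config_error("group_sizes",
                 "must be named with groups among parentA, parentB, admixed, F2")
  if (any(cfg$group_sizes < 1L)) config_error("group_sizes", "all counts >= 1")
  if (cfg$fraction_nonlinear + cfg$fraction_unresponsive > 1)
    config_error("fraction_nonlinear", "defect fractions must sum to <= 1")
  if (cfg$nb_dispersion < 0) config_error("nb_dispersion", "must be >= 0")
  if (cfg$droplet_volume_nl <= 0) config_error("droplet_volume_nl", "must be > 0")
  if (cfg$bubble_attenuation < 0 || cfg$bubble_attenuation > 1)
    config_error("bubble_attenuation", "must be in [0, 1]")
  invisible(cfg)
}

#' Intensity-scale noise sd for a target log2-ratio noise level
#'
#' The simulators add Gaussian noise on the linear intensity scale. For a
#' signal S observed in two channels with additive noise sd s, the induced
#' noise on the per-feature log2 ratio M is approximately
#' sd(M) = sqrt(2) * s / (S * ln 2). This helper inverts that relation at the
#' typical signal of the experimental design (median response slope at the
#' starting DNA amount, plus the background intercept), so scenarios can be
#' specified by their log2-ratio noise.
#'
#' @param m_sd target per-feature sd of the log2 ratio.
#' @param config a [sim_config()].
#' @return intensity-scale noise sd (a.u.).
#' @export
noise_sd_for_m_sd <- function(m_sd, config) {
  typical_signal <- config$intercept_distribution$mean +
    exp(config$slope_distribution$meanlog) * config$starting_dna_ng
  m_sd * typical_signal * log(2) / sqrt(2)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  genes: ", x$n_genes, " (", x$n_probes_per_gene,
      " calibration probes each)\n", sep = "")
  cat("  dilution series (ng): ", paste(x$dilution_levels_ng, collapse = ", "),
      "\n", sep = "")
  cat("  array groups: ",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  repeat library: ", x$n_elements, " elements; ",
      round(100 * x$element_effect_fraction, 1),
      "% increased by ", round(100 * x$element_effect_size, 1),
      "% in the admixed group\n", sep = "")
  invisible(x)
}

# Named substreams: each simulator re-seeds from (master seed, stream name) so
# adding or reordering simulators never perturbs the draws of another.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) * 2654435 %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}
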