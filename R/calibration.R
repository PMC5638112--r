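#' Fit one probe's linear signal response over the dilution series
#'
#' Ordinary least squares of mean signal intensity on DNA amount (linear
#' scale, as required by the DNAcal back-transformation). Quality metrics:
#' the coefficient of determination; the signal-to-error ratio, defined as
#' the fitted signal at the highest dilution level divided by the residual
#' standard error; and a one-sided t-test of slope > 0 at alpha = 0.05 that
#' labels unresponsive probes. Status is `unresponsive` when the slope is not
#' significantly positive, else `nonlinear` when R^2 < 0.95, else `low_ser`
#' when the signal-to-error ratio is below 10, else `pass`.
#'
#' @param levels DNA amounts (ng), at least 3 distinct values.
#' @param signals mean signal intensities, same length.
#' @return list(slope, intercept, r_squared, signal_to_error, p_slope,
#'   status) of class `probe_response_fit`.
#' @export
fit_probe_response <- function(levels, signals) {
  x <- as.numeric(levels)
  y <- as.numeric(signals)
  if (length(x) != length(y) || length(unique(x)) < 3L)
    stop("input error: need signals at >= 3 distinct dilution levels",
         call. = FALSE)
  f <- fit_response_vec(matrix(y, nrow = 1), x)
  out <- lapply(f, `[`, 1)
  class(out) <- "probe_response_fit"
  out
}

#' @export
print.probe_response_fit <- function(x, ...) {
  cat(sprintf(
    "probe response: slope %.4g a.u./ng, intercept %.4g a.u., R^2 %.4f, S/E %.3g -> %s\n",
    x$slope, x$intercept, x$r_squared, x$signal_to_error, x$status))
  invisible(x)
}

# Row-wise OLS of signal on DNA amount: Y is probes x levels. Returns the
# per-probe fit and QC metrics as vectors.
fit_response_vec <- function(Y, x) {
  n <- length(x)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  ybar <- rowMeans(Y)
  sxy <- as.numeric(Y %*% (x - xbar))
  syy <- rowSums((Y - ybar)^2)
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  rss <- pmax(0, syy - slope * sxy)
  r2 <- ifelse(syy > 0, pmax(0, pmin(1, 1 - rss / syy)), 0)
  res_se <- sqrt(rss / (n - 2))
  se_slope <- res_se / sqrt(sxx)
  t_slope <- ifelse(se_slope > 0, slope / se_slope,
                    ifelse(slope > 0, Inf, 0))
  p_slope <- stats::pt(t_slope, df = n - 2, lower.tail = FALSE)
  fitted_top <- intercept + slope * max(x)
  ser <- ifelse(res_se > 0, fitted_top / res_se, Inf)
  status <- rep("pass", nrow(Y))
  status[ser < 10] <- "low_ser"
  status[r2 < 0.95] <- "nonlinear"
  status[!(p_slope < 0.05)] <- "unresponsive"
  list(slope = slope, intercept = intercept, r_squared = r2,
       signal_to_error = ser, p_slope = p_slope, status = status)
}

#' Fit all probe responses of a calibration experiment
#'
#' Takes the summarized calibration intensities (one mean per probe, array
#' and channel, arrays being dilution levels), fits every probe's response
#' per channel, and also records the log-log response slope (`slope_score`,
#' 1 = proportional response) used for probe selection.
#'
#' @param summarized output of [summarize_replicates()] on the calibration
#'   feature table.
#' @param dilution_levels_ng named or ordered DNA amounts; `array_id`s are
#'   matched to levels by sorted order unless `level_of_array` is given.
#' @param level_of_array optional named vector array_id -> ng.
#' @return data.frame of class `probe_calibration`: probe_id, channel,
#'   slope, intercept, r_squared, signal_to_error, p_slope, slope_score,
#'   status. Probes missing any level in a channel are dropped (reported via
#'   attribute `n_incomplete`).
#' @export
calibrate_probes <- function(summarized, dilution_levels_ng,
                             level_of_array = NULL) {
  dt <- data.table::as.data.table(summarized)
  if (is.null(level_of_array)) {
    arrays <- sort(unique(dt$array_id))
    if (length(arrays) != length(dilution_levels_ng))
      stop("input error: number of arrays != number of dilution levels",
           call. = FALSE)
    level_of_array <- stats::setNames(as.numeric(dilution_levels_ng), arrays)
  }
  dt$ng <- level_of_array[dt$array_id]
  one_channel <- function(ch) {
    sub <- dt[dt$channel == ch]
    wide <- data.table::dcast(sub, probe_id ~ ng, value.var = "mean_signal")
    lev <- as.numeric(names(wide)[-1])
    Y <- as.matrix(wide[, -1])
    complete <- stats::complete.cases(Y)
    wide <- wide[complete]
    Y <- Y[complete, , drop = FALSE]
    f <- fit_response_vec(Y, lev)
    # log-log response slope: 1 means signal proportional to DNA amount
    lx <- log(lev)
    lY <- log(pmax(Y, .Machine$double.eps))
    sxx <- sum((lx - mean(lx))^2)
    slope_score <- as.numeric(lY %*% (lx - mean(lx))) / sxx
    data.table::data.table(
      probe_id = wide$probe_id, channel = ch,
      slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
      signal_to_error = f$signal_to_error, p_slope = f$p_slope,
      slope_score = slope_score, status = f$status,
      n_incomplete = sum(!complete)
    )
  }
  out <- data.table::rbindlist(list(one_channel("green"), one_channel("red")))
  n_inc <- sum(out$n_incomplete[!duplicated(out$channel)])
  out[, "n_incomplete" := NULL]
  out <- as.data.frame(out)
  attr(out, "n_incomplete") <- n_inc
  class(out) <- c("probe_calibration", "data.frame")
  out
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat("Probe calibration:", length(unique(x$probe_id)), "probes x 2 channels\n")
  print(table(channel = x$channel, status = x$status))
  invisible(x)
}

#' @export
summary.probe_calibration <- function(object, ...) {
  both_pass <- filter_probes(object)
  cat("Probe calibration summary\n")
  cat("  probes fitted:           ", length(unique(object$probe_id)), "\n")
  cat("  pass in both channels:   ", length(both_pass$pass), "\n")
  cat("  failure counts (probes):\n")
  print(both_pass$failure_counts)
  invisible(both_pass)
}

#' Retain probes that pass quality control in both channels
#'
#' A probe is retained only when its fit status is `pass` in the green and
#' the red channel. Failure counts classify each excluded probe by its most
#' severe failure (unresponsive > nonlinear > low_ser).
#'
#' @param fits a `probe_calibration` table.
#' @return list(pass = probe ids, failure_counts = named counts).
#' @export
filter_probes <- function(fits) {
  st <- data.table::as.data.table(fits)
  wide <- data.table::dcast(st, probe_id ~ channel, value.var = "status")
  ok <- !is.na(wide$green) & wide$green == "pass" &
    !is.na(wide$red) & wide$red == "pass"
  sev <- function(g, r) {
    both <- c(g, r)
    if (any(both == "unresponsive", na.rm = TRUE)) return("unresponsive")
    if (any(both == "nonlinear", na.rm = TRUE)) return("nonlinear")
    if (any(both == "low_ser", na.rm = TRUE)) return("low_ser")
    "incomplete"
  }
  fail <- mapply(sev, wide$green[!ok], wide$red[!ok])
  counts <- table(factor(fail, levels = c("unresponsive", "nonlinear",
                                          "low_ser", "incomplete")))
  list(pass = wide$probe_id[ok], failure_counts = counts)
}

#' Select one probe per gene by proportionality of response
#'
#' Among a gene's passing probes, picks the probe whose log-log response
#' slope (averaged over the two channels) is closest to 1, i.e. the probe
#' whose signal scales most nearly proportionally with DNA amount. Ties are
#' broken by lexicographically smaller probe id.
#'
#' @param fits a `probe_calibration` table.
#' @param probe_gene data.frame(probe_id, gene_id).
#' @param pass_only restrict to probes passing QC in both channels
#'   (default TRUE).
#' @return data.frame(gene_id, probe_id, slope_score).
#' @export
select_probe_per_gene <- function(fits, probe_gene, pass_only = TRUE) {
  st <- data.table::as.data.table(fits)
  sc <- st[, list(slope_score = mean(.SD$slope_score)), by = "probe_id"]
  if (pass_only) {
    keep <- filter_probes(fits)$pass
    sc <- sc[sc$probe_id %in% keep]
  }
  sc$gene_id <- probe_gene$gene_id[match(sc$probe_id, probe_gene$probe_id)]
  sc <- sc[!is.na(sc$gene_id)]
  sc$dist <- abs(sc$slope_score - 1)
  data.table::setorderv(sc, c("gene_id", "dist", "probe_id"))
  sel <- sc[!duplicated(sc$gene_id)]
  as.data.frame(sel[, c("gene_id", "probe_id", "slope_score")])
}

#' Back-transform an observed signal into calibrated DNA-equivalents
#'
#' DNAcal = (observed - intercept) / slope, using the probe's dilution-series
#' regression for the matching channel.
#'
#' @param observed observed mean signal (a.u.).
#' @param fit a `probe_response_fit` or anything with `slope`, `intercept`
#'   and `status` fields.
#' @return calibrated DNA-equivalent (ng); may be non-positive -- see
#'   [calibrate_intensities()] for the clamping applied before logarithms.
#' @export
apply_calibration <- function(observed, fit) {
  if (!is.null(fit$status) && !all(fit$status == "pass"))
    stop("calibration error: probe did not pass QC", call. = FALSE)
  if (any(fit$slope <= 0))
    stop("calibration error: slope must be > 0", call. = FALSE)
  (observed - fit$intercept) / fit$slope
}

#' Calibrate a summarized intensity table
#'
#' Applies DNAcal per probe/array/channel for the given passing fits.
#' Non-positive calibrated values are clamped to a floor (default: half the
#' smallest positive calibrated value on that array) and flagged, so
#' downstream logarithms are defined.
#'
#' @param summarized output of [summarize_replicates()] on experimental
#'   arrays.
#' @param fits a `probe_calibration` table; only probes passing both
#'   channels are calibrated.
#' @param floor optional fixed clamping floor (ng).
#' @return data.table(array_id, probe_id, channel, dna_cal, clamped).
#' @export
calibrate_intensities <- function(summarized, fits, floor = NULL) {
  st <- data.table::as.data.table(summarized)
  ft <- data.table::as.data.table(fits)
  pass_ids <- filter_probes(fits)$pass
  st <- st[st$probe_id %in% pass_ids]
  ft <- ft[ft$probe_id %in% pass_ids]
  idx <- match(paste(st$probe_id, st$channel),
               paste(ft$probe_id, ft$channel))
  slope <- ft$slope[idx]
  intercept <- ft$intercept[idx]
  if (any(slope <= 0, na.rm = TRUE))
    stop("calibration error: slope must be > 0", call. = FALSE)
  out <- data.table::data.table(
    array_id = st$array_id, probe_id = st$probe_id, channel = st$channel,
    dna_cal = (st$mean_signal - intercept) / slope
  )
  out$clamped <- out$dna_cal <= 0
  for (aid in unique(out$array_id[out$clamped])) {
    sel <- out$array_id == aid
    fl <- floor
    if (is.null(fl)) {
      pos <- out$dna_cal[sel & out$dna_cal > 0]
      fl <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
    }
    data.table::set(out, i = which(sel & out$clamped), j = "dna_cal",
                    value = fl)
  }
  out[]
}
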