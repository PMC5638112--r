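#' Log-ratio / average-intensity (M, A) coordinates
#'
#' M = log2(test / reference), A = mean of the two log2 calibrated values.
#' Inputs must be positive: non-positive calibrated values must have been
#' clamped upstream ([calibrate_intensities()]).
#'
#' @param test,reference calibrated DNA-equivalents (ng) of the test (Cy5)
#'   and reference (Cy3) channel, matched element-wise.
#' @return data.frame(M, A).
#' @export
compute_ma <- function(test, reference) {
  if (any(test <= 0) || any(reference <= 0))
    stop("compute_ma: non-positive calibrated values; clamp upstream",
         call. = FALSE)
  lt <- log2(test)
  lr <- log2(reference)
  data.frame(M = lt - lr, A = 0.5 * (lt + lr))
}

#' LOESS normalization of log2 ratios against average intensity
#'
#' Fits a robust local linear regression of M on A (tricube weights, the
#' given span, `iterations` total fitting passes of which the later ones
#' reweight with bisquare robustness weights) and returns the residuals as
#' normalized log2 ratios, removing intensity-dependent dye bias. No
#' background correction is applied anywhere in the pipeline. With fewer
#' than `min_pairs` points a LOESS fit is not meaningful and the function
#' falls back to median-centering, with a warning.
#'
#' @param M,A numeric vectors from [compute_ma()], one array's worth.
#' @param span fraction of points in each local window (default 0.3).
#' @param iterations total fitting passes (default 4, i.e. 3 robustifying
#'   reweights).
#' @param min_pairs minimum points for a LOESS fit (default 50).
#' @return numeric vector of normalized M values.
#' @export
loess_normalize <- function(M, A, span = 0.3, iterations = 4, min_pairs = 50) {
  if (length(span) != 1 || is.na(span) || span <= 0 || span > 1)
    stop("parameter error: span must be in (0, 1]", call. = FALSE)
  stopifnot(length(M) == length(A))
  if (length(M) < min_pairs) {
    warning("fewer than ", min_pairs,
            " (M, A) pairs: falling back to median-centering")
    return(M - stats::median(M, na.rm = TRUE))
  }
  fit <- limma::loessFit(y = M, x = A, span = span, iterations = iterations)
  fit$residuals
}

#' Normalize a calibrated two-channel experiment to a probes x samples matrix
#'
#' For each array, pairs the red-channel (test) and green-channel (common
#' reference) calibrated values per probe, computes (M, A) and applies
#' [loess_normalize()]; columns are assembled into a probes x samples matrix
#' (NA where a probe is absent on an array).
#'
#' @param calibrated output of [calibrate_intensities()].
#' @param samples sample metadata; `sample_id` must equal the array ids.
#' @param span,iterations passed to [loess_normalize()].
#' @return matrix of class `normalized_matrix` (probes x samples) with the
#'   metadata in attribute `samples`.
#' @export
normalize_arrays <- function(calibrated, samples, span = 0.3, iterations = 4) {
  ct <- data.table::as.data.table(calibrated)
  wide <- data.table::dcast(ct, array_id + probe_id ~ channel,
                            value.var = "dna_cal")
  wide <- wide[!is.na(wide$green) & !is.na(wide$red)]
  probes <- sort(unique(wide$probe_id))
  arrays <- samples$sample_id
  mat <- matrix(NA_real_, length(probes), length(arrays),
                dimnames = list(probes, arrays))
  for (aid in arrays) {
    sub <- wide[wide$array_id == aid]
    if (nrow(sub) == 0L) next
    ma <- compute_ma(sub$red, sub$green)
    mat[sub$probe_id, aid] <- loess_normalize(ma$M, ma$A, span, iterations)
  }
  attr(mat, "samples") <- samples
  class(mat) <- c("normalized_matrix", class(mat))
  mat
}
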