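#' Point-in-polygon test (ray casting, boundary inclusive)
#'
#' Points on a polygon edge or vertex count as inside: when excising artifact
#' regions it is conservative to drop borderline features.
#'
#' @param px,py point coordinates (row, col).
#' @param vx,vy polygon vertex coordinates in order.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, vx, vy) {
  if (length(vx) < 3L)
    stop("geometry error: polygon needs at least 3 vertices", call. = FALSE)
  eps <- 1e-9
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= min(xi, xj) - eps & px <= max(xi, xj) + eps &
      py >= min(yi, yj) - eps & py <= max(yi, yj) + eps
    on_edge <- on_edge | (abs(cross) < eps & within)
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside | on_edge
}

#' Flag features inside bubble-artifact polygons
#'
#' Applies every polygon to the features of its own array and sets the
#' `masked` flag for features whose grid position lies inside or on the
#' boundary. Idempotent; never unsets an existing mask; row count and order
#' are preserved.
#'
#' @param features a feature table (columns array_id, probe_id, replicate,
#'   row, col, signal_green, signal_red, masked).
#' @param polygons data.frame(array_id, vertex_index, row, col); one polygon
#'   per array_id.
#' @return the feature table with updated `masked`.
#' @export
mask_features <- function(features, polygons) {
  ft <- data.table::as.data.table(features)
  if (is.null(polygons) || nrow(polygons) == 0L) return(ft[])
  for (aid in unique(polygons$array_id)) {
    pp <- polygons[polygons$array_id == aid, , drop = FALSE]
    pp <- pp[order(pp$vertex_index), , drop = FALSE]
    if (nrow(pp) < 3L)
      stop("geometry error: polygon needs at least 3 vertices", call. = FALSE)
    sel <- which(ft$array_id == aid)
    if (length(sel) == 0L) next
    hit <- points_in_polygon(ft$row[sel], ft$col[sel], pp$row, pp$col)
    if (any(hit))
      data.table::set(ft, i = sel[hit], j = "masked", value = TRUE)
  }
  ft[]
}

#' Tukey-fence outlier filter for probe replicates
#'
#' Removes replicate intensities outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR], with
#' quartiles by linear interpolation between order statistics (quantile
#' type 7). Fewer than three values are returned unchanged -- fences are
#' meaningless for n <= 2.
#'
#' @param values non-negative replicate intensities (masked replicates
#'   already excluded).
#' @param k fence width in IQR multiples (default 1.5).
#' @return the retained values.
#' @export
filter_replicate_outliers <- function(values, k = 1.5) {
  values <- as.numeric(values)
  if (length(values) < 3L) return(values)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

# Vectorised Tukey-fence keep flags over many groups at once (type-7
# quartiles via order statistics). Equivalent to filter_replicate_outliers()
# group by group, but O(n log n) overall -- needed at the scale of ~600k
# (array, probe, channel) groups per experiment.
tukey_keep_grouped <- function(v, g, n_groups = max(g), k = 1.5) {
  o <- order(g, v)
  gs <- g[o]
  vs <- v[o]
  n <- tabulate(gs, n_groups)
  start <- cumsum(n) - n
  q_at <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    i_lo <- start + lo + 1
    i_hi <- pmin(start + lo + 2, start + pmax(n, 1L))
    vs[i_lo] + (h - lo) * (vs[i_hi] - vs[i_lo])
  }
  q1 <- q_at(0.25)
  q3 <- q_at(0.75)
  iqr <- q3 - q1
  keep_s <- vs >= (q1 - k * iqr)[gs] & vs <= (q3 + k * iqr)[gs]
  keep_s[n[gs] < 3L] <- TRUE
  keep <- logical(length(v))
  keep[o] <- keep_s
  keep
}

#' Summarize replicate features to one intensity per probe, array and channel
#'
#' Masked features are dropped, the Tukey-fence replicate filter is applied
#' per (array, probe, channel), and the arithmetic mean of the survivors is
#' returned. Probes with no surviving replicate on an array are simply absent
#' for that array.
#'
#' @param features a feature table, typically after [mask_features()].
#' @param iqr_multiplier fence width of the replicate filter (default 1.5).
#' @return data.table(array_id, probe_id, channel, mean_signal, n_used).
#' @export
summarize_replicates <- function(features, iqr_multiplier = 1.5) {
  ft <- data.table::as.data.table(features)
  ft <- ft[!ft$masked]
  grp <- NULL # R CMD check NSE note
  ft[, "grp" := .GRP, by = c("array_id", "probe_id")]
  n_groups <- max(ft$grp)
  key <- ft[!duplicated(ft$grp), c("grp", "array_id", "probe_id"),
            with = FALSE]
  data.table::setorderv(key, "grp")
  one_channel <- function(col, channel) {
    keep <- tukey_keep_grouped(ft[[col]], ft$grp, n_groups,
                               k = iqr_multiplier)
    s <- rowsum(ft[[col]][keep], ft$grp[keep])
    n <- tabulate(ft$grp[keep], n_groups)
    present <- n > 0L
    idx <- as.integer(rownames(s))
    data.table::data.table(
      array_id = key$array_id[idx], probe_id = key$probe_id[idx],
      channel = channel, mean_signal = as.numeric(s) / n[idx],
      n_used = n[idx]
    )
  }
  out <- data.table::rbindlist(list(one_channel("signal_green", "green"),
                                    one_channel("signal_red", "red")))
  data.table::setorderv(out, c("array_id", "probe_id", "channel"))
  out[]
}

#' Per-probe array coverage of a summarized intensity table
#'
#' @param summarized output of [summarize_replicates()].
#' @return data.frame(probe_id, n_arrays) counting arrays on which the probe
#'   survived QC (in both channels).
#' @export
probe_coverage <- function(summarized) {
  dt <- data.table::as.data.table(summarized)
  wide <- data.table::dcast(dt, array_id + probe_id ~ channel,
                            value.var = "n_used")
  ok <- !is.na(wide$green) & !is.na(wide$red)
  tab <- table(wide$probe_id[ok])
  data.frame(probe_id = names(tab), n_arrays = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
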