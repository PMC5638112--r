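# TSV readers/writers for the pipeline's on-disk artifacts. All writes are
# atomic (temp file in the target directory, then rename) so an interrupted
# stage never leaves a half-written table.

write_tsv_atomic <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  data.table::fwrite(x, tmp, sep = "\t", quote = FALSE)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path))
    stop("missing input file: ", path, call. = FALSE)
  data.table::fread(path, sep = "\t")
}

#' Write a feature table in the feature-extraction-style TSV dialect
#'
#' Columns: array_id, probe_id, replicate, row, col, gMedianSignal,
#' rMedianSignal, masked.
#'
#' @param features internal feature table.
#' @param path output TSV path.
#' @export
write_feature_table <- function(features, path) {
  out <- data.table::as.data.table(features)
  data.table::setnames(out, c("signal_green", "signal_red"),
                       c("gMedianSignal", "rMedianSignal"))
  write_tsv_atomic(out, path)
}

#' Read a feature-extraction-style TSV into the internal feature table
#'
#' @param path TSV written by [write_feature_table()] (or an export with the
#'   same columns).
#' @return feature table (data.table).
#' @export
read_feature_table <- function(path) {
  ft <- read_tsv(path)
  need <- c("array_id", "probe_id", "replicate", "row", "col",
            "gMedianSignal", "rMedianSignal")
  miss <- setdiff(need, names(ft))
  if (length(miss))
    stop("feature table ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.table::setnames(ft, c("gMedianSignal", "rMedianSignal"),
                       c("signal_green", "signal_red"))
  if (is.null(ft$masked)) ft$masked <- FALSE
  if (any(ft$signal_green < 0) || any(ft$signal_red < 0))
    stop("feature intensities must be non-negative", call. = FALSE)
  ft
}

#' Write/read a count matrix with its totals sidecar
#'
#' The count TSV has element_id rows and one column per individual; totals
#' live in `<path>.totals.tsv` (sample_id, total_reads).
#'
#' @param cm a [count_matrix()].
#' @param path output TSV path.
#' @export
write_count_matrix <- function(cm, path) {
  dt <- data.table::as.data.table(cm$counts, keep.rownames = "element_id")
  write_tsv_atomic(dt, path)
  write_tsv_atomic(
    data.frame(sample_id = names(cm$totals), total_reads = unname(cm$totals)),
    paste0(path, ".totals.tsv"))
  if (!is.null(cm$annotation))
    write_tsv_atomic(cm$annotation, paste0(path, ".annotation.tsv"))
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  dt <- read_tsv(path)
  counts <- as.matrix(dt[, -1])
  rownames(counts) <- dt[[1]]
  tot <- read_tsv(paste0(path, ".totals.tsv"))
  ann_path <- paste0(path, ".annotation.tsv")
  ann <- if (file.exists(ann_path)) as.data.frame(read_tsv(ann_path)) else NULL
  count_matrix(counts, stats::setNames(tot$total_reads, tot$sample_id), ann)
}

#' Write/read a normalized probes x samples matrix
#'
#' First column `probe_id`, one column per sample; missing cells empty.
#'
#' @param mat a `normalized_matrix`.
#' @param path output TSV path.
#' @export
write_normalized_matrix <- function(mat, path) {
  dt <- data.table::as.data.table(unclass(mat), keep.rownames = "probe_id")
  write_tsv_atomic(dt, path)
}

#' @rdname write_normalized_matrix
#' @export
read_normalized_matrix <- function(path) {
  dt <- read_tsv(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
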