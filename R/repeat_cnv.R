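#' Count matrix of mapped reads over a repeat library
#'
#' @param counts elements x individuals integer matrix with dimnames.
#' @param totals named per-individual total read counts (names matching
#'   columns).
#' @param annotation optional element annotation data.frame (element_id,
#'   te_class, te_order, length, complete).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, totals, annotation = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || is.null(rownames(counts)))
    stop("counts must have element and individual dimnames", call. = FALSE)
  totals <- totals[colnames(counts)]
  if (anyNA(totals))
    stop("every individual needs a declared total read count", call. = FALSE)
  if (any(totals <= 0))
    stop("input error: total_reads must be > 0", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(counts > rep(totals, each = nrow(counts))))
    stop("counts cannot exceed an individual's total reads", call. = FALSE)
  structure(list(counts = counts, totals = totals, annotation = annotation),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "elements x", ncol(x$counts),
      "individuals; median depth", format(stats::median(x$totals), big.mark = ","),
      "reads\n")
  invisible(x)
}

#' Counts per million mapped reads
#'
#' cpm[i, j] = counts[i, j] / total_reads[j] * 1e6.
#'
#' @param counts a `count_matrix`, or an elements x individuals matrix.
#' @param totals per-individual totals (ignored when `counts` is a
#'   `count_matrix`).
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(counts, totals = NULL) {
  if (inherits(counts, "count_matrix")) {
    totals <- counts$totals
    counts <- counts$counts
  }
  if (is.null(totals)) stop("totals required", call. = FALSE)
  if (any(totals <= 0)) stop("input error: total_reads must be > 0", call. = FALSE)
  sweep(counts, 2, totals, "/") * 1e6
}

#' One-tailed abundance tests for repetitive elements
#'
#' Per element, a one-tailed Wilcoxon rank-sum test of the focal group
#' against the combined background on CPM values, BH-adjusted across
#' elements; candidates are significant at `alpha`. The symmetric decrease
#' test is run with the opposite tail.
#'
#' @param cpm_mat elements x individuals CPM matrix (see [cpm()]).
#' @param design a [group_design()].
#' @param alpha significance level on adjusted values (default 0.05).
#' @return list(increase, decrease) of data.frames (element_id, p, q,
#'   candidate), plus vectors `increase_candidates`/`decrease_candidates`.
#' @export
test_element_increase <- function(cpm_mat, design, alpha = 0.05) {
  fi <- match(design$focal, colnames(cpm_mat))
  bi <- match(design$background, colnames(cpm_mat))
  one <- function(alt) {
    res <- row_wilcoxon(cpm_mat, fi, bi, alternative = alt)
    q <- bh_fdr(res$p_value)
    data.frame(element_id = rownames(cpm_mat), p = res$p_value, q = q,
               candidate = !is.na(q) & q < alpha,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  inc <- one("greater")
  dec <- one("less")
  list(increase = inc, decrease = dec,
       increase_candidates = inc$element_id[inc$candidate],
       decrease_candidates = dec$element_id[dec$candidate])
}

#' Parental-bias decomposition of candidate elements
#'
#' Within the candidate set only, tests each element in both one-tailed
#' directions between the two parental groups, BH-correcting within the
#' candidate set, and counts elements significantly higher in parent B and
#' in parent A.
#'
#' @param cpm_mat elements x individuals CPM matrix.
#' @param candidates element ids (e.g. increase candidates).
#' @param parentA,parentB sample id vectors of the two parental groups.
#' @param alpha significance level on adjusted values.
#' @return list(n_higher_in_B, n_higher_in_A, pct_higher_in_B,
#'   pct_higher_in_A, table).
#' @export
parental_bias <- function(cpm_mat, candidates, parentA, parentB,
                          alpha = 0.05) {
  sub <- cpm_mat[rownames(cpm_mat) %in% candidates, , drop = FALSE]
  ai <- match(parentA, colnames(sub))
  bi <- match(parentB, colnames(sub))
  if (nrow(sub) == 0L)
    return(list(n_higher_in_B = 0L, n_higher_in_A = 0L,
                pct_higher_in_B = 0, pct_higher_in_A = 0,
                table = data.frame()))
  qB <- bh_fdr(row_wilcoxon(sub, bi, ai, alternative = "greater")$p_value)
  qA <- bh_fdr(row_wilcoxon(sub, ai, bi, alternative = "greater")$p_value)
  higher_B <- !is.na(qB) & qB < alpha
  higher_A <- !is.na(qA) & qA < alpha
  n <- nrow(sub)
  list(
    n_higher_in_B = sum(higher_B), n_higher_in_A = sum(higher_A),
    pct_higher_in_B = round_half_up(100 * sum(higher_B) / n, 1),
    pct_higher_in_A = round_half_up(100 * sum(higher_A) / n, 1),
    table = data.frame(element_id = rownames(sub), q_higher_B = qB,
                       q_higher_A = qA, higher_in_B = higher_B,
                       higher_in_A = higher_A, stringsAsFactors = FALSE,
                       row.names = NULL)
  )
}

#' Mean relative CPM increase of candidate elements
#'
#' Per candidate: 100 * (mean focal CPM - mean parental CPM) / mean parental
#' CPM; the unweighted average over candidates is returned. Candidates with
#' parental mean 0 are excluded from the average and counted.
#'
#' @param cpm_mat elements x individuals CPM matrix.
#' @param candidates candidate element ids.
#' @param design a [group_design()] (focal vs combined parents).
#' @return list(mean_percent, per_element, n_excluded_zero_parental).
#' @export
mean_relative_increase <- function(cpm_mat, candidates, design) {
  sub <- cpm_mat[rownames(cpm_mat) %in% candidates, , drop = FALSE]
  fi <- match(design$focal, colnames(sub))
  bi <- match(design$background, colnames(sub))
  mf <- rowMeans(sub[, fi, drop = FALSE], na.rm = TRUE)
  mp <- rowMeans(sub[, bi, drop = FALSE], na.rm = TRUE)
  ok <- mp > 0
  rel <- 100 * (mf[ok] - mp[ok]) / mp[ok]
  list(mean_percent = if (length(rel)) mean(rel) else NA_real_,
       per_element = data.frame(element_id = rownames(sub)[ok],
                                percent_increase = rel,
                                stringsAsFactors = FALSE, row.names = NULL),
       n_excluded_zero_parental = sum(!ok))
}

# Half-up decimal rounding (printed percentages follow the convention of
# rounding .x5 away from zero, unlike R's round-half-even).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with half-up rounding to one decimal
#'
#' @param part,whole counts.
#' @return percentage; 0 when whole is 0.
#' @export
report_percent <- function(part, whole) {
  if (whole == 0) return(0)
  round_half_up(100 * part / whole, 1)
}

#' Class/order composition of a repeat library and its candidate set
#'
#' Counts and percentages per TE class and per order, for the full library
#' and for the candidate set, with the candidate fraction per class.
#' Percentages are rounded half-up to one decimal.
#'
#' @param elements annotation data.frame(element_id, te_class, te_order, ...).
#' @param candidates candidate element ids.
#' @return list of data.frames `by_class`, `by_order`, plus scalars
#'   `n_candidates`, `n_classified_candidates`, `pct_classified_candidates`.
#' @export
classification_summary <- function(elements, candidates) {
  is_cand <- elements$element_id %in% candidates
  n_cand <- sum(is_cand)
  one_level <- function(var) {
    lv <- sort(unique(elements[[var]]))
    lib_n <- vapply(lv, function(l) sum(elements[[var]] == l), integer(1))
    cand_n <- vapply(lv, function(l) sum(is_cand & elements[[var]] == l),
                     integer(1))
    data.frame(
      level = lv, n_library = lib_n,
      pct_library = vapply(lib_n, report_percent, numeric(1),
                           whole = nrow(elements)),
      n_candidates = cand_n,
      pct_of_candidates = vapply(cand_n, report_percent, numeric(1),
                                 whole = n_cand),
      pct_increased_within = mapply(report_percent, cand_n, lib_n),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  classified <- elements$te_class %in% c("I", "II", "host_gene")
  n_class_cand <- sum(is_cand & classified)
  list(by_class = one_level("te_class"), by_order = one_level("te_order"),
       n_candidates = n_cand, n_classified_candidates = n_class_cand,
       pct_classified_candidates = report_percent(n_class_cand, n_cand))
}

#' Per-element share of CPM across individuals (heatmap export)
#'
#' For each element, each individual's percentage of the element's total CPM
#' across all individuals -- the colour scale of the abundance heatmap.
#'
#' @param cpm_mat elements x individuals CPM matrix.
#' @return matrix of percentages, rows summing to 100 (0 rows stay 0).
#' @export
cpm_share_table <- function(cpm_mat) {
  rs <- rowSums(cpm_mat, na.rm = TRUE)
  out <- sweep(cpm_mat, 1, ifelse(rs > 0, rs, 1), "/") * 100
  out[rs == 0, ] <- 0
  out
}
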