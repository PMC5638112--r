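cm_fixture <- function() {
  counts <- matrix(c(0, 500, 100, 200, 40, 80), nrow = 3, byrow = TRUE,
                   dimnames = list(c("e1", "e2", "e3"), c("s1", "s2")))
  count_matrix(counts, c(s1 = 2e6, s2 = 2e6))
}

test_that("CPM arithmetic and scale invariance", {
  cpm_mat <- cpm(cm_fixture())
  expect_equal(cpm_mat["e1", ], c(s1 = 0, s2 = 250))
  expect_equal(cpm_mat["e2", "s1"], 50)
  # doubling one individual's counts and total leaves its CPM unchanged
  counts <- cm_fixture()$counts
  counts[, "s1"] <- counts[, "s1"] * 2
  cm2 <- count_matrix(counts, c(s1 = 4e6, s2 = 2e6))
  expect_equal(cpm(cm2), cpm_mat)
  expect_error(cpm(counts, c(s1 = 0, s2 = 1)), "total_reads")
  expect_error(count_matrix(counts, c(s1 = 10, s2 = 2e6)), "total reads")
})

rep_cohort <- function(seed = 1, ...) {
  sc <- small_config(seed = seed, n_elements = 300, ...)
  samp <- simulate_samples(sc, c(parentA = 13, parentB = 7, admixed = 10))
  rs <- simulate_repeat_counts(sc, samp)
  list(sc = sc, samp = samp, rs = rs, cpm = cpm(rs$counts),
       des = group_design(samp, "admixed", c("parentA", "parentB")))
}

test_that("depth renormalization leaves tests and candidate sets unchanged", {
  co <- rep_cohort()
  t1 <- test_element_increase(co$cpm, co$des)
  counts <- co$rs$counts$counts
  totals <- co$rs$counts$totals
  counts[, 3] <- counts[, 3] * 5
  totals[3] <- totals[3] * 5
  t2 <- test_element_increase(cpm(count_matrix(counts, totals)), co$des)
  expect_equal(t1$increase$p, t2$increase$p)
  expect_identical(t1$increase_candidates, t2$increase_candidates)
})

test_that("increase and decrease candidate sets are disjoint; null is empty", {
  co <- rep_cohort()
  tt <- test_element_increase(co$cpm, co$des)
  expect_length(intersect(tt$increase_candidates, tt$decrease_candidates), 0)

  co0 <- rep_cohort(seed = 8, element_effect_fraction = 0,
                    element_decrease_fraction = 0,
                    element_parentB_high_fraction = 0,
                    element_parentA_high_fraction = 0)
  t0 <- test_element_increase(co0$cpm, co0$des)
  expect_length(t0$increase_candidates, 0)
  expect_length(t0$decrease_candidates, 0)
})

test_that("parental bias counts biased elements within candidates only", {
  set.seed(51)
  n <- 40
  base <- matrix(stats::rlnorm(n * 20, 5, 0.05), n)
  colnames(base) <- c(sprintf("A%02d", 1:13), sprintf("B%02d", 1:7))
  rownames(base) <- sprintf("e%02d", 1:n)
  base[1:10, 14:20] <- base[1:10, 14:20] * 3  # strongly B-high
  pb <- parental_bias(base, rownames(base)[1:20],
                      sprintf("A%02d", 1:13), sprintf("B%02d", 1:7))
  expect_equal(pb$n_higher_in_B, 10)
  expect_equal(pb$n_higher_in_A, 0)
  expect_equal(pb$pct_higher_in_B, 50)
  expect_lte(pb$n_higher_in_A + pb$n_higher_in_B, 20)
  # identical parental distributions: counted in neither
  pb0 <- parental_bias(base[11:20, , drop = FALSE], rownames(base)[11:20],
                       sprintf("A%02d", 1:13), sprintf("B%02d", 1:7))
  expect_equal(pb0$n_higher_in_B + pb0$n_higher_in_A, 0)
})

test_that("mean relative increase follows the parental-mean convention", {
  cpm_mat <- matrix(c(13, 13, 10, 10,
                      5, 5, 5, 5,
                      7, 7, 0, 0), nrow = 3, byrow = TRUE,
                    dimnames = list(c("e1", "e2", "e3"),
                                    c("adm1", "adm2", "par1", "par2")))
  des <- group_design(data.frame(sample_id = colnames(cpm_mat),
                                 group = c("admixed", "admixed",
                                           "parentA", "parentB")),
                      "admixed", c("parentA", "parentB"))
  mri <- mean_relative_increase(cpm_mat, c("e1", "e2", "e3"), des)
  expect_equal(mri$mean_percent, mean(c(30, 0)))  # e3 excluded: parental 0
  expect_equal(mri$n_excluded_zero_parental, 1)
})

test_that("classification summary reproduces printed-percentage arithmetic", {
  expect_equal(report_percent(86, 208), 41.3)
  expect_equal(report_percent(76, 312), 24.4)
  expect_equal(report_percent(122, 553), 22.1)
  expect_equal(report_percent(0, 0), 0)
  # half-up rounding, not half-even
  expect_equal(report_percent(1, 8), 12.5)
  expect_equal(report_percent(25, 1000), 2.5)
  expect_equal(hybridCNV:::round_half_up(0.25, 1), 0.3)

  ann <- data.frame(
    element_id = sprintf("e%03d", 1:100),
    te_class = rep(c("I", "II", "unclassified", "host_gene"),
                   c(40, 20, 35, 5)),
    te_order = "undetermined", stringsAsFactors = FALSE)
  cs <- classification_summary(ann, sprintf("e%03d", 1:50))
  expect_equal(cs$n_candidates, 50)
  expect_equal(cs$n_classified_candidates, 50)  # e001-e050 all I/II
  expect_equal(cs$pct_classified_candidates, 100)
  bc <- cs$by_class
  expect_equal(bc$n_candidates[bc$level == "I"], 40)
  expect_equal(bc$pct_of_candidates[bc$level == "I"], 80)
  # empty candidate set: zero percentages, no division error
  cs0 <- classification_summary(ann, character())
  expect_equal(cs0$pct_classified_candidates, 0)
  expect_true(all(cs0$by_class$pct_of_candidates == 0))
})

test_that("CPM share table rows sum to 100", {
  co <- rep_cohort()
  sh <- cpm_share_table(co$cpm)
  nonzero <- rowSums(co$cpm) > 0
  expect_equal(unname(rowSums(sh)[nonzero]),
               rep(100, sum(nonzero)), tolerance = 1e-9)
})
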