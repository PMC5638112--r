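levels8 <- c(25, 50, 100, 200, 400, 800, 1200, 1600)

test_that("noiseless linear response is recovered exactly", {
  f <- fit_probe_response(levels8, 2 + 0.01 * levels8)
  expect_equal(f$slope, 0.01)
  expect_equal(f$intercept, 2)
  expect_equal(f$r_squared, 1)
  expect_true(is.infinite(f$signal_to_error))
  expect_equal(f$status, "pass")
})

test_that("flat and saturating responses are flagged", {
  fc <- fit_probe_response(levels8, rep(50, 8))
  expect_equal(fc$slope, 0)
  expect_equal(fc$status, "unresponsive")

  sat <- 2 + 0.05 * (150 * levels8 / (150 + levels8))
  fs <- fit_probe_response(levels8, sat)
  expect_lt(fs$r_squared, 0.95)
  expect_equal(fs$status, "nonlinear")

  expect_error(fit_probe_response(c(25, 50), c(1, 2)), "input error")
})

test_that("QC thresholds act at their boundaries", {
  mk <- function(r2, ser, p = 1e-6) {
    data.frame(probe_id = rep("p1", 2), channel = c("green", "red"),
               slope = 1, intercept = 0, r_squared = r2,
               signal_to_error = ser, p_slope = p, slope_score = 1,
               status = ifelse(p >= 0.05, "unresponsive",
                        ifelse(r2 < 0.95, "nonlinear",
                        ifelse(ser < 10, "low_ser", "pass"))),
               stringsAsFactors = FALSE)
  }
  expect_length(filter_probes(mk(0.94, 50))$pass, 0)     # nonlinear
  expect_length(filter_probes(mk(0.99, 9.9))$pass, 0)    # low SER
  expect_equal(filter_probes(mk(0.99, 50))$pass, "p1")   # retained
  fail <- filter_probes(mk(0.94, 50))$failure_counts
  expect_equal(unname(fail["nonlinear"]), 1L)
  # one channel failing is enough to exclude the probe
  mixed <- rbind(mk(0.99, 50)[1, ], mk(0.9, 50)[2, ])
  expect_length(filter_probes(mixed)$pass, 0)
})

test_that("probe selection minimizes |log-log slope - 1| with id tie-break", {
  fits <- data.frame(
    probe_id = rep(c("g1_p1", "g1_p2", "g1_p3"), each = 2),
    channel = rep(c("green", "red"), 3),
    slope = 1, intercept = 0, r_squared = 1, signal_to_error = 100,
    p_slope = 0, slope_score = rep(c(0.8, 1.05, 1.3), each = 2),
    status = "pass", stringsAsFactors = FALSE)
  pg <- data.frame(probe_id = unique(fits$probe_id), gene_id = "g1")
  expect_equal(select_probe_per_gene(fits, pg)$probe_id, "g1_p2")

  fits$slope_score <- rep(c(0.9, 1.1, 5), each = 2)
  expect_equal(select_probe_per_gene(fits, pg)$probe_id, "g1_p1")

  solo <- fits[fits$probe_id == "g1_p3", ]
  expect_equal(select_probe_per_gene(solo, pg)$probe_id, "g1_p3")
})

test_that("DNAcal back-transformation and clamping behave as specified", {
  fit <- list(slope = 4, intercept = 2, status = "pass")
  expect_equal(apply_calibration(10, fit), 2)
  expect_equal(apply_calibration(2, fit), 0)  # raw zero; clamping is bulk-side
  expect_equal(apply_calibration(7, list(slope = 1, intercept = 0,
                                         status = "pass")), 7)
  expect_error(apply_calibration(10, list(slope = -1, intercept = 0,
                                          status = "pass")), "calibration")
  expect_error(apply_calibration(10, list(slope = 1, intercept = 0,
                                          status = "low_ser")), "calibration")

  summ <- data.frame(array_id = "a1", probe_id = c("p1", "p2"),
                     channel = "green", mean_signal = c(2, 10),
                     n_used = 2L, stringsAsFactors = FALSE)
  fits <- data.frame(probe_id = rep(c("p1", "p2"), each = 2),
                     channel = rep(c("green", "red"), 2),
                     slope = 4, intercept = 2, r_squared = 1,
                     signal_to_error = 100, p_slope = 0, slope_score = 1,
                     status = "pass", stringsAsFactors = FALSE)
  out <- calibrate_intensities(summ, fits)
  expect_true(out$clamped[out$probe_id == "p1"])
  expect_equal(out$dna_cal[out$probe_id == "p1"], 1)  # half of smallest positive
  expect_equal(out$dna_cal[out$probe_id == "p2"], 2)
})

test_that("calibration recovers generative parameters on noiseless arrays", {
  sc <- noiseless_config(n_genes = 80)
  cal <- simulate_calibration_arrays(sc)
  fits <- calibrate_probes(summarize_replicates(cal$features),
                           sc$dilution_levels_ng)
  pp <- cal$truth$probe_params
  g <- fits[fits$channel == "green", ]
  i <- match(g$probe_id, pp$probe_id)
  expect_equal(g$slope, pp$slope_green[i], tolerance = 1e-10)
  expect_equal(g$intercept, pp$intercept_green[i], tolerance = 1e-9)
  expect_true(all(g$status == "pass"))

  # round-trip identity through DNAcal
  summ <- summarize_replicates(cal$features)
  calq <- calibrate_intensities(summ, fits)
  lev <- stats::setNames(sc$dilution_levels_ng,
                         sprintf("cal_L%02d", seq_along(sc$dilution_levels_ng)))
  expect_equal(calq$dna_cal, unname(lev[calq$array_id]), tolerance = 1e-9)
})

test_that("QC separates constructed defects perfectly", {
  sc <- noiseless_config(n_genes = 100, fraction_nonlinear = 0.1,
                         fraction_unresponsive = 0.1)
  cal <- simulate_calibration_arrays(sc)
  fits <- calibrate_probes(summarize_replicates(cal$features),
                           sc$dilution_levels_ng)
  pp <- cal$truth$probe_params
  pass <- filter_probes(fits)$pass
  expect_setequal(pass, pp$probe_id[pp$defect == "none"])
})

test_that("slope recovery error shrinks as noise shrinks", {
  errs <- vapply(c(20, 5, 0.5), function(sd) {
    sc <- noiseless_config(seed = 42, n_genes = 60, noise_sd = sd)
    cal <- simulate_calibration_arrays(sc)
    fits <- calibrate_probes(summarize_replicates(cal$features),
                             sc$dilution_levels_ng)
    pp <- cal$truth$probe_params
    g <- fits[fits$channel == "green", ]
    mean(abs(g$slope - pp$slope_green[match(g$probe_id, pp$probe_id)]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("bulk row-wise fits equal the scalar fit", {
  set.seed(9)
  Y <- matrix(stats::rnorm(5 * 8, 100, 10), 5)
  for (i in 1:5) {
    f1 <- fit_probe_response(levels8, Y[i, ])
    fv <- hybridCNV:::fit_response_vec(Y[i, , drop = FALSE], levels8)
    expect_equal(f1$slope, fv$slope[1])
    expect_equal(f1$r_squared, fv$r_squared[1])
    expect_equal(f1$signal_to_error, fv$signal_to_error[1])
  }
})
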