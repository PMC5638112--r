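square <- data.frame(array_id = "a1", vertex_index = 1:4,
                     row = c(2, 2, 6, 6), col = c(2, 6, 6, 2))

feat <- function(rows, cols, array = "a1") {
  data.frame(array_id = array, probe_id = sprintf("p%02d", seq_along(rows)),
             replicate = 1L, row = rows, col = cols,
             signal_green = 10, signal_red = 10, masked = FALSE,
             stringsAsFactors = FALSE)
}

test_that("point-in-polygon is boundary-inclusive and array-scoped", {
  ft <- feat(rows = c(4, 10, 2, 6, 4), cols = c(4, 10, 4, 6, 2))
  out <- mask_features(ft, square)
  # inside, outside, on edge, on vertex, on edge
  expect_equal(out$masked, c(TRUE, FALSE, TRUE, TRUE, TRUE))

  # same coordinates on another array stay untouched
  ft2 <- feat(rows = 4, cols = 4, array = "a2")
  expect_false(mask_features(ft2, square)$masked)
})

test_that("masking is idempotent and rejects degenerate polygons", {
  ft <- feat(rows = c(4, 10), cols = c(4, 10))
  once <- mask_features(ft, square)
  twice <- mask_features(once, square)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  bad <- square[1:2, ]
  expect_error(mask_features(ft, bad), "geometry")
  expect_error(points_in_polygon(1, 1, c(0, 1), c(0, 1)), "geometry")
})

test_that("ray casting agrees with a winding-number oracle on random polygons", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    r <- stats::runif(k, 2, 10)
    vx <- 12 + r * cos(ang)  # star-shaped => simple
    vy <- 12 + r * sin(ang)
    px <- stats::runif(200, 0, 24)
    py <- stats::runif(200, 0, 24)
    expect_equal(points_in_polygon(px, py, vx, vy),
                 winding_number_inside(px, py, vx, vy))
  }
})

test_that("replicate outlier filter applies type-7 Tukey fences", {
  expect_equal(filter_replicate_outliers(c(10, 10, 10, 10, 100)),
               c(10, 10, 10, 10))
  expect_equal(filter_replicate_outliers(rep(5, 5)), rep(5, 5))
  expect_equal(filter_replicate_outliers(c(8, 12)), c(8, 12))  # n < 3 guard
  expect_equal(filter_replicate_outliers(numeric(0)), numeric(0))
  # generic agreement with a direct quantile computation
  set.seed(3)
  for (i in 1:50) {
    v <- round(stats::rlnorm(sample(3:9, 1), 3, 1))
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
    expect_equal(filter_replicate_outliers(v), v[v >= lo & v <= hi])
  }
})

test_that("grouped fence filter matches the scalar filter group by group", {
  set.seed(4)
  g <- rep(1:500, times = sample(1:8, 500, replace = TRUE))
  v <- stats::rlnorm(length(g), 5, 1)
  keep <- hybridCNV:::tukey_keep_grouped(v, g, 500)
  for (gg in sample(500, 50)) {
    sel <- g == gg
    expect_equal(v[sel][keep[sel]], filter_replicate_outliers(v[sel]))
  }
})

test_that("replicate summarization averages survivors per array/probe/channel", {
  ft <- rbind(feat(rows = 1:2, cols = 1:2), feat(rows = 3:4, cols = 3:4))
  ft$probe_id <- c("p1", "p2", "p1", "p2")
  ft$replicate <- c(1L, 1L, 2L, 2L)
  ft$signal_green <- c(4, 7, 6, 9)
  ft$signal_red <- c(10, 20, 30, 40)
  s <- summarize_replicates(ft)
  expect_equal(s$mean_signal[s$probe_id == "p1" & s$channel == "green"], 5)
  expect_equal(s$n_used[s$probe_id == "p1" & s$channel == "green"], 2L)
  expect_equal(s$mean_signal[s$probe_id == "p2" & s$channel == "red"], 30)

  # order invariance
  s2 <- summarize_replicates(ft[sample(nrow(ft)), ])
  expect_equal(as.data.frame(s), as.data.frame(s2))

  # a fully masked probe on one array is absent there, present elsewhere
  ft$masked[ft$probe_id == "p1"] <- TRUE
  s3 <- summarize_replicates(ft)
  expect_false("p1" %in% s3$probe_id)
})

test_that("masked feature set equals geometric truth on simulated arrays", {
  sc <- small_config(n_genes = 300)
  samples <- simulate_samples(sc)
  truth <- simulate_gene_truth(sc)
  expt <- simulate_experiment_arrays(sc, samples, truth)
  masked <- mask_features(expt, attr(expt, "bubble_polygons"))
  expect_equal(masked$masked, attr(expt, "feature_truth")$in_bubble)
  expect_gt(sum(masked$masked), 0)
})

test_that("probe coverage counts arrays with both channels present", {
  sc <- small_config()
  res <- acgh_pipeline(sc)
  cov <- probe_coverage(summarize_replicates(
    mask_features(simulate_experiment_arrays(sc, res$samples, res$truth),
                  data.frame(array_id = character(), vertex_index = integer(),
                             row = numeric(), col = numeric()))))
  expect_true(all(cov$n_arrays <= nrow(res$samples)))
  expect_true(all(cov$n_arrays >= 1))
})
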