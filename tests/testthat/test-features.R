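test_that("mutual information matches the plug-in definition and closed forms", {
  # perfectly separable at balanced prior: exactly H(C) = 1 bit
  expect_identical(mutual_information(500, 0, 500, 500, 0.5), 1)
  # same at the search prior: H(C) for p = 0.1
  h01 <- -(0.1 * log2(0.1) + 0.9 * log2(0.9))
  expect_equal(mutual_information(500, 0, 500, 500, 0.1), h01,
               tolerance = 1e-12)
  expect_equal(h01, 0.469, tolerance = 1e-3)
  # equal detection rates carry no information
  expect_equal(mutual_information(250, 250, 500, 500, 0.5), 0)
  set.seed(1)
  for (i in 1:200) {
    nw <- sample(2:400, 1); no <- sample(2:400, 1)
    n11 <- sample(0:nw, 1); n01 <- sample(0:no, 1)
    prior <- runif(1, 0.05, 0.95)
    expect_lt(abs(mutual_information(n11, n01, nw, no, prior) -
                    oracle_mi(n11, n01, nw, no, prior)), 1e-12)
  }
  expect_error(mutual_information(0, 0, 0, 10, 0.5), "zero-size")
})

test_that("feature responses attain the NCC bounds and match a naive lag loop", {
  set.seed(2)
  rates <- matrix(abs(rnorm(8 * 120)), 8, 120)
  map <- rates_map(rates)
  patch <- rates[3:6, 41:60]
  f <- patch_feature(patch, ch_lo = 3)
  r <- feature_response(f, map)
  expect_equal(r$max_ncc, 1, tolerance = 1e-12)
  expect_equal(r$best_lag_ms, 40)
  # sign-flip about the mean is perfectly anti-correlated
  flipped <- rates_map(2 * mean(patch) - patch)
  expect_equal(feature_response(patch_feature(patch), flipped)$max_ncc, -1,
               tolerance = 1e-12)
  # naive per-lag oracle
  for (i in 1:20) {
    fm <- matrix(rnorm(5 * 12), 5, 12)
    bm <- matrix(rnorm(5 * 100), 5, 100)
    expect_equal(as.numeric(mifcat:::ncc_trace_cpp(fm, bm)),
                 oracle_ncc_trace(fm, bm), tolerance = 1e-10)
  }
  # shorter map errors unless floored
  short <- rates_map(rates[, 1:10, drop = FALSE])
  expect_error(feature_response(f, short), "shorter")
  expect_equal(feature_response(f, short, short = "floor")$max_ncc, -1)
})

test_that("threshold optimization maximizes information with rank-based grid", {
  tk <- task_spec("x", prior_threshold = 0.5, prior_report = 0.5)
  # separable case: merit exactly 1 bit, threshold in the gap
  opt <- optimize_threshold(rep(0.9, 50), rep(0.2, 50), tk)
  expect_equal(opt$merit, 1)
  expect_true(opt$threshold > 0.2 && opt$threshold <= 0.9)
  # identical response distributions: merit bounded by plug-in bias
  set.seed(3)
  r <- runif(1000)
  opt2 <- optimize_threshold(r[1:500], r[501:1000], tk)
  expect_lt(opt2$merit, 0.02)
  # exhaustive-grid oracle equivalence
  for (i in 1:10) {
    rw <- round(runif(30), 2); ro <- round(runif(40), 2)
    pooled <- sort(unique(c(rw, ro)))
    grid <- c(pooled[-length(pooled)] + diff(pooled) / 2, max(pooled) + 1)
    mi <- vapply(grid, function(th)
      oracle_mi(sum(rw >= th), sum(ro >= th), 30, 40, 0.5), numeric(1))
    opt3 <- optimize_threshold(rw, ro, tk)
    expect_equal(opt3$merit, max(mi), tolerance = 1e-12)
  }
  # merit invariant to strictly monotone response transforms
  rw <- rnorm(40); ro <- rnorm(40) + 0.5
  expect_equal(optimize_threshold(rw, ro, tk)$merit,
               optimize_threshold(exp(rw), exp(ro), tk)$merit,
               tolerance = 1e-12)
  # degenerate: all responses identical
  deg <- optimize_threshold(rep(0.4, 10), rep(0.4, 10), tk)
  expect_true(deg$degenerate)
  expect_equal(deg$merit, 0)
  expect_gt(deg$threshold, 0.4)
})

test_that("log-likelihood weights use add-half smoothing and can be negative", {
  expect_equal(log_likelihood_weight(250, 250, 500, 500), 0)
  expect_equal(log_likelihood_weight(500, 0, 500, 500), log2(1001),
               tolerance = 1e-12)
  expect_equal(log2(1001), 9.97, tolerance = 1e-2)
  expect_equal(log_likelihood_weight(0, 500, 500, 500), -log2(1001),
               tolerance = 1e-12)
})

test_that("feature complexity is reduced kurtosis with a degenerate-zero rule", {
  set.seed(4)
  expect_lt(abs(feature_complexity(matrix(rnorm(10000), 100))), 0.2)
  expect_identical(feature_complexity(matrix(1, 5, 5)), 0)
  sparse <- matrix(0, 20, 50)
  sparse[sample(1000, 50)] <- rexp(50) + 2
  expect_gt(feature_complexity(sparse),
            feature_complexity(matrix(rnorm(1000), 20)) + 3)
})

test_that("random feature sampling honors quotas, bounds, and feasibility", {
  run <- tiny_run()
  within <- run$corpus$call_id[run$corpus$split == "train" &
                                 run$corpus$call_type == "twitter_like"]
  cgs <- run$cg_train[within]
  pool <- sample_random_features(cgs, 90,
                                 quotas = list(list(n = 30,
                                                    max_bandwidth_oct = 1,
                                                    max_length_ms = 100)),
                                 seed = 9)
  expect_equal(nrow(pool), 90)
  small <- pool$bandwidth_oct < 1 & pool$length_ms < 100
  expect_gte(sum(small), 30)
  # rectangles fully inside their sources
  for (i in seq_len(nrow(pool))) {
    src <- cgs[[pool$source_call[i]]]
    expect_lte(pool$ch_hi[i], nrow(src$rates))
    expect_lte((pool$t_on_ms[i] + pool$length_ms[i]) / 1000 * src$frame_rate,
               ncol(src$rates) + 1e-9)
    expect_identical(dim(pool$patch[[i]]),
                     c(pool$ch_hi[i] - pool$ch_lo[i] + 1L,
                       as.integer(round(pool$length_ms[i] / 1000 *
                                          src$frame_rate))))
  }
  # constrained-only pools satisfy both bounds ("large features only")
  big <- sample_random_features(cgs, 20,
                                constraints = list(min_length_ms = 250,
                                                   min_bandwidth_oct = 2),
                                seed = 10)
  expect_true(all(big$length_ms >= 250 & big$bandwidth_oct >= 2))
  expect_identical(pool, sample_random_features(cgs, 90,
    quotas = list(list(n = 30, max_bandwidth_oct = 1, max_length_ms = 100)),
    seed = 9))
  short_src <- list(a = rates_map(matrix(1:40 + 0, 4, 10), frame_rate = 200))
  expect_error(sample_random_features(short_src, 5,
                                      constraints = list(min_length_ms = 100),
                                      seed = 1),
               "length constraint infeasible")
})

test_that("stored detections equal thresholded responses bit-exactly", {
  run <- tiny_run()
  det <- attr(run$mifs$twitter_like, "detections")
  expect_identical(det$detections,
                   sweep(det$responses, 1,
                         attr(run$mifs$twitter_like, "scored_pool")$threshold,
                         `>=`))
})
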