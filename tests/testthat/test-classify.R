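test_that("evidence scores are weight-normalized detection sums", {
  set.seed(51)
  rates <- matrix(abs(rnorm(6 * 80)), 6, 80)
  map <- rates_map(rates)
  f1 <- patch_feature(rates[1:3, 11:20], ch_lo = 1, id = "f1",
                      threshold = 0.99, weight = 2)
  f2 <- patch_feature(rates[2:5, 31:45], ch_lo = 2, id = "f2",
                      threshold = 0.99, weight = 1)
  ms <- toy_mif_set(dplyr::bind_rows(f1, f2))
  # both features present in the map: all detected, score 1
  expect_equal(call_score(ms, map), 1)
  # silence: nothing detected, score 0
  expect_equal(call_score(ms, rates_map(matrix(0, 6, 80))), 0)
  # only f1 present: w1 / (w1 + w2)
  only1 <- rates
  only1[, 25:80] <- 0.5
  expect_equal(call_score(ms, rates_map(only1)), 2 / 3)
})

test_that("ROC curves sweep all scores and AUC equals pair counting", {
  r <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(roc_auc(r), 1)
  expect_equal(r$fa_rate[1], 0); expect_equal(r$hit_rate[1], 0)
  expect_equal(r$fa_rate[nrow(r)], 1); expect_equal(r$hit_rate[nrow(r)], 1)
  expect_true(all(diff(r$fa_rate) >= 0), all(diff(r$hit_rate) >= 0))
  # chance level for identically distributed scores
  set.seed(52)
  s <- runif(4000)
  expect_equal(roc_auc(roc_curve(s[1:2000], s[2001:4000])), 0.5,
               tolerance = 0.05)
  # toy scores with ties: exhaustive pair-count oracle
  w <- c(0.3, 0.5, 0.5, 0.9); o <- c(0.1, 0.5, 0.4, 0.3)
  expect_equal(roc_auc(roc_curve(w, o)), oracle_auc(w, o))
  set.seed(53)
  for (i in 1:10) {
    w <- sample(seq(0, 1, 0.1), 8, TRUE); o <- sample(seq(0, 1, 0.1), 6, TRUE)
    expect_equal(roc_auc(roc_curve(w, o)), oracle_auc(w, o),
                 tolerance = 1e-12)
  }
  # DET points are the miss-rate complement
  d <- det_curve(w, o)
  expect_equal(d$miss_rate, 1 - roc_curve(w, o)$hit_rate)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  w <- rnorm(60, 1); o <- rnorm(80)
  expect_equal(roc_auc(roc_curve(w, o)),
               as.numeric(pROC::auc(pROC::roc(
                 response = rep(c(1, 0), c(60, 80)), predictor = c(w, o),
                 quiet = TRUE, direction = "<"))),
               tolerance = 1e-10)
})

test_that("variant comparison runs pairwise rank-sum tests with Bonferroni", {
  s <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 5, 6))
  out <- compare_variants(s)
  expect_equal(nrow(out), 3)
  # identical sequences: no evidence of difference
  ab <- out[out$variant_a == "a" & out$variant_b == "b", ]
  expect_equal(ab$p_adjusted, 1)
  # Bonferroni with 3 pairs
  expect_equal(out$p_adjusted, pmin(1, out$p_value * 3))
  # statistic equals hand enumeration: all of {1,2,3} below {4,5,6} -> W = 0
  ac <- out[out$variant_a == "a" & out$variant_b == "c", ]
  expect_equal(unname(ac$statistic), 0)
  expect_error(compare_variants(list(a = 1, b = c(1, 2))), "length >= 2")
})

test_that("streaming detection emits refractory-spaced events inside matching calls", {
  run <- tiny_run()
  ms <- run$mifs$twitter_like
  # the MIF's own source call: detected in call mode
  src <- run$cg_train[[ms$features$source_call[1]]]
  det <- detect_mifs(ms, src, "call")
  expect_true(det$detected[1])
  # silence: no events
  sil <- rates_map(matrix(0, run$fp$n_channels, 200), run$fp$frame_rate)
  expect_equal(nrow(detect_mifs(ms, sil, "stream")), 0)
  ev <- detect_mifs(ms, src, "stream", refractory_ms = 2)
  if (nrow(ev) > 1) {
    by_f <- split(ev$time_ms, ev$feature_id)
    for (tms in by_f) if (length(tms) > 1) expect_true(all(diff(tms) >= 2))
  }
})

test_that("evidence traces favor the true category over a call sequence", {
  run <- tiny_run()
  test <- run$corpus[run$corpus$split == "test", ]
  picks <- c(which(test$call_type == "twitter_like")[1:3],
             which(test$call_type == "trill_like")[1:3])
  sr <- attr(run$corpus, "sample_rate")
  gap <- rep(0, round(0.15 * sr))
  seq_wave <- unlist(lapply(picks, function(i)
    c(test$waveform[[i]], gap)))
  rep <- make_representation(seq_wave, sr, run$fp)
  tr <- evidence_trace(run$mifs, rep, bin_ms = 50)
  expect_s3_class(tr, "mif_evidence")
  # bins tile the stimulus
  expect_gte(max(tr$bin_start_ms) + 50,
             ncol(rep$rates) / rep$frame_rate * 1000)
  # no detections -> zero evidence
  expect_true(all(tr$evidence[tr$bin_start_ms == max(tr$bin_start_ms)] == 0))
  # within each call interval the true category accumulates the most evidence
  starts <- cumsum(c(0, head(vapply(picks, function(i)
    length(test$waveform[[i]]) + length(gap), numeric(1)), -1))) / sr * 1000
  durs <- vapply(picks, function(i) length(test$waveform[[i]]), numeric(1)) /
    sr * 1000
  correct <- 0
  for (k in seq_along(picks)) {
    seg <- tr[tr$bin_start_ms >= starts[k] &
                tr$bin_start_ms < starts[k] + durs[k], ]
    tot <- tapply(seg$evidence, seg$category, sum)
    if (names(which.max(tot)) == test$call_type[picks[k]]) {
      correct <- correct + 1
    }
  }
  expect_gte(correct, 5)
})

test_that("cross-task evaluation with matching task reduces to the standard one", {
  run <- tiny_run()
  test <- run$corpus[run$corpus$split == "test", ]
  ev_a <- evaluate_mifs(run$mifs$twitter_like, run$cg_test, test$call_type)
  ev_b <- cross_task_evaluation(run$mifs$twitter_like, run$cg_test,
                                test$call_type, task_spec("twitter_like"))
  expect_equal(ev_a$auc, ev_b$auc)
  expect_equal(ev_a$scores$score, ev_b$scores$score)
})
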