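test_that("the rectified power law has the stated closed-form behavior", {
  expect_equal(firing_rate(0.5, theta = 0.5), 0)
  expect_equal(firing_rate(0.3, theta = 0.5), 0)
  expect_equal(firing_rate(1.0, theta = 0.5, k = 1, p = 4), 0.0625)
  # doubling the suprathreshold drive scales the rate 16-fold at p = 4
  expect_equal(firing_rate(0.7, 0.5) * 16, firing_rate(0.9, 0.5))
  # monotone and continuous at threshold
  v <- seq(0, 1, 0.01)
  fr <- firing_rate(v, theta = 0.4)
  expect_true(all(diff(fr) >= 0))
  expect_lt(firing_rate(0.4 + 1e-8, 0.4), 1e-16)
  expect_error(firing_rate(1, 0.5, k = -1), "k > 0")
})

test_that("the stimulus battery renders every stimulus class to audio", {
  bat <- stimulus_battery(sample_rate = 24000,
                          tone_freqs = c(1000, 4000),
                          sweep_lengths_ms = c(40, 80),
                          train_counts = 1:3, am_rates = c(16, 33))
  expect_true(all(c("tone", "fm_sweep", "sweep_train", "am_tone", "noise",
                    "click", "two_tone") %in% bat$class))
  expect_true(all(vapply(bat$waveform, length, integer(1)) > 0))
  expect_equal(attr(bat, "sample_rate"), 24000)
  # deterministic
  bat2 <- stimulus_battery(sample_rate = 24000,
                           tone_freqs = c(1000, 4000),
                           sweep_lengths_ms = c(40, 80),
                           train_counts = 1:3, am_rates = c(16, 33))
  expect_identical(bat$waveform, bat2$waveform)
})

test_that("multi-phrase templates prefer sweep trains over single sweeps", {
  fp <- tiny_frontend()
  fs <- 48000
  # a two-phrase template cut from a clean phrase train
  tw <- mifcat:::synth_phrase_train(5000, 9000, 0.080, 0.110, 4, fs)
  cg <- make_representation(tw, fs, fp)
  fr2 <- round(0.38 * fp$frame_rate) # two phrases + the gap between
  patch <- cg$rates[8:28, 1:fr2]
  # single sweep vs three-sweep train with the template's own period
  bat <- stimulus_battery(sample_rate = fs, tone_freqs = 1000,
                          sweep_lengths_ms = 80, sweep_octaves = log2(9 / 5),
                          center_freq = sqrt(5000 * 9000),
                          train_counts = c(1, 3), train_isi_ms = 110,
                          am_rates = 16)
  reps <- lapply(bat$waveform, make_representation, sample_rate = fs,
                 params = fp)
  names(reps) <- bat$stimulus_id
  f <- patch_feature(patch, ch_lo = 8)
  v1 <- feature_response(f, reps$train_1x80ms, short = "floor")$max_ncc
  v3 <- feature_response(f, reps$train_3x80ms, short = "floor")$max_ncc
  expect_gt(v3, v1 + 0.1)
  # a threshold between the two turns this into train-selective spiking
  theta <- (v1 + v3) / 2
  expect_equal(firing_rate(v1, theta), 0)
  expect_gt(firing_rate(v3, theta), 0)
  # tuning_curve wires responses through the power law
  f$threshold <- theta
  ms <- toy_mif_set(f)
  tc <- tuning_curve(ms, bat, frontend = fp)
  expect_equal(nrow(tc), nrow(bat))
  expect_equal(tc$fr[tc$stimulus_id == "train_1x80ms"], 0)
  expect_gt(tc$fr[tc$stimulus_id == "train_3x80ms"], 0)
  # the template's own source is the best stimulus in the battery
  own <- feature_response(f, cg)$max_ncc
  expect_gte(own, max(tc$v_m))
})

test_that("model neurons prefer natural over time-reversed phrase trains", {
  run <- tiny_run()
  te <- run$corpus[run$corpus$split == "test" &
                     run$corpus$call_type == "twitter_like", ][1:8, ]
  attr(te, "sample_rate") <- attr(run$corpus, "sample_rate")
  nr <- natural_vs_reversed(run$mifs$twitter_like, te)
  expect_equal(nrow(nr$pairs), 8 * nrow(run$mifs$twitter_like$features))
  expect_true(all(nr$pairs$fr_natural >= 0 & nr$pairs$fr_reversed >= 0))
  expect_gt(nr$fraction_natural, 0.5)
  # a temporally symmetric stimulus is direction-blind
  fs <- attr(run$corpus, "sample_rate")
  tone <- sin(2 * pi * 6000 * seq_len(fs / 4) / fs)
  sym <- tibble::tibble(call_id = "tone", waveform = list(tone))
  attr(sym, "sample_rate") <- fs
  nrs <- natural_vs_reversed(run$mifs$twitter_like, sym)
  expect_equal(nrs$pairs$fr_natural, nrs$pairs$fr_reversed,
               tolerance = 1e-6)
  # joint reversal symmetry of the correlation itself
  set.seed(61)
  rates <- matrix(abs(rnorm(6 * 90)), 6, 90)
  patch <- rates[2:4, 30:50]
  fwd <- feature_response(patch_feature(patch, 2), rates_map(rates))$max_ncc
  bwd <- feature_response(patch_feature(patch[, ncol(patch):1], 2),
                          rates_map(rates[, ncol(rates):1]))$max_ncc
  expect_equal(fwd, bwd, tolerance = 1e-12)
})

test_that("reconstruction recovers a single-feature stimulus and degrades gracefully", {
  set.seed(62)
  rates <- matrix(abs(rnorm(10 * 60)), 10, 60)
  map <- rates_map(rates, frame_rate = 500)
  f <- patch_feature(rates, ch_lo = 1, threshold = 0.95, weight = 2.5)
  ms <- toy_mif_set(f)
  rec <- reconstruct_stimulus(ms, map)
  expect_s3_class(rec, "mif_reconstruction")
  expect_equal(rec$accuracy, 1, tolerance = 1e-6)
  # gain invariance of the accuracy metric
  map3 <- rates_map(rates * 3, frame_rate = 500)
  expect_equal(reconstruct_stimulus(ms, map3)$accuracy, 1, tolerance = 1e-6)
  # silence: no events, accuracy defined as 0
  sil <- rates_map(matrix(0, 10, 60), frame_rate = 500)
  rec0 <- reconstruct_stimulus(ms, sil)
  expect_equal(rec0$n_events, 0)
  expect_equal(rec0$accuracy, 0)
  # placements at the detected times beat shuffled placements
  run <- tiny_run()
  m <- run$mifs$twitter_like
  src <- run$cg_train[[m$features$source_call[1]]]
  rec_true <- reconstruct_stimulus(m, src)
  expect_gt(rec_true$accuracy, 0)
  shuf <- m
  set.seed(63)
  nfr <- ncol(src$rates)
  recon <- matrix(0, nrow(src$rates), nfr)
  for (i in seq_len(nrow(m$features))) {
    L <- ncol(m$features$patch[[i]])
    if (L >= nfr) next
    t0 <- sample.int(nfr - L, 1)
    rows <- m$features$ch_lo[i]:m$features$ch_hi[i]
    recon[rows, t0:(t0 + L - 1)] <- recon[rows, t0:(t0 + L - 1)] +
      m$features$patch[[i]] * m$features$weight[i]
  }
  acc_shuf <- mifcat:::zero_lag_ncc(src$rates, recon)
  expect_gt(rec_true$accuracy, acc_shuf)
})

test_that("battery responses of trained MIF neurons are sparse and tone-silent", {
  run <- tiny_run()
  bat <- stimulus_battery(sample_rate = attr(run$corpus, "sample_rate"),
                          tone_freqs = 2^seq(log2(1000), log2(11000),
                                             length.out = 8),
                          sweep_lengths_ms = c(20, 80, 160),
                          center_freq = 7000, train_counts = c(1, 3, 5),
                          am_rates = c(16, 33))
  frs <- lapply(run$mifs, tuning_curve, battery = bat)
  # no pure-tone responses from phrase-train or modulated-call MIF neurons
  for (tc in frs) expect_true(all(tc$fr[tc$class == "tone"] == 0))
  # sparse: most (MIF, stimulus-class) combinations stay silent
  pairs <- dplyr::bind_rows(frs) |>
    dplyr::group_by(.data$feature_id, .data$class) |>
    dplyr::summarize(active = any(.data$fr > 0), .groups = "drop")
  expect_lt(mean(pairs$active), 0.5)
})
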