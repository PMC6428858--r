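# Putative MIF-selective neurons: power-law firing rates, parametric
# stimulus batteries, natural-vs-reversed preference, and stimulus
# reconstruction from MIF detections.

#' Firing rate of a putative MIF-selective neuron
#'
#' A rectified power law applied to the membrane-potential proxy (the maximum
#' NCC value): `FR = k * max(v_m - theta, 0)^p`. Zero at and below the MIF's
#' optimal threshold, continuous at threshold, monotone above it.
#'
#' @param v_m Membrane-potential proxy (max NCC), vectorized.
#' @param theta The MIF's optimal threshold.
#' @param k Scale factor (spk/s per unit^p); arbitrary units by default.
#' @param p Exponent of the nonlinearity (default 4).
#' @return Firing rate(s), >= 0.
#' @export
firing_rate <- function(v_m, theta, k = 1, p = 4) {
  stopifnot(k > 0, p > 0)
  k * pmax(v_m - theta, 0)^p
}

battery_row <- function(class, label, waveform, ...) {
  tibble::tibble(stimulus_id = label, class = class,
                 params = list(list(...)), waveform = list(waveform))
}

#' Parametric stimulus battery
#'
#' Renders the comparison stimuli used to probe model MIF-neuron tuning:
#' pure tones, linear FM sweeps of several lengths and directions, trains of
#' upward sweeps (variable count, fixed inter-sweep interval), AM tones,
#' band-limited noise bursts, click trains, and two-tone combinations.
#'
#' @param sample_rate Hz.
#' @param tone_freqs Pure-tone frequencies (Hz).
#' @param sweep_lengths_ms Sweep durations (ms).
#' @param sweep_octaves Sweep extent (octaves around `center_freq`).
#' @param center_freq Center frequency (Hz) for sweeps/AM/two-tone stimuli.
#' @param train_counts Sweep counts for sweep trains.
#' @param train_isi_ms Inter-sweep interval in trains (ms).
#' @param am_rates AM rates (Hz).
#' @param seed Seed for the noise bursts.
#' @return Tibble `stimulus_id`, `class`, `params`, `waveform`; sample rate
#'   in attribute `"sample_rate"`.
#' @export
stimulus_battery <- function(sample_rate = 48000,
                             tone_freqs = 2^seq(log2(500), log2(16000),
                                                length.out = 12),
                             sweep_lengths_ms = c(10, 20, 40, 80, 160, 320),
                             sweep_octaves = 1.2,
                             center_freq = 7000,
                             train_counts = 1:5, train_isi_ms = 50,
                             am_rates = c(8, 16, 33, 64), seed = 1) {
  fs <- sample_rate
  rows <- list()
  for (f in tone_freqs) {
    n <- round(0.2 * fs)
    rows[[length(rows) + 1]] <- battery_row(
      "tone", sprintf("tone_%.0fHz", f),
      sin(2 * pi * f * seq_len(n) / fs) * ramp_env(n, fs), freq = f)
  }
  f_lo <- center_freq * 2^(-sweep_octaves / 2)
  f_hi <- center_freq * 2^(sweep_octaves / 2)
  for (len in sweep_lengths_ms) for (dir in c("up", "down")) {
    sw <- synth_phrase_train(if (dir == "up") f_lo else f_hi,
                             if (dir == "up") f_hi else f_lo,
                             len / 1000, 0.05, 1, fs)
    rows[[length(rows) + 1]] <- battery_row(
      "fm_sweep", sprintf("sweep_%s_%dms", dir, len), sw,
      direction = dir, length_ms = len)
  }
  for (k in train_counts) {
    tr <- synth_phrase_train(f_lo, f_hi, 0.080, train_isi_ms / 1000, k, fs)
    rows[[length(rows) + 1]] <- battery_row(
      "sweep_train", sprintf("train_%dx80ms", k), tr,
      n_sweeps = k, isi_ms = train_isi_ms)
  }
  for (r in am_rates) {
    n <- round(0.3 * fs)
    t <- seq_len(n) / fs
    am <- sin(2 * pi * center_freq * t) *
      (0.5 * (1 + sin(2 * pi * r * t))) * ramp_env(n, fs)
    rows[[length(rows) + 1]] <- battery_row(
      "am_tone", sprintf("am_%gHz", r), am, am_rate = r)
  }
  rows[[length(rows) + 1]] <- battery_row(
    "noise", "noise_burst",
    with_local_seed(seed, synth_band_noise(f_lo / 2, min(f_hi * 2, fs / 2.2),
                                           0.2, fs)))
  click <- numeric(round(0.2 * fs))
  click[round(seq(0.01, 0.19, by = 0.02) * fs)] <- 1
  rows[[length(rows) + 1]] <- battery_row("click", "click_train", click)
  for (gap_oct in c(0.25, 0.5, 1)) {
    n <- round(0.2 * fs)
    t <- seq_len(n) / fs
    tt <- (sin(2 * pi * center_freq * 2^(-gap_oct / 2) * t) +
             sin(2 * pi * center_freq * 2^(gap_oct / 2) * t)) *
      ramp_env(n, fs)
    rows[[length(rows) + 1]] <- battery_row(
      "two_tone", sprintf("twotone_%goct", gap_oct), tt, gap_oct = gap_oct)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sample_rate") <- fs
  out
}

#' Tuning curves of model MIF neurons over a stimulus battery
#'
#' Each battery stimulus is rendered through the same front-end used for
#' training; the max-NCC response of each MIF is converted to a firing rate
#' with the rectified power law.
#'
#' @param mif_set A `mif_set` (must carry its `frontend` parameters, or pass
#'   `frontend`).
#' @param battery A [stimulus_battery()] tibble.
#' @param frontend A [frontend_params()]; defaults to the set's.
#' @param k,p Nonlinearity parameters ([firing_rate()]).
#' @return Tibble `feature_id`, `stimulus_id`, `class`, `v_m`, `fr`.
#' @export
tuning_curve <- function(mif_set, battery, frontend = mif_set$frontend,
                         k = 1, p = 4) {
  stopifnot(!is.null(frontend))
  fs <- attr(battery, "sample_rate")
  reps <- lapply(battery$waveform, make_representation, sample_rate = fs,
                 params = frontend)
  names(reps) <- battery$stimulus_id
  vm <- compute_responses(mif_set$features, reps, short = "floor")
  out <- tibble::as_tibble(expand.grid(
    feature_id = mif_set$features$feature_id,
    stimulus_id = battery$stimulus_id, stringsAsFactors = FALSE))
  out$class <- battery$class[match(out$stimulus_id, battery$stimulus_id)]
  out$v_m <- vm[cbind(out$feature_id, out$stimulus_id)]
  theta <- mif_set$features$threshold[match(out$feature_id,
                                            mif_set$features$feature_id)]
  out$fr <- firing_rate(out$v_m, theta, k, p)
  out
}

#' Natural-versus-reversed call preference of model MIF neurons
#'
#' Responses of each MIF neuron to each call and to its time-reversed
#' waveform, plus the fraction of responsive (MIF, call) pairs preferring the
#' natural direction.
#'
#' @param mif_set A `mif_set`.
#' @param corpus Corpus tibble (rows to test, e.g. held-out within-class
#'   calls).
#' @param frontend A [frontend_params()]; defaults to the set's.
#' @param k,p Nonlinearity parameters.
#' @return A list: `pairs` tibble (`feature_id`, `call_id`, `fr_natural`,
#'   `fr_reversed`) and `fraction_natural` (among pairs with any response).
#' @export
natural_vs_reversed <- function(mif_set, corpus,
                                frontend = mif_set$frontend, k = 1, p = 4) {
  stopifnot(!is.null(frontend))
  sr <- attr(corpus, "sample_rate")
  nat <- corpus_cochleagrams(corpus, frontend)
  rev_corpus <- corpus
  rev_corpus$waveform <- lapply(corpus$waveform, rev)
  rvs <- corpus_cochleagrams(rev_corpus, frontend)
  vn <- compute_responses(mif_set$features, nat, short = "floor")
  vr <- compute_responses(mif_set$features, rvs, short = "floor")
  theta <- mif_set$features$threshold
  frn <- firing_rate(vn, matrix(theta, nrow(vn), ncol(vn)), k, p)
  frr <- firing_rate(vr, matrix(theta, nrow(vr), ncol(vr)), k, p)
  pairs <- tibble::tibble(
    feature_id = rep(rownames(vn), times = ncol(vn)),
    call_id = rep(colnames(vn), each = nrow(vn)),
    fr_natural = as.numeric(frn), fr_reversed = as.numeric(frr))
  resp <- pairs$fr_natural > 0 | pairs$fr_reversed > 0
  frac <- if (any(resp))
    mean(pairs$fr_natural[resp] > pairs$fr_reversed[resp]) else NA_real_
  list(pairs = pairs, fraction_natural = frac)
}

# alpha kernel peaking at tau_ms after the event
alpha_kernel <- function(tau_ms, frame_rate) {
  dt <- 1000 / frame_rate
  t <- seq(0, 8 * tau_ms, by = dt)
  (t / tau_ms) * exp(1 - t / tau_ms)
}

#' Reconstruct a stimulus from MIF detections
#'
#' MIF detection times (2 ms resolution) are convolved with an alpha kernel;
#' at each peak of the convolved trace a copy of the MIF patch, scaled by the
#' MIF's log-likelihood weight, is placed (peak time corrected for the kernel
#' delay), summing where copies overlap. Accuracy is the zero-lag NCC between
#' the original and reconstructed maps.
#'
#' @param mif_set A `mif_set`.
#' @param rep A `cochleagram` (same front-end as training).
#' @param tau_ms Alpha-kernel time constant (ms).
#' @param refractory_ms Event resolution (ms).
#' @return A `mif_reconstruction`: list with `rates` (reconstructed map),
#'   `accuracy`, `n_events`.
#' @export
reconstruct_stimulus <- function(mif_set, rep, tau_ms = 5,
                                 refractory_ms = 2) {
  feats <- mif_set$features
  nch <- nrow(rep$rates); nfr <- ncol(rep$rates)
  recon <- matrix(0, nch, nfr)
  kern <- alpha_kernel(tau_ms, rep$frame_rate)
  delay_frames <- which.max(kern) - 1L
  events <- detect_mifs(mif_set, rep, "stream", refractory_ms)
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(feats))) {
      ev <- events$time_ms[events$feature_id == feats$feature_id[i]]
      if (length(ev) == 0) next
      trace <- numeric(nfr + length(kern))
      fr_idx <- round(ev / 1000 * rep$frame_rate) + 1L
      for (t in fr_idx) {
        idx <- t:(t + length(kern) - 1L)
        trace[idx] <- trace[idx] + kern
      }
      peaks <- which(diff(sign(diff(trace))) < 0) + 1L
      peaks <- peaks[trace[peaks] > 1e-9]
      patch <- feats$patch[[i]] * feats$weight[i]
      for (pk in peaks) {
        t0 <- pk - delay_frames # kernel delay corrected
        if (t0 < 1) t0 <- 1L
        t1 <- min(nfr, t0 + ncol(patch) - 1L)
        if (t1 < t0) next
        rows <- feats$ch_lo[i]:feats$ch_hi[i]
        recon[rows, t0:t1] <- recon[rows, t0:t1] +
          patch[, seq_len(t1 - t0 + 1), drop = FALSE]
      }
    }
  }
  acc <- if (nrow(events) == 0 || stats::var(as.numeric(recon)) == 0) 0 else
    zero_lag_ncc(rep$rates, recon)
  structure(list(rates = recon, accuracy = acc, n_events = nrow(events),
                 frame_rate = rep$frame_rate),
            class = "mif_reconstruction")
}

# zero-lag NCC between two equal-size maps
zero_lag_ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  va <- stats::var(a) * (length(a) - 1) / length(a)
  vb <- stats::var(b) * (length(b) - 1) / length(b)
  if (va <= 0 || vb <= 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / sqrt(va * vb)
}

#' @export
print.mif_reconstruction <- function(x, ...) {
  cat(sprintf("<mif_reconstruction> %d x %d map, %d events, accuracy %.3f\n",
              nrow(x$rates), ncol(x$rates), x$n_events, x$accuracy))
  invisible(x)
}
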