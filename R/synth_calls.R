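# Synthetic vocalization generator.
#
# Emulates the statistical structure the feature-selection method depends on:
# call categories whose long-term spectra overlap but whose short-time
# spectrotemporal structure differs (repeated upward FM phrases; short
# sinusoidally FM/AM-modulated calls; long slowly-modulated tonal calls;
# noise-like distractors), with per-caller production variability in
# bandwidth, dominant frequency, duration and inter-phrase interval.

#' Call-type specification
#'
#' Defines the parameter distributions of one synthetic call category.
#' Frequencies are drawn log-normally (Gaussian on the log2/octave scale),
#' durations and intervals Gaussian, all truncated to physical range.
#'
#' @param name Category label.
#' @param model One of `"twitter_like"` (train of upward linear-FM phrases),
#'   `"trill_like"` (sinusoidal FM/AM short call), `"phee_like"` (long tonal
#'   call with slow FM and vibrato), `"noise_like"` (band-limited noise
#'   distractor with amplitude modulation), `"chatter_like"` (irregular train
#'   of FM sweeps of variable length, spacing and direction), or
#'   `"mixture"` (draw uniformly among `components`).
#' @param dom_freq_hz,dom_freq_sd_oct Median dominant frequency (Hz) and its
#'   spread in octaves.
#' @param bandwidth_oct,bandwidth_sd Mean call bandwidth (octaves) and sd.
#' @param duration_s,duration_sd Mean duration (s) and sd (for phrase trains
#'   the duration is determined by phrase count and period instead).
#' @param phrase_len_s,phrase_len_sd Phrase length (s) for phrase trains.
#' @param ipi_s,ipi_sd Inter-phrase interval (s): silent gap between phrases.
#' @param phrase_count_range Integer range of phrases per call.
#' @param am_period_s,am_period_sd Modulation period (s) for `trill_like`.
#' @param fm_depth_oct FM depth (octaves, peak-to-peak) for `trill_like` /
#'   slow-FM extent for `phee_like`.
#' @param components For `model = "mixture"`, list of `call_type_spec`s.
#' @return A `call_type_spec` list.
#' @export
call_type_spec <- function(name, model = c("twitter_like", "trill_like",
                                           "phee_like", "noise_like",
                                           "chatter_like", "mixture"),
                           dom_freq_hz = 7000, dom_freq_sd_oct = 0.15,
                           bandwidth_oct = 1.2, bandwidth_sd = 0.2,
                           duration_s = 0.5, duration_sd = 0.07,
                           phrase_len_s = 0.080, phrase_len_sd = 0.008,
                           ipi_s = 0.110, ipi_sd = 0.012,
                           phrase_count_range = c(5L, 9L),
                           am_period_s = 0.030, am_period_sd = 0.003,
                           fm_depth_oct = 0.4,
                           components = NULL) {
  model <- match.arg(model)
  if (model == "mixture" && (is.null(components) || length(components) < 2))
    stop("mixture model needs >= 2 components", call. = FALSE)
  structure(list(name = name, model = model,
                 dom_freq_hz = dom_freq_hz, dom_freq_sd_oct = dom_freq_sd_oct,
                 bandwidth_oct = bandwidth_oct, bandwidth_sd = bandwidth_sd,
                 duration_s = duration_s, duration_sd = duration_sd,
                 phrase_len_s = phrase_len_s, phrase_len_sd = phrase_len_sd,
                 ipi_s = ipi_s, ipi_sd = ipi_sd,
                 phrase_count_range = as.integer(phrase_count_range),
                 am_period_s = am_period_s, am_period_sd = am_period_sd,
                 fm_depth_oct = fm_depth_oct, components = components),
            class = "call_type_spec")
}

#' Default synthetic call-type specifications
#'
#' Two structured target categories plus a heterogeneous distractor category
#' (a mixture of amplitude-modulated noise calls, long tonal calls with
#' vibrato, and irregular FM sweep chatter). Dominant-frequency distributions
#' overlap across categories, and the distractors share local spectrotemporal
#' elements with the targets (sweep segments, 20-45 Hz modulation), so brief
#' fragments are ambiguous and only intermediate-scale structure (the regular
#' ~190 ms phrase period of the sweep train; the sustained deep ~30 ms
#' modulation of the short call) is category-specific -- the precondition of
#' the feature-selection method.
#'
#' @return Named list of [call_type_spec()] objects
#'   (`twitter_like`, `trill_like`, `other`).
#' @export
default_call_specs <- function() {
  twitter <- call_type_spec("twitter_like", "twitter_like",
                            dom_freq_hz = 7000, dom_freq_sd_oct = 0.06,
                            bandwidth_oct = 1.2, bandwidth_sd = 0.2,
                            phrase_len_s = 0.080, phrase_len_sd = 0.008,
                            ipi_s = 0.110, ipi_sd = 0.012,
                            phrase_count_range = c(5L, 9L))
  trill <- call_type_spec("trill_like", "trill_like",
                          dom_freq_hz = 7500, dom_freq_sd_oct = 0.08,
                          duration_s = 0.5, duration_sd = 0.07,
                          am_period_s = 0.030, am_period_sd = 0.003,
                          fm_depth_oct = 0.7)
  phee <- call_type_spec("phee_like", "phee_like",
                         dom_freq_hz = 7000, dom_freq_sd_oct = 0.12,
                         duration_s = 1.25, duration_sd = 0.15,
                         fm_depth_oct = 0.15)
  noise <- call_type_spec("noise_like", "noise_like",
                          dom_freq_hz = 6500, dom_freq_sd_oct = 0.2,
                          bandwidth_oct = 1.5, bandwidth_sd = 0.3,
                          duration_s = 0.6, duration_sd = 0.1)
  chatter <- call_type_spec("chatter_like", "chatter_like",
                            dom_freq_hz = 7000, dom_freq_sd_oct = 0.18,
                            bandwidth_oct = 1.1, bandwidth_sd = 0.25,
                            phrase_count_range = c(3L, 8L))
  other <- call_type_spec("other", "mixture",
                          components = list(noise, phee, chatter))
  list(twitter_like = twitter, trill_like = trill, other = other)
}

#' Caller specifications
#'
#' Per-caller production offsets: Gaussian offsets on log-frequency and
#' multiplicative log-normal scales on durations/intervals, emulating
#' between-individual variability.
#'
#' @param n_callers Number of callers.
#' @param seed Integer seed.
#' @param freq_sd_oct SD of the caller's dominant-frequency offset (octaves).
#' @param scale_sd SD (log scale) of duration/interval/bandwidth scales.
#' @return Tibble with one row per caller.
#' @export
make_callers <- function(n_callers, seed, freq_sd_oct = 0.12,
                         scale_sd = 0.08) {
  stopifnot(n_callers >= 1)
  with_local_seed(seed, {
    tibble::tibble(
      caller = sprintf("caller%02d", seq_len(n_callers)),
      freq_offset_oct = rnorm(n_callers, 0, freq_sd_oct),
      duration_scale = exp(rnorm(n_callers, 0, scale_sd)),
      ipi_scale = exp(rnorm(n_callers, 0, scale_sd)),
      bandwidth_scale = exp(rnorm(n_callers, 0, scale_sd))
    )
  })
}

# Evaluate expr with a locally-set RNG seed, restoring global state after.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Truncated draw helpers; redraw out-of-range values, error after 100 tries.
draw_trunc <- function(rfun, lo, hi, what) {
  for (i in 1:100) {
    x <- rfun()
    if (x >= lo && x <= hi) return(x)
  }
  stop(sprintf("parameter draw for %s outside [%g, %g] after 100 rejections",
               what, lo, hi), call. = FALSE)
}

#' Generate one synthetic call
#'
#' Deterministic for a fixed seed. Realized production parameters are
#' returned in the metadata so that generator output can be audited.
#'
#' @param type_spec A [call_type_spec()].
#' @param caller One row of [make_callers()] (data frame or list), or `NULL`
#'   for a neutral caller.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate in Hz.
#' @param noise_snr_db Broadband background-noise level (signal-to-noise
#'   ratio in dB); `Inf` for a clean call.
#' @param phrase_count Optionally fix the number of phrases (phrase trains).
#' @return List with `waveform`, `sample_rate`, `call_type`, `caller`,
#'   `duration` and a `meta` list of realized parameters.
#' @export
generate_call <- function(type_spec, caller = NULL, seed = 1,
                          sample_rate = 48000, noise_snr_db = 10,
                          phrase_count = NULL) {
  stopifnot(inherits(type_spec, "call_type_spec"))
  if (is.null(caller)) {
    caller <- list(caller = "caller00", freq_offset_oct = 0,
                   duration_scale = 1, ipi_scale = 1, bandwidth_scale = 1)
  }
  with_local_seed(seed, {
    spec <- type_spec
    if (spec$model == "mixture") {
      spec <- spec$components[[sample.int(length(spec$components), 1)]]
    }
    nyq <- sample_rate / 2
    dom <- draw_trunc(function()
      spec$dom_freq_hz * 2^(rnorm(1, caller$freq_offset_oct,
                                  spec$dom_freq_sd_oct)),
      20, nyq, "dominant frequency")
    bw <- draw_trunc(function()
      rnorm(1, spec$bandwidth_oct * caller$bandwidth_scale,
            spec$bandwidth_sd), 0.05, 6, "bandwidth")
    f_lo <- dom * 2^(-bw / 2)
    f_hi <- dom * 2^(bw / 2)
    if (f_hi > nyq * 0.95) { # keep inside Nyquist
      f_hi <- nyq * 0.95
      f_lo <- f_hi * 2^(-bw)
    }
    wave <- switch(spec$model,
      twitter_like = {
        plen <- draw_trunc(function()
          rnorm(1, spec$phrase_len_s * caller$duration_scale,
                spec$phrase_len_sd), 0.02, 0.5, "phrase length")
        ipi <- draw_trunc(function()
          rnorm(1, spec$ipi_s * caller$ipi_scale, spec$ipi_sd),
          0.01, 1, "inter-phrase interval")
        npk <- if (is.null(phrase_count)) {
          spec$phrase_count_range[1] +
            sample.int(diff(spec$phrase_count_range) + 1L, 1) - 1L
        } else as.integer(phrase_count)
        synth_phrase_train(f_lo, f_hi, plen, ipi, npk, sample_rate)
      },
      trill_like = {
        dur <- draw_trunc(function()
          rnorm(1, spec$duration_s * caller$duration_scale,
                spec$duration_sd), 0.1, 3, "duration")
        amp <- draw_trunc(function()
          rnorm(1, spec$am_period_s, spec$am_period_sd),
          0.01, 0.1, "modulation period")
        synth_modulated_tone(dom, dur, amp, spec$fm_depth_oct, sample_rate)
      },
      phee_like = {
        dur <- draw_trunc(function()
          rnorm(1, spec$duration_s * caller$duration_scale,
                spec$duration_sd), 0.2, 4, "duration")
        synth_long_tonal(dom, dur, spec$fm_depth_oct, sample_rate)
      },
      noise_like = {
        dur <- draw_trunc(function()
          rnorm(1, spec$duration_s * caller$duration_scale,
                spec$duration_sd), 0.1, 3, "duration")
        synth_band_noise(f_lo, f_hi, dur, sample_rate)
      },
      chatter_like = {
        npk <- if (is.null(phrase_count)) {
          spec$phrase_count_range[1] +
            sample.int(diff(spec$phrase_count_range) + 1L, 1) - 1L
        } else as.integer(phrase_count)
        synth_chatter(f_lo, f_hi, npk, sample_rate)
      })
    # level-normalize and add recording-like background noise
    wave <- wave / max(stats::sd(wave), 1e-12) * 0.1
    if (is.finite(noise_snr_db)) {
      wave <- wave + rnorm(length(wave), 0,
                           0.1 * 10^(-noise_snr_db / 20))
    }
    meta <- list(
      model = spec$model,
      dom_freq_hz = dom,
      bandwidth_oct = if (spec$model %in% c("twitter_like", "noise_like",
                                            "chatter_like")) bw
      else spec$fm_depth_oct,
      duration_s = length(wave) / sample_rate,
      ipi_s = if (spec$model == "twitter_like") get0("ipi",
        envir = environment(), ifnotfound = NA_real_) else NA_real_,
      phrase_count = if (spec$model == "twitter_like") get0("npk",
        envir = environment(), ifnotfound = NA_integer_) else NA_integer_,
      am_period_s = if (spec$model == "trill_like") get0("amp",
        envir = environment(), ifnotfound = NA_real_) else NA_real_
    )
    list(waveform = wave, sample_rate = sample_rate,
         call_type = type_spec$name, caller = caller$caller,
         duration = length(wave) / sample_rate, meta = meta)
  })
}

ramp_env <- function(n, fs, ramp_s = 0.005) {
  nr <- max(2L, min(round(ramp_s * fs), floor(n / 2)))
  e <- rep(1, n)
  r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  e[seq_len(nr)] <- r
  e[n - seq_len(nr) + 1] <- r
  e
}

# upward linear-FM sweep phrases separated by silent gaps
synth_phrase_train <- function(f_lo, f_hi, phrase_len, ipi, n_phrases, fs) {
  np <- round(phrase_len * fs)
  t <- seq_len(np) / fs
  phase <- 2 * pi * (f_lo * t + (f_hi - f_lo) / (2 * phrase_len) * t^2)
  phrase <- sin(phase) * ramp_env(np, fs)
  gap <- numeric(round(ipi * fs))
  out <- numeric(0)
  for (i in seq_len(n_phrases)) {
    out <- c(out, phrase, if (i < n_phrases) gap)
  }
  out
}

# sinusoidally frequency- and amplitude-modulated tone
synth_modulated_tone <- function(dom, dur, am_period, fm_depth_oct, fs,
                                 am_depth = 0.8) {
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  finst <- dom * 2^(fm_depth_oct / 2 * sin(2 * pi * t / am_period))
  phase <- 2 * pi * cumsum(finst) / fs
  env <- 1 - am_depth / 2 * (1 - cos(2 * pi * t / am_period))
  sin(phase) * env * ramp_env(n, fs)
}

# long tonal call with slow FM and vibrato (vibrato rate near the modulated
# short call's rate, so brief fragments of the two are locally confusable)
synth_long_tonal <- function(dom, dur, fm_extent_oct, fs) {
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  vib_hz <- runif(1, 20, 30)
  finst <- dom * 2^(fm_extent_oct * (t / dur - 0.5) +
                      0.07 * sin(2 * pi * vib_hz * t))
  phase <- 2 * pi * cumsum(finst) / fs
  env <- 1 - 0.25 * (1 - cos(2 * pi * vib_hz * t)) / 2
  sin(phase) * env * ramp_env(n, fs, 0.02)
}

# band-limited noise with slow random bumps plus amplitude modulation
synth_band_noise <- function(f_lo, f_hi, dur, fs) {
  n <- round(dur * fs)
  x <- rnorm(n)
  X <- fft(x)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)
  X[freq < f_lo | freq > f_hi] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  # slow random envelope: lowpassed noise, positive
  k <- max(3, round(n / (0.08 * fs)))
  env <- abs(fft(ifelse(seq_len(n) <= k | seq_len(n) > n - k,
                        fft(rnorm(n)), 0), inverse = TRUE) / n)
  env <- env / max(env)
  am_hz <- runif(1, 15, 45)
  am <- 1 - 0.6 * (1 - cos(2 * pi * am_hz * seq_len(n) / fs)) / 2
  y * (0.3 + 0.7 * env) * am * ramp_env(n, fs)
}

# irregular train of upward FM sweeps through the same band as the regular
# phrase train, but slower (120-200 ms) and at irregular intervals: brief
# windows see an ambiguous diagonal ridge, while the stereotyped ~190 ms
# two-phrase conjunction remains specific to the regular train
synth_chatter <- function(f_lo, f_hi, n_sweeps, fs) {
  out <- numeric(0)
  for (i in seq_len(n_sweeps)) {
    len <- runif(1, 0.12, 0.20)
    jit <- 2^runif(1, -0.25, 0.25)
    lo <- f_lo * jit; hi <- min(f_hi * jit, fs / 2.2)
    sw <- synth_phrase_train(lo, hi, len, 0.05, 1, fs)
    gap <- numeric(round(runif(1, 0.10, 0.30) * fs))
    out <- c(out, sw, if (i < n_sweeps) gap)
  }
  out
}

#' Generate a labeled synthetic corpus
#'
#' Generates `n_per_class` calls per category, allocated round-robin over a
#' shared pool of synthetic callers, with a caller-stratified train/test
#' split. Fully deterministic for a fixed seed.
#'
#' @param specs Named list of [call_type_spec()]s (default
#'   [default_call_specs()]).
#' @param n_per_class Calls per category (>= 2).
#' @param n_callers Number of synthetic callers (>= 1).
#' @param split_fractions Named numeric `c(train = , test = )`, each in
#'   (0, 1), summing to 1.
#' @param seed Integer master seed.
#' @param sample_rate Hz.
#' @param noise_snr_db Background noise level passed to [generate_call()].
#' @return Tibble (one row per call): `call_id`, `call_type`, `caller`,
#'   `split`, realized production parameters, and a `waveform` list-column;
#'   `sample_rate` stored as an attribute.
#' @export
generate_corpus <- function(specs = default_call_specs(), n_per_class = 100,
                            n_callers = 8,
                            split_fractions = c(train = 0.5, test = 0.5),
                            seed = 1, sample_rate = 48000,
                            noise_snr_db = 10) {
  stopifnot(n_per_class >= 2, n_callers >= 1)
  if (any(split_fractions <= 0) || any(split_fractions >= 1) ||
      abs(sum(split_fractions) - 1) > 1e-9) {
    stop("split fractions must be in (0,1) and sum to 1", call. = FALSE)
  }
  callers <- make_callers(n_callers, seed = substream_seed(seed, "callers"))
  call_seeds <- with_local_seed(substream_seed(seed, "call_seeds"),
                                sample.int(.Machine$integer.max,
                                           n_per_class * length(specs)))
  rows <- list()
  idx <- 0
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    caller_idx <- rep_len(seq_len(n_callers), n_per_class)
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1
      cal <- as.list(callers[caller_idx[j], ])
      rec <- generate_call(spec, cal, seed = call_seeds[idx],
                           sample_rate = sample_rate,
                           noise_snr_db = noise_snr_db)
      rows[[idx]] <- tibble::tibble(
        call_id = sprintf("%s_%04d", spec$name, j),
        call_type = spec$name, caller = cal$caller,
        duration_s = rec$duration,
        dom_freq_hz = rec$meta$dom_freq_hz,
        bandwidth_oct = rec$meta$bandwidth_oct,
        ipi_s = rec$meta$ipi_s,
        phrase_count = rec$meta$phrase_count,
        am_period_s = rec$meta$am_period_s,
        model = rec$meta$model,
        waveform = list(rec$waveform)
      )
    }
  }
  corpus <- dplyr::bind_rows(rows)
  # caller-stratified split within each class; cumulative rounding keeps the
  # overall split balanced even when cells have odd sizes
  corpus$split <- NA_character_
  cells <- split(seq_len(nrow(corpus)),
                 paste(corpus$call_type, corpus$caller, sep = "|"))
  frac <- split_fractions[["train"]]
  assigned <- 0
  cum_n <- 0
  for (nm in sort(names(cells))) {
    cell <- cells[[nm]]
    n <- length(cell)
    cum_n <- cum_n + n
    n_train <- max(0, min(n, round(frac * cum_n) - assigned))
    assigned <- assigned + n_train
    ord <- with_local_seed(substream_seed(seed, paste0("split_", nm)),
                           sample.int(n))
    corpus$split[cell] <- "test"
    corpus$split[cell[ord[seq_len(n_train)]]] <- "train"
  }
  corpus <- dplyr::relocate(corpus, "split", .after = "caller")
  attr(corpus, "sample_rate") <- sample_rate
  corpus
}

#' Summarize production variability of a corpus
#'
#' One row per call with the realized production parameters (bandwidth,
#' dominant frequency, duration, inter-phrase interval), the caller, and the
#' split. Parameters undefined for a call model (e.g. inter-phrase interval
#' of a single-phrase or non-phrased call) are `NA`.
#'
#' @param corpus A [generate_corpus()] tibble.
#' @return Tibble of per-call parameters.
#' @export
summarize_production_variability <- function(corpus) {
  dplyr::select(corpus, "call_id", "call_type", "caller", "split",
                "bandwidth_oct", "dom_freq_hz", "duration_s", "ipi_s")
}

#' Derive a stage seed from a master seed
#'
#' Each randomized stage consumes an independently derived substream seed so
#' that any stage can be re-run in isolation.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @export
substream_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 7919) %% 2147483647L) + 1L
}
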