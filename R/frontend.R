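#' Front-end parameters
#'
#' Parameters of the peripheral model that converts waveforms into
#' cochleagrams: a gammatone filterbank followed by half-wave rectification,
#' power-law compression and per-frame averaging. Defaults cover the marmoset
#' call band with 1 ms frames.
#'
#' @param n_channels Number of filterbank channels.
#' @param cf_min,cf_max Lowest/highest center frequency (Hz); channels are
#'   log-spaced between them.
#' @param frame_rate Output frames per second.
#' @param compression_exponent Power-law compression exponent applied to the
#'   half-wave rectified filter output.
#' @param waveform_rate Sampling rate (Hz) of the single-channel map returned
#'   in waveform mode (the control front-end that skips the filterbank).
#' @return A `frontend_params` list.
#' @export
frontend_params <- function(n_channels = 64, cf_min = 200, cf_max = 16000,
                            frame_rate = 1000, compression_exponent = 0.3,
                            waveform_rate = 16000) {
  stopifnot(n_channels >= 2, cf_min > 0, cf_max > cf_min, frame_rate > 0,
            compression_exponent > 0, waveform_rate > 0)
  structure(list(n_channels = n_channels, cf_min = cf_min, cf_max = cf_max,
                 frame_rate = frame_rate,
                 compression_exponent = compression_exponent,
                 waveform_rate = waveform_rate),
            class = "frontend_params")
}

#' Center frequencies of a front-end
#' @param params A [frontend_params()] object.
#' @return Numeric vector (Hz), strictly increasing.
#' @export
center_freqs <- function(params) {
  exp(seq(log(params$cf_min), log(params$cf_max),
          length.out = params$n_channels))
}

#' Convert a waveform into a time-frequency map
#'
#' In `"cochleagram"` mode the waveform is passed through a gammatone
#' filterbank (4th-order, ERB bandwidths), each channel half-wave rectified,
#' compressed with a power law, and averaged within frames, yielding a
#' nonnegative channels x frames rate map: a stand-in for the population
#' activity of model auditory nerve fibers. In `"waveform"` mode the raw
#' signal is resampled to `waveform_rate` and returned as a single signed
#' channel, so that the identical template-matching machinery can be run on
#' the acoustic waveform as a control.
#'
#' @param waveform Numeric vector of audio samples.
#' @param sample_rate Sampling rate in Hz.
#' @param params A [frontend_params()] object.
#' @param mode `"cochleagram"` (default) or `"waveform"`.
#' @return A `cochleagram` object: list with `rates` (channels x frames
#'   matrix), `center_freqs`, `frame_rate`, `mode`.
#' @export
make_representation <- function(waveform, sample_rate,
                                params = frontend_params(),
                                mode = c("cochleagram", "waveform")) {
  mode <- match.arg(mode)
  if (length(waveform) == 0) stop("empty waveform", call. = FALSE)
  stopifnot(sample_rate > 0)
  if (mode == "cochleagram") {
    if (params$cf_max > sample_rate / 2) {
      stop("cf_max exceeds the Nyquist frequency", call. = FALSE)
    }
    cfs <- center_freqs(params)
    rates <- cochleagram_cpp(as.numeric(waveform), sample_rate, cfs,
                             params$frame_rate, params$compression_exponent)
    new_cochleagram(rates, cfs, params$frame_rate, "cochleagram")
  } else {
    y <- resample_wave(as.numeric(waveform), sample_rate, params$waveform_rate)
    new_cochleagram(matrix(y, nrow = 1), NA_real_, params$waveform_rate,
                    "waveform")
  }
}

new_cochleagram <- function(rates, center_freqs, frame_rate, mode) {
  structure(list(rates = rates, center_freqs = center_freqs,
                 frame_rate = frame_rate, mode = mode),
            class = "cochleagram")
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("<cochleagram [%s]> %d channels x %d frames @ %g frames/s\n",
              x$mode, nrow(x$rates), ncol(x$rates), x$frame_rate))
  invisible(x)
}

#' @export
dim.cochleagram <- function(x) dim(x$rates)

# FFT-based resampler: brick-wall lowpass at the target Nyquist, then linear
# interpolation onto the new sample grid. Deterministic; adequate for the
# waveform-mode control.
resample_wave <- function(x, fs_in, fs_out) {
  if (fs_out >= fs_in) {
    t_new <- seq(0, (length(x) - 1) / fs_in, by = 1 / fs_out)
    return(stats::approx(seq_along(x) / fs_in - 1 / fs_in, x, xout = t_new,
                         rule = 2)$y)
  }
  n <- length(x)
  X <- fft(x)
  freq <- (seq_len(n) - 1) / n * fs_in
  freq <- pmin(freq, fs_in - freq)
  X[freq > fs_out / 2] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  t_new <- seq(0, (n - 1) / fs_in, by = 1 / fs_out)
  stats::approx((seq_len(n) - 1) / fs_in, y, xout = t_new, rule = 2)$y
}

#' Tidy a cochleagram into a long tibble
#'
#' @param x A `cochleagram`.
#' @param ... Unused.
#' @return Tibble with `channel`, `center_freq`, `time_ms`, `rate`.
#' @export
tidy.cochleagram <- function(x, ...) {
  nf <- ncol(x$rates)
  tibble::tibble(
    channel = rep(seq_len(nrow(x$rates)), times = nf),
    center_freq = rep(if (all(is.na(x$center_freqs))) NA_real_ else
      x$center_freqs, times = nf),
    time_ms = rep((seq_len(nf) - 0.5) / x$frame_rate * 1000,
                  each = nrow(x$rates)),
    rate = as.vector(x$rates)
  )
}

#' Plot a cochleagram
#' @param object A `cochleagram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cochleagram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "rate") +
    ggplot2::labs(x = "time (ms)", y = "channel") +
    ggplot2::theme_minimal()
}
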