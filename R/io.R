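# Persistence: WAV audio, corpus manifests, and the versioned JSON container
# for MIF sets.

MIF_SET_FORMAT <- "mifcat_mif_set"
MIF_SET_FORMAT_VERSION <- 1L

#' Write a mono waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit PCM or 32-bit IEEE float).
#'
#' @param waveform Numeric samples in \[-1, 1\] (clipped otherwise).
#' @param path Output path.
#' @param sample_rate Hz.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  x <- pmin(1, pmax(-1, as.numeric(waveform)))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16/24-bit PCM and 32-bit IEEE float, mono or first channel of
#' multichannel.
#'
#' @param path WAV path.
#' @return List with `waveform` (numeric, \[-1, 1\] scale) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file", call. = FALSE)
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file", call. = FALSE)
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found",
                                               call. = FALSE)
    size <- readBin(con, integer(), 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), 1, 2, endian = "little")
      n_chan <- readBin(con, integer(), 1, 2, endian = "little")
      sample_rate <- readBin(con, integer(), 1, 4, endian = "little")
      invisible(readBin(con, integer(), 1, 4, endian = "little"))
      invisible(readBin(con, integer(), 1, 2, endian = "little"))
      bits <- readBin(con, integer(), 1, 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), size - 16))
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk",
                                  call. = FALSE)
      if (fmt_code == 1 && bits == 16) {
        raw16 <- readBin(con, integer(), size / 2, 2, signed = TRUE,
                         endian = "little")
        x <- raw16 / 32767
      } else if (fmt_code == 1 && bits == 24) {
        b <- readBin(con, raw(), size)
        m <- matrix(as.integer(b), nrow = 3)
        v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
        x <- v / 8388607
      } else if (fmt_code == 3 && bits == 32) {
        x <- readBin(con, numeric(), size / 4, 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV format (code %d, %d bit)",
                     fmt_code, bits), call. = FALSE)
      }
      if (n_chan > 1) x <- x[seq(1, length(x), by = n_chan)]
      return(list(waveform = x, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, raw(), size + size %% 2))
    }
  }
}

#' Write a corpus to WAV files plus a CSV manifest
#'
#' @param corpus A [generate_corpus()] tibble.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sr <- attr(corpus, "sample_rate")
  paths <- character(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    paths[i] <- file.path(dir, paste0(corpus$call_id[i], ".wav"))
    write_wav(corpus$waveform[[i]] / max(abs(corpus$waveform[[i]])) * 0.9,
              paths[i], sr)
  }
  manifest <- dplyr::mutate(dplyr::select(corpus, -"waveform"),
                            path = paths, sample_rate = sr)
  mf <- file.path(dir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  mf
}

#' Read a corpus from a CSV manifest
#'
#' The manifest must have columns `path`, `call_type`, `caller`, `split`;
#' waveforms are loaded from the referenced WAV files.
#'
#' @param manifest_path Manifest CSV path.
#' @return Corpus tibble as from [generate_corpus()].
#' @export
read_corpus <- function(manifest_path) {
  m <- tibble::as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  need <- c("path", "call_type", "caller", "split")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  srs <- integer(nrow(m))
  waves <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- m$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(m$path[i]))
    w <- read_wav(p)
    waves[[i]] <- w$waveform
    srs[i] <- w$sample_rate
  }
  if (length(unique(srs)) != 1) stop("mixed sample rates in corpus",
                                     call. = FALSE)
  if (!"call_id" %in% names(m)) {
    m$call_id <- sub("\\.wav$", "", basename(m$path))
  }
  m$waveform <- waves
  attr(m, "sample_rate") <- srs[1]
  m
}

#' Save a MIF set to a versioned JSON container
#'
#' @param mif_set A `mif_set`.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
save_mif_set <- function(mif_set, path) {
  feats <- mif_set$features
  flist <- lapply(seq_len(nrow(feats)), function(i) {
    p <- feats$patch[[i]]
    list(feature_id = feats$feature_id[i],
         source_call = feats$source_call[i],
         ch_lo = feats$ch_lo[i], ch_hi = feats$ch_hi[i],
         t_on_ms = feats$t_on_ms[i], length_ms = feats$length_ms[i],
         bandwidth_oct = feats$bandwidth_oct[i],
         threshold = feats$threshold[i], merit = feats$merit[i],
         weight = feats$weight[i], complexity = feats$complexity[i],
         degenerate = feats$degenerate[i],
         added_information = feats$added_information[i],
         patch_dim = dim(p), patch = as.numeric(p))
  })
  obj <- list(format = MIF_SET_FORMAT,
              format_version = MIF_SET_FORMAT_VERSION,
              task = unclass(mif_set$task),
              prior = mif_set$prior,
              total_information = mif_set$total_information,
              stop_reason = mif_set$stop_reason,
              frontend = if (!is.null(mif_set$frontend))
                unclass(mif_set$frontend) else NULL,
              features = flist)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a MIF set from a JSON container
#'
#' Refuses containers with a different format or format version; a truncated
#' or corrupt file raises an explicit format error.
#'
#' @param path Container path.
#' @return A `mif_set`.
#' @export
load_mif_set <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("not a valid MIF-set container: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, MIF_SET_FORMAT)) {
    stop("not a MIF-set container (format field missing or wrong)",
         call. = FALSE)
  }
  if (!identical(as.integer(obj$format_version), MIF_SET_FORMAT_VERSION)) {
    stop(sprintf("MIF-set container format version %s not supported (need %d)",
                 obj$format_version, MIF_SET_FORMAT_VERSION), call. = FALSE)
  }
  rows <- lapply(obj$features, function(f) {
    patch <- matrix(unlist(f$patch), nrow = f$patch_dim[[1]])
    tibble::tibble(feature_id = f$feature_id, source_call = f$source_call,
                   ch_lo = as.integer(f$ch_lo), ch_hi = as.integer(f$ch_hi),
                   t_on_ms = f$t_on_ms, length_ms = f$length_ms,
                   bandwidth_oct = f$bandwidth_oct, patch = list(patch),
                   threshold = f$threshold, merit = f$merit,
                   weight = f$weight, complexity = f$complexity,
                   degenerate = f$degenerate,
                   added_information = f$added_information)
  })
  feats <- dplyr::bind_rows(rows)
  task <- if (!is.null(obj$task)) {
    structure(lapply(obj$task, function(x) if (is.list(x)) unlist(x) else x),
              class = "task_spec")
  } else NULL
  frontend <- if (!is.null(obj$frontend)) {
    structure(obj$frontend, class = "frontend_params")
  } else NULL
  new_mif_set(dplyr::select(feats, -"added_information"),
              feats$added_information, obj$stop_reason, task, obj$prior,
              frontend)
}
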