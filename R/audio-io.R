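#' Waveform objects
#'
#' A waveform is a lightweight container for a mono audio signal: a numeric
#' vector of dimensionless amplitudes (nominally in \[-1, 1\]) plus its sample
#' rate in Hz.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param sample_rate Sampling rate in Hz (single positive number).
#' @return An object of class `"waveform"`: a list with elements `samples`
#'   and `sample_rate`.
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop("'samples' must be a finite numeric vector", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("'sample_rate' must be a single positive number", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.1f ms)>\n",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave A `waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$sample_rate

# little-endian raw -> unsigned integer (vectorised over a raw matrix with
# one column per value)
.le_bytes_to_uint <- function(bytes_mat) {
  n_bytes <- nrow(bytes_mat)
  v <- numeric(ncol(bytes_mat))
  for (b in seq_len(n_bytes)) {
    v <- v + as.numeric(bytes_mat[b, ]) * 256^(b - 1)
  }
  v
}

#' Read a mono RIFF WAV file
#'
#' Supports PCM encodings of 16, 24 and 32 bits per sample and IEEE float
#' (32 or 64 bit). Integer encodings are rescaled to \[-1, 1\] by division
#' by 2^(bits-1). Only single-channel files are accepted; multi-channel
#' audio must be down-mixed before use.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop(sprintf("not a RIFF/WAV file (bad header): '%s'", path), call. = FALSE)
  }
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave_tag <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave_tag, "WAVE")) {
    stop(sprintf("not a WAVE file: '%s'", path), call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    chunk_id <- readChar(con, 4L, useBytes = TRUE)
    if (length(chunk_id) == 0L || nchar(chunk_id) < 4L) break
    chunk_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(chunk_size) == 0L) break
    if (identical(chunk_id, "fmt ")) {
      body <- readBin(con, "raw", chunk_size)
      if (length(body) < 16L) {
        stop(sprintf("corrupt fmt chunk in '%s'", path), call. = FALSE)
      }
      fmt <- list(
        audio_format = .le_bytes_to_uint(matrix(body[1:2], ncol = 1L)),
        n_channels   = .le_bytes_to_uint(matrix(body[3:4], ncol = 1L)),
        sample_rate  = .le_bytes_to_uint(matrix(body[5:8], ncol = 1L)),
        bits         = .le_bytes_to_uint(matrix(body[15:16], ncol = 1L))
      )
    } else if (identical(chunk_id, "data")) {
      data_raw <- readBin(con, "raw", chunk_size)
      if (length(data_raw) < chunk_size) {
        stop(sprintf("truncated data chunk in '%s'", path), call. = FALSE)
      }
    } else {
      invisible(readBin(con, "raw", chunk_size + chunk_size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("truncated or corrupt WAV file (missing fmt/data): '%s'", path),
         call. = FALSE)
  }
  if (fmt$n_channels != 1) {
    stop(sprintf("'%s' has %d channels; down-mix to mono before reading",
                 path, fmt$n_channels), call. = FALSE)
  }
  bytes_per <- fmt$bits / 8
  n <- floor(length(data_raw) / bytes_per)
  data_raw <- data_raw[seq_len(n * bytes_per)]
  if (fmt$audio_format == 3) { # IEEE float
    samples <- readBin(data_raw, "double", n, size = bytes_per, endian = "little")
  } else if (fmt$audio_format == 1) { # integer PCM
    if (fmt$bits == 16) {
      samples <- readBin(data_raw, "integer", n, size = 2L, signed = TRUE,
                         endian = "little") / 2^15
    } else if (fmt$bits == 24) {
      m <- matrix(data_raw, nrow = 3L)
      u <- .le_bytes_to_uint(m)
      u <- ifelse(u >= 2^23, u - 2^24, u)
      samples <- u / 2^23
    } else if (fmt$bits == 32) {
      samples <- readBin(data_raw, "integer", n, size = 4L, endian = "little") / 2^31
    } else {
      stop(sprintf("unsupported PCM bit depth %d in '%s'", fmt$bits, path),
           call. = FALSE)
    }
  } else {
    stop(sprintf("unsupported WAV encoding (format tag %d) in '%s'",
                 fmt$audio_format, path), call. = FALSE)
  }
  waveform(samples, fmt$sample_rate)
}

#' Write a mono RIFF WAV file
#'
#' @param path Output path.
#' @param wave A [waveform].
#' @param bit_depth `"float32"` (default), `"pcm24"` or `"pcm16"`.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(path, wave, bit_depth = c("float32", "pcm24", "pcm16")) {
  bit_depth <- match.arg(bit_depth)
  x <- wave$samples
  fs <- as.integer(round(wave$sample_rate))
  spec <- switch(bit_depth,
                 float32 = list(fmt = 3L, bits = 32L),
                 pcm24   = list(fmt = 1L, bits = 24L),
                 pcm16   = list(fmt = 1L, bits = 16L))
  bytes_per <- spec$bits %/% 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(spec$fmt, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # mono
  writeBin(fs, con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(spec$bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == "float32") {
    writeBin(x, con, size = 4L, endian = "little")
  } else if (bit_depth == "pcm16") {
    q <- as.integer(pmax(pmin(round(x * 2^15), 2^15 - 1), -2^15))
    writeBin(q, con, size = 2L, endian = "little")
  } else { # pcm24
    q <- pmax(pmin(round(x * 2^23), 2^23 - 1), -2^23)
    q <- ifelse(q < 0, q + 2^24, q)
    b1 <- as.raw(q %% 256)
    b2 <- as.raw((q %/% 256) %% 256)
    b3 <- as.raw((q %/% 65536) %% 256)
    writeBin(as.vector(rbind(b1, b2, b3)), con)
  }
  invisible(path)
}

# milliseconds to samples, rounding halves up (5 ms @ 44.1 kHz -> 221)
.ms_to_samples <- function(ms, fs) floor(ms / 1000 * fs + 0.5)

.sel_required_cols <- c("Selection", "Begin Time (s)", "End Time (s)",
                        "Low Freq (Hz)", "High Freq (Hz)")

#' Read a Raven-style selection table
#'
#' Parses the tab-separated selection-table dialect used by the Raven sound
#' analysis software: a header row with (at least) the columns
#' `Selection`, `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)` and
#' `High Freq (Hz)` (matched case-sensitively). Any additional columns are
#' preserved as annotations.
#'
#' @param path Path to a tab-separated selection table.
#' @return A data frame of class `"selection_table"` with columns
#'   `selection_id`, `begin_time`, `end_time`, `low_freq`, `high_freq`, and
#'   one column per annotation.
#' @export
read_selection_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("selection table not found: '%s'", path), call. = FALSE)
  }
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(.sel_required_cols, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("selection table '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' of '%s' at data line %d",
                   col, path, bad[1L]), call. = FALSE)
    }
    v
  }
  out <- data.frame(
    selection_id = as.integer(num("Selection")),
    begin_time   = num("Begin Time (s)"),
    end_time     = num("End Time (s)"),
    low_freq     = num("Low Freq (Hz)"),
    high_freq    = num("High Freq (Hz)"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  extra <- setdiff(names(raw), .sel_required_cols)
  for (col in extra) out[[col]] <- raw[[col]]
  bad <- which(out$end_time <= out$begin_time)
  if (length(bad)) {
    stop(sprintf("selection %d has end_time <= begin_time", out$selection_id[bad[1L]]),
         call. = FALSE)
  }
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Write a Raven-style selection table
#'
#' @param path Output path.
#' @param table A `selection_table` (or data frame with the same columns).
#' @return Invisibly, `path`.
#' @export
write_selection_table <- function(path, table) {
  core <- data.frame(
    table$selection_id, table$begin_time, table$end_time,
    table$low_freq, table$high_freq,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(core) <- .sel_required_cols
  extra <- setdiff(names(table),
                   c("selection_id", "begin_time", "end_time",
                     "low_freq", "high_freq"))
  for (col in extra) core[[col]] <- table[[col]]
  utils::write.table(core, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract padded call clips from a recording
#'
#' Cuts one clip per selection out of a longer recording, adding `pad_ms`
#' of context on each side (clamped at the ends of the recording). The pad
#' is converted to samples by rounding to the nearest sample, so 5 ms at
#' 44.1 kHz becomes 221 samples.
#'
#' @param wave A [waveform] holding the full recording.
#' @param table A `selection_table` with begin/end times inside the recording.
#' @param pad_ms Padding on each side, in milliseconds (default 5).
#' @return A list of [waveform] clips, one per selection, named by
#'   `selection_id`.
#' @export
extract_clips <- function(wave, table, pad_ms = 5) {
  fs <- wave$sample_rate
  n <- length(wave$samples)
  pad <- .ms_to_samples(pad_ms, fs)
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    i0 <- round(table$begin_time[i] * fs) + 1L
    i1 <- round(table$end_time[i] * fs)
    if (i1 < 1L || i0 > n) {
      stop(sprintf("selection %d lies entirely outside the recording",
                   table$selection_id[i]), call. = FALSE)
    }
    a <- max(1L, i0 - pad)
    b <- min(n, i1 + pad)
    out[[i]] <- waveform(wave$samples[a:b], fs)
  }
  names(out) <- as.character(table$selection_id)
  out
}

#' Short-time Fourier power spectrogram
#'
#' Computes a one-sided power spectrogram with a 256-sample Hann window,
#' a 256-point FFT and a hop (advance) of 38 samples -- the standard
#' narrow-band setting for short flight-call clips at 44.1 kHz. Frames
#' that would run past the end of the signal are dropped (the signal body
#' is never zero-padded), so the frame count is
#' `floor((N - nfft)/hop) + 1`.
#'
#' @param wave A [waveform] of length at least `nfft` samples.
#' @param nfft FFT size and window length in samples (default 256).
#' @param hop Advance between consecutive windows in samples (default 38).
#' @return An object of class `"spectrogram"`: a list with `power`
#'   (`n_frames x n_bins` matrix of squared magnitudes), `times`
#'   (frame-centre seconds), `freqs` (bin-centre Hz), and `params`.
#' @export
compute_spectrogram <- function(wave, nfft = 256L, hop = 38L) {
  x <- wave$samples
  fs <- wave$sample_rate
  n <- length(x)
  if (n < nfft) {
    stop(sprintf("clip too short for spectrogram: %d samples < window of %d; provide at least one full window",
                 n, nfft), call. = FALSE)
  }
  n_frames <- (n - nfft) %/% hop + 1L
  win <- 0.5 * (1 - cos(2 * pi * seq(0L, nfft - 1L) / (nfft - 1L))) # Hann
  idx <- outer(seq_len(nfft), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(x[idx], nrow = nfft) * win
  spec <- stats::mvfft(frames)
  n_bins <- nfft %/% 2L + 1L
  power <- t(Mod(spec[seq_len(n_bins), , drop = FALSE])^2)
  structure(list(
    power = power,
    times = ((seq_len(n_frames) - 1L) * hop + nfft / 2) / fs,
    freqs = (seq_len(n_bins) - 1L) * fs / nfft,
    params = list(nfft = nfft, window = "hann", hop = hop, sample_rate = fs)
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frames x %d bins, hop %d, nfft %d @ %g Hz>\n",
              nrow(x$power), ncol(x$power), x$params$hop, x$params$nfft,
              x$params$sample_rate))
  invisible(x)
}
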