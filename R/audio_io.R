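#' Construct an audio recording
#'
#' The canonical in-memory representation of one subject's audio: a numeric
#' amplitude sequence in \[-1, 1\] with its sample rate, subject id and an
#' optional class label. Multi-channel audio is held as a samples-by-channels
#' matrix until [standardize_recording()] collapses it to mono.
#'
#' @param samples Numeric vector (mono) or matrix (samples x channels) of
#'   amplitudes in \[-1, 1\].
#' @param sample_rate_hz Positive integer sampling rate.
#' @param subject_id Subject identifier string.
#' @param label Optional class label, `"AD"` or `"NONAD"`.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate_hz, subject_id = "unknown",
                            label = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("samples must be a non-empty numeric vector or matrix", call. = FALSE)
  }
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0L) {
    stop("sample_rate_hz must be a positive integer", call. = FALSE)
  }
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("samples must lie in [-1, 1]", call. = FALSE)
  }
  assert_label(label)
  structure(
    list(subject_id = as.character(subject_id), samples = samples,
         sample_rate_hz = sample_rate_hz, label = label),
    class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<audio_recording> subject=%s label=%s %.2f s @ %d Hz (%d ch)\n",
              x$subject_id, x$label %||% "NA", n / x$sample_rate_hz,
              x$sample_rate_hz, ch))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE file with 8-, 16- or 32-bit integer PCM encoding and
#' scales amplitudes to \[-1, 1\]. The original sample rate is preserved;
#' multi-channel files come back as a samples-by-channels matrix.
#'
#' @param path Path to a PCM WAV file.
#' @param subject_id,label Passed to [audio_recording()].
#' @return An [audio_recording()].
#' @export
read_wav <- function(path, subject_id = basename(path), label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      break
    } else {
      seek(con, sz + sz %% 2, origin = "current")  # chunks are word-aligned
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("malformed WAV (missing fmt/data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L) {
    stop("unsupported WAV encoding (only integer PCM): ", path, call. = FALSE)
  }
  x <- switch(as.character(fmt$bits),
    "8" = (readBin(data_raw, "integer", length(data_raw), 1, signed = FALSE) -
             128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2L, 2,
                   endian = "little") / 32768,
    "32" = readBin(data_raw, "integer", length(data_raw) %/% 4L, 4,
                   endian = "little") / 2147483648,
    stop("unsupported PCM bit depth ", fmt$bits, ": ", path, call. = FALSE))
  if (fmt$n_channels > 1L) {
    x <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  }
  audio_recording(x, fmt$sample_rate, subject_id = subject_id, label = label)
}

#' Write a PCM 16-bit WAV file
#'
#' @param rec An [audio_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- rec$samples
  n_ch <- if (is.matrix(x)) ncol(x) else 1L
  if (is.matrix(x)) x <- as.vector(t(x))  # interleave channels
  # scale by 32768 (the int16 quantization step is 1/32768) and clip the
  # single unrepresentable value +1 -> 32767
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  data_size <- length(pcm) * 2L
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(rec$sample_rate_hz, con, size = 4, endian = "little")
  writeBin(rec$sample_rate_hz * n_ch * 2L, con, size = 4, endian = "little")
  writeBin(n_ch * 2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Standardize a recording to the canonical representation
#'
#' Collapses multi-channel audio to mono by channel averaging, resamples to
#' `target_rate_hz` and peak-normalizes so the maximum absolute amplitude is
#' 1 (all-zero input is returned unchanged apart from the rate, with a
#' warning). Idempotent: standardizing twice equals standardizing once.
#'
#' @param rec An [audio_recording()].
#' @param target_rate_hz Canonical sampling rate, default 16000 Hz.
#' @return A mono, peak-normalized [audio_recording()] at `target_rate_hz`.
#' @export
standardize_recording <- function(rec, target_rate_hz = 16000L) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- rec$samples
  if (is.matrix(x)) x <- rowMeans(x)
  if (rec$sample_rate_hz != target_rate_hz) {
    r <- ratio_pq(target_rate_hz, rec$sample_rate_hz)
    n_in <- length(x)
    x <- signal::resample(x, r[1], r[2])
    # resample() returns ceiling(n * p / q) samples; trim to the exact ratio
    n_exp <- floor(n_in * target_rate_hz / rec$sample_rate_hz)
    x <- x[seq_len(min(length(x), n_exp))]
  }
  peak <- max(abs(x))
  if (peak == 0) {
    warning("all-zero recording for subject ", rec$subject_id,
            "; skipping peak normalization", call. = FALSE)
  } else if (abs(peak - 1) > 1e-12) {
    x <- x / peak
  }
  audio_recording(x, target_rate_hz, subject_id = rec$subject_id,
                  label = rec$label)
}

len_mono <- function(rec) {
  if (is.matrix(rec$samples)) nrow(rec$samples) else length(rec$samples)
}

# Reduce target/source rate to the smallest integer p/q for resample().
ratio_pq <- function(p, q) {
  g <- gcd_int(p, q)
  c(p %/% g, q %/% g)
}
gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Read or write a corpus manifest
#'
#' A manifest is a CSV with header `subject_id,path,label,partition` listing
#' one recording per subject. `partition` may be empty until a train/test
#' split is assigned.
#'
#' @param path CSV path.
#' @return A `data.frame` with columns subject_id, path, label, partition.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest Manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(m) {
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$subject_id)) {
    stop("manifest subject_ids must be unique", call. = FALSE)
  }
  if (!all(m$label %in% .labels)) {
    stop("manifest labels must be in {AD, NONAD}", call. = FALSE)
  }
  if (is.null(m$partition)) m$partition <- ""
  m
}
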