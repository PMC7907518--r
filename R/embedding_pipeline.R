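# Log-mel front-end, pluggable 128-D embedder, and PCA whitening.
#
# Front-end geometry: 0.96 s patches at 16 kHz (15360 samples), 25 ms Hann
# window, 10 ms hop, 512-point FFT, 64 triangular mel filters spanning
# 125-7500 Hz on the HTK mel scale m = 2595 log10(1 + f/700). A 0.96 s
# segment is symmetrically zero-padded by 240 samples so the framer yields
# exactly 96 frames (96 hops of 160 need 15600 samples under a 400-sample
# window).

mel_window_s <- 0.025
mel_hop_s <- 0.010
mel_n_bands <- 64L
mel_fmin_hz <- 125
mel_fmax_hz <- 7500
mel_log_offset <- 0.01
mel_nfft <- 512L

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters with peaks equally spaced on the HTK mel scale between
#' `fmin_hz` and `fmax_hz`, evaluated on the positive-frequency bins of an
#' `nfft`-point FFT at `rate_hz`. Center frequencies are strictly increasing
#' and adjacent filters overlap so the band \[fmin, fmax\] is covered.
#'
#' @param rate_hz Sampling rate.
#' @param nfft FFT length.
#' @param n_bands Number of mel bands.
#' @param fmin_hz,fmax_hz Filterbank frequency range.
#' @return A `(nfft/2 + 1) x n_bands` matrix of filter weights, with the
#'   band center frequencies in Hz as attribute `"centers_hz"`.
#' @export
mel_filterbank <- function(rate_hz = 16000L, nfft = mel_nfft,
                           n_bands = mel_n_bands, fmin_hz = mel_fmin_hz,
                           fmax_hz = mel_fmax_hz) {
  n_bins <- nfft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1) * rate_hz / nfft
  edges_mel <- seq(hz_to_mel(fmin_hz), hz_to_mel(fmax_hz),
                   length.out = n_bands + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  fb <- matrix(0, n_bins, n_bands)
  for (b in seq_len(n_bands)) {
    lo <- edges_hz[b]; ctr <- edges_hz[b + 1L]; hi <- edges_hz[b + 2L]
    up <- (bin_hz - lo) / (ctr - lo)
    down <- (hi - bin_hz) / (hi - ctr)
    fb[, b] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- edges_hz[2:(n_bands + 1L)]
  fb
}

#' Compute the 96 x 64 log-mel patch of one segment
#'
#' @param seg One segment from [extract_patches()] (exactly 0.96 s at
#'   16 kHz, i.e. 15360 samples), or a bare numeric vector of that length.
#' @param rate_hz Sampling rate of the segment.
#' @return A 96 x 64 matrix of `log(mel energy + 0.01)` values.
#' @export
mel_patch <- function(seg, rate_hz = 16000L) {
  x <- if (is.list(seg)) seg$samples else seg
  expected <- round(0.96 * rate_hz)
  if (length(x) != expected) {
    stop("segment must be exactly 0.96 s at ", rate_hz, " Hz (",
         expected, " samples), got ", length(x), call. = FALSE)
  }
  win_len <- round(mel_window_s * rate_hz)   # 400
  hop <- round(mel_hop_s * rate_hz)          # 160
  n_frames <- 96L
  need <- win_len + (n_frames - 1L) * hop    # 15600
  pad <- need - length(x)
  x <- c(numeric(pad %/% 2L), x, numeric(pad - pad %/% 2L))
  # periodic Hann window
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_len) - 1) / win_len)
  idx <- outer(seq_len(win_len), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(x[idx], win_len, n_frames) * win
  frames <- rbind(frames, matrix(0, mel_nfft - win_len, n_frames))
  spec <- stats::mvfft(frames)[seq_len(mel_nfft %/% 2L + 1L), , drop = FALSE]
  power <- Re(spec)^2 + Im(spec)^2
  fb <- mel_filterbank(rate_hz)
  mel_e <- crossprod(power, fb)              # frames x bands
  log(mel_e + mel_log_offset)
}

#' Built-in deterministic surrogate embedder
#'
#' Maps a flattened 96 x 64 log-mel patch to 128 dimensions through a fixed
#' seeded Gaussian random projection followed by an elementwise tanh. It
#' stands behind the same embedder interface as a checkpoint-backed deep
#' embedding and is deterministic given its seed; it performs no learning.
#'
#' @param seed Seed fixing the projection.
#' @return An object of class `embedder` with a `$transform` function
#'   mapping a mel patch to a length-128 numeric vector.
#' @export
surrogate_embedder <- function(seed = 20L) {
  d_in <- 96L * 64L
  d_out <- 128L
  proj <- with_local_seed(seed, {
    matrix(stats::rnorm(d_in * d_out, sd = 1 / sqrt(d_in)), d_in, d_out)
  })
  custom_embedder(
    function(patch) as.numeric(tanh(crossprod(proj, as.vector(patch)))),
    name = sprintf("surrogate-rp-%d", seed))
}

#' Wrap any patch-to-vector function as an embedder
#'
#' The adapter point for checkpoint-backed embedders: any deterministic
#' function from a 96 x 64 mel patch to a length-128 numeric vector.
#'
#' @param fn Function taking a mel patch matrix, returning 128 numbers.
#' @param name Embedder name recorded in reports.
#' @return An object of class `embedder`.
#' @export
custom_embedder <- function(fn, name = "custom") {
  stopifnot(is.function(fn))
  structure(list(name = name, transform = fn), class = "embedder")
}

#' Embed one mel patch
#'
#' @param embedder An `embedder`.
#' @param patch A 96 x 64 mel patch.
#' @return Length-128 numeric vector.
#' @export
embed_patch <- function(embedder, patch) {
  stopifnot(inherits(embedder, "embedder"))
  v <- embedder$transform(patch)
  if (length(v) != 128L || !all(is.finite(v))) {
    stop("embedder '", embedder$name,
         "' must return 128 finite values", call. = FALSE)
  }
  v
}

#' Fit a PCA whitening transform
#'
#' Principal axes of the centered training vectors with per-component
#' variance rescaled to 1, so the transformed training data is white.
#'
#' @param vectors Numeric matrix, one embedding per row.
#' @param n_components Number of components to keep, default 128.
#' @return An object of class `whitening_model` with fields `mean`,
#'   `projection` (d x k) and `component_sd` (k).
#' @export
fit_whitening <- function(vectors, n_components = 128L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < n_components) {
    stop("need at least n_components = ", n_components,
         " vectors to fit whitening (got ", nrow(vectors),
         "); reduce n_components", call. = FALSE)
  }
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  sd_k <- pc$sdev[seq_len(n_components)]
  if (any(sd_k < 1e-10)) {
    stop("training vectors are rank-deficient: fewer than ", n_components,
         " linearly independent directions; reduce n_components",
         call. = FALSE)
  }
  structure(list(mean = pc$center,
                 projection = pc$rotation[, seq_len(n_components),
                                          drop = FALSE],
                 component_sd = sd_k),
            class = "whitening_model")
}

#' Apply a fitted whitening transform
#'
#' @param model A [fit_whitening()] result.
#' @param v A single embedding vector or a matrix of row vectors.
#' @return Whitened vector(s) with `n_components` columns.
#' @export
apply_whitening <- function(model, v) {
  if (!inherits(model, "whitening_model")) {
    stop("model must be a fitted whitening_model", call. = FALSE)
  }
  single <- is.null(dim(v))
  v <- if (single) matrix(v, nrow = 1L) else as.matrix(v)
  out <- sweep(v, 2L, model$mean) %*% model$projection
  out <- sweep(out, 2L, model$component_sd, `/`)
  if (single) as.numeric(out) else out
}

#' Write or read a feature matrix as CSV
#'
#' One row per segment: `subject_id`, `segment_index`, `label`, then the
#' 128 feature columns `f001`..`f128`, for inspection or external tooling.
#'
#' @param feats Result of [extract_features()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feats, path) {
  fm <- as.data.frame(feats$features)
  names(fm) <- sprintf("f%03d", seq_len(ncol(fm)))
  utils::write.csv(cbind(feats$meta, fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f\\d+$", names(df))
  list(features = as.matrix(df[, fcols]),
       meta = df[, setdiff(seq_along(df), fcols), drop = FALSE])
}

#' Extract per-segment embedding features from recordings
#'
#' Composes patch extraction, the log-mel front-end and the embedder; rows
#' are ordered by (subject, segment index). Whitening is applied only when a
#' fitted model is supplied — that model must have been fitted on training
#' subjects only.
#'
#' @param recs List of standardized [audio_recording()]s.
#' @param embedder An `embedder`, default the built-in surrogate.
#' @param whitening Optional [fit_whitening()] model.
#' @param patch_duration_s Patch length in seconds.
#' @return List with `features` (n_segments x 128 matrix) and `meta`
#'   (data.frame with subject_id, segment_index, label per row).
#' @export
extract_features <- function(recs, embedder = surrogate_embedder(),
                             whitening = NULL, patch_duration_s = 0.96) {
  if (length(recs) == 0L) stop("no recordings supplied", call. = FALSE)
  rows <- list()
  meta <- list()
  for (rec in recs) {
    for (seg in extract_patches(rec, patch_duration_s)) {
      rows[[length(rows) + 1L]] <-
        embed_patch(embedder, mel_patch(seg, rec$sample_rate_hz))
      meta[[length(meta) + 1L]] <-
        data.frame(subject_id = seg$subject_id, segment_index = seg$index,
                   label = seg$label %||% NA_character_,
                   stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  if (!is.null(whitening)) features <- apply_whitening(whitening, features)
  list(features = features, meta = do.call(rbind, meta))
}
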