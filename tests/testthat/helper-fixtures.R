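# Shared fixtures, all generated in code.

# A pure sine recording.
sine_recording <- function(freq_hz, duration_s, rate_hz = 16000L,
                           amplitude = 1, subject_id = "tone") {
  n <- round(duration_s * rate_hz)
  audio_recording(amplitude * sin(2 * pi * freq_hz * (seq_len(n) - 1) /
                                    rate_hz),
                  rate_hz, subject_id = subject_id)
}

# Energy-threshold silence detector used as an independent oracle for the
# pause structure of generated speech: fraction of 10 ms windows whose mean
# square is below the threshold.
silent_fraction <- function(x, rate_hz = 16000L, win_s = 0.01,
                            threshold = 1e-4) {
  w <- round(win_s * rate_hz)
  n <- (length(x) %/% w) * w
  m <- colMeans(matrix(x[seq_len(n)]^2, w))
  mean(m < threshold)
}

# Small two-Gaussian feature cloud embedded in 128-D; sep is the distance
# between the class means in units of the within-class sd.
gaussian_cloud <- function(n_per_class, sep, seed = 1L, d = 128L) {
  withr::with_seed(seed, {
    shift <- c(rep(sep / sqrt(2), 2L), rep(0, d - 2L))
    X <- rbind(
      matrix(rnorm(n_per_class * d), n_per_class, d) +
        rep(shift, each = n_per_class),
      matrix(rnorm(n_per_class * d), n_per_class, d) -
        rep(shift, each = n_per_class))
    list(X = X, y = rep(c("AD", "NONAD"), each = n_per_class))
  })
}

# A tiny prepared DemCNN configuration for fast unit tests (same code path
# as the default geometry, much smaller tensors).
tiny_demcnn_config <- function(seed = 1L, input_len = 512L) {
  demcnn_config(
    input_len = input_len,
    blocks = data.frame(out_channels = c(4L, 4L, 8L, 8L, 8L, 8L),
                        kernel = 5L, stride = 2L,
                        dropout = c(0.05, 0.05, 0.05, 0.05, 0.2, 0.2)),
    seed = seed)
}
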