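test_that("decimation by (4,4,2) yields the exact length/rate and its filters pass 50 Hz but kill 1 kHz", {
  rec <- audio_recording(sin(2 * pi * 50 * (0:31999) / 16000), 16000, "t50")
  d <- decimate_recording(rec)
  expect_length(d$samples, 1000)
  expect_equal(d$sample_rate_hz, 500L)
  # passband oracle: FFT peak amplitude within 1 dB (interior, away from
  # filtfilt edge transients)
  mid <- d$samples[101:900]
  amp <- 2 * max(Mod(fft(mid))) / length(mid)
  expect_lt(abs(20 * log10(amp / 1)), 1)

  rec2 <- audio_recording(sin(2 * pi * 1000 * (0:31999) / 16000), 16000, "t1k")
  d2 <- decimate_recording(rec2)
  atten_db <- 10 * log10(sum(d2$samples^2) / (sum(rec2$samples^2) / 32))
  expect_lt(atten_db, -40)

  expect_error(decimate_recording(audio_recording(rep(0.1, 20), 16000, "x")),
               "too short")
})

test_that("prepare_input center-crops and symmetrically zero-pads", {
  expect_identical(prepare_input(1:16 / 16, 16L), 1:16 / 16)
  expect_identical(prepare_input((1:10) / 10, 16L),
                   c(0, 0, 0, (1:10) / 10, 0, 0, 0))
  expect_identical(prepare_input((1:20) / 20, 16L), (3:18) / 20)
})

test_that("the network has the contracted output head and seeded deterministic weights", {
  cfg <- tiny_demcnn_config(seed = 4)
  m <- build_demcnn(cfg)
  x <- withr::with_seed(1, rnorm(512))
  p <- forward_scores(m, x)
  expect_equal(dim(p), c(1L, 2L))
  expect_equal(sum(p), 1, tolerance = 1e-9)

  m2 <- build_demcnn(tiny_demcnn_config(seed = 4))
  expect_identical(m$params, m2$params)
  m3 <- build_demcnn(tiny_demcnn_config(seed = 5))
  expect_false(identical(m$params$W1, m3$params$W1))

  bad_blocks <- data.frame(out_channels = rep(4L, 5), kernel = 5L,
                           stride = 2L, dropout = c(0.1, 0.1, 0.1, 0.3, 0.3))
  expect_error(demcnn_config(blocks = bad_blocks), "6 conv blocks")
  flat <- data.frame(out_channels = rep(4L, 6), kernel = 5L, stride = 2L,
                     dropout = rep(0.1, 6))
  expect_error(demcnn_config(blocks = flat), "dropout")
})

test_that("inference probabilities are valid, repeatable and shape-checked", {
  m <- build_demcnn(tiny_demcnn_config(seed = 2))
  X <- withr::with_seed(3, matrix(rnorm(3 * 512), 3, 512))
  p1 <- forward_scores(m, X)
  expect_equal(dim(p1), c(3L, 2L))
  expect_identical(p1, forward_scores(m, X))  # dropout off at inference
  expect_error(forward_scores(m, matrix(0, 1, 100)), "length")

  fuzz <- withr::with_seed(9, matrix(rnorm(100 * 512, sd = 3), 100, 512))
  pf <- forward_scores(m, fuzz)
  expect_true(all(is.finite(pf)) && all(pf >= 0) && all(pf <= 1))
  expect_equal(rowSums(pf), rep(1, 100), tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences on a tiny network", {
  blocks <- data.frame(out_channels = c(3L, 4L, 4L, 5L, 5L, 6L), kernel = 5L,
                       stride = 2L, dropout = c(0, 0, 0, 0, 1e-4, 1e-4))
  m <- build_demcnn(demcnn_config(input_len = 512L, blocks = blocks,
                                  seed = 7))
  X <- withr::with_seed(2, matrix(rnorm(2 * 512), 2, 512))
  y01 <- c(0L, 1L)
  loss_at <- function(mm) withr::with_seed(99,
    demscreen:::demcnn_fwd_bwd(mm, X, y01)$loss)
  res <- withr::with_seed(99, demscreen:::demcnn_fwd_bwd(m, X, y01))
  eps <- 1e-5
  for (nm in c("W1", "W4", "W6", "gamma2", "beta5", "b3", "Wd", "bd")) {
    idx <- withr::with_seed(nchar(nm) + match(nm, names(res$grads)),
                            sample(seq_along(res$grads[[nm]]),
                                   min(4, length(res$grads[[nm]]))))
    for (i in idx) {
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      rel <- abs(num - res$grads[[nm]][i]) /
        max(1e-8, abs(num) + abs(res$grads[[nm]][i]))
      expect_lt(rel, 1e-3)
    }
  }
})

test_that("two-step training follows the schedule, logs history and is deterministic", {
  cfg <- tiny_demcnn_config(seed = 6, input_len = 256L)
  sched <- train_schedule(step1_lr = 0.05, step1_cycles = 2,
                          step1_cycle_len = 2, step2_lr = 0.005,
                          step2_cycles = 1, step2_cycle_len = 3)
  dat <- withr::with_seed(8, {
    X <- rbind(matrix(rnorm(4 * 256, mean = 0.5, sd = 0.3), 4, 256),
               matrix(rnorm(4 * 256, mean = -0.5, sd = 0.3), 4, 256))
    list(X = pmin(pmax(X, -1), 1), y = rep(c("AD", "NONAD"), each = 4))
  })
  f1 <- fit_two_step(build_demcnn(cfg), dat$X, dat$y, sched, seed = 2)
  expect_equal(nrow(f1$history), 2 * 2 + 1 * 3)
  expect_equal(f1$history$step, rep(1:2, c(4, 3)))
  expect_equal(unique(f1$history$lr), c(0.05, 0.005))
  expect_equal(f1$selected_lr, 0.005)
  f2 <- fit_two_step(build_demcnn(cfg), dat$X, dat$y, sched, seed = 2)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-12)
  expect_identical(f1$model$params, f2$model$params)
  expect_error(fit_two_step(build_demcnn(cfg), dat$X, rep("AD", 8), sched),
               "both AD and NONAD")
})

test_that("training divergence raises a condition carrying the finite history", {
  cfg <- tiny_demcnn_config(seed = 1, input_len = 256L)
  dat <- withr::with_seed(4, matrix(rnorm(4 * 256, sd = 0.5), 4, 256))
  # batch norm makes the net nearly scale-invariant, so only an
  # overflow-level rate drives the loss non-finite
  sched <- train_schedule(step1_lr = 1e200, step1_cycles = 1,
                          step1_cycle_len = 4, step2_lr = 1,
                          step2_cycles = 1, step2_cycle_len = 1)
  err <- tryCatch(
    fit_two_step(build_demcnn(cfg), dat, c("AD", "AD", "NONAD", "NONAD"),
                 sched, seed = 1),
    demscreen_divergence = function(e) e)
  expect_s3_class(err, "demscreen_divergence")
  expect_true(is.data.frame(err$history))
  expect_true(all(is.finite(err$history$loss)))
})
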