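test_that("log-mel patches have the exact 96 x 64 geometry", {
  seg <- extract_patches(sine_recording(440, 0.96))[[1]]
  m <- mel_patch(seg)
  expect_equal(dim(m), c(96L, 64L))
  expect_true(all(is.finite(m)))
  expect_error(mel_patch(numeric(1000)), "0.96 s")
})

test_that("an all-zero segment maps to the log offset and a tone to its nearest band", {
  z <- mel_patch(numeric(15360))
  expect_true(all(z == log(0.01)))

  centers <- attr(mel_filterbank(), "centers_hz")
  for (f in c(250, 1000, 3000)) {
    m <- mel_patch(sin(2 * pi * f * (0:15359) / 16000))
    expect_equal(which.max(colMeans(m)), which.min(abs(centers - f)))
  }
})

test_that("mel filterbank centers increase and the filters cover the band", {
  fb <- mel_filterbank()
  centers <- attr(fb, "centers_hz")
  expect_true(all(diff(centers) > 0))
  expect_true(centers[1] > 125 && centers[64] < 7500)
  bin_hz <- (0:256) * 16000 / 512
  covered <- bin_hz > centers[1] & bin_hz < centers[64]
  expect_true(all(rowSums(fb)[covered] > 0))
})

test_that("the surrogate embedder is a deterministic, discriminating 128-D map", {
  emb <- surrogate_embedder(seed = 20)
  p1 <- withr::with_seed(1, matrix(rnorm(96 * 64), 96, 64))
  v1 <- embed_patch(emb, p1)
  expect_length(v1, 128)
  expect_identical(v1, embed_patch(emb, p1))
  expect_identical(v1, embed_patch(surrogate_embedder(seed = 20), p1))
  # patches differing in a single frame map to different vectors
  for (i in 1:10) {
    p2 <- p1
    p2[i, ] <- p2[i, ] + withr::with_seed(100 + i, rnorm(64))
    expect_false(identical(v1, embed_patch(emb, p2)))
  }
  bad <- custom_embedder(function(p) rep(1, 5))
  expect_error(embed_patch(bad, p1), "128")
})

test_that("whitening makes seeded Gaussian data unit-variance and centers to zero", {
  V <- withr::with_seed(11, matrix(rnorm(500 * 128,
                                         sd = rep(seq(0.3, 3, length.out = 128),
                                                  each = 500)), 500, 128))
  w <- fit_whitening(V)
  tv <- apply(apply_whitening(w, V), 2, var)
  expect_true(all(tv > 0.9 & tv < 1.1))
  expect_equal(apply_whitening(w, w$mean), rep(0, 128))
  expect_error(fit_whitening(V[1:100, ]), "n_components")
  expect_error(apply_whitening(list(), V[1, ]), "whitening_model")
})

test_that("whitening is an affine map and preserves the 128 dimension", {
  V <- withr::with_seed(2, matrix(rnorm(300 * 128), 300, 128))
  w <- fit_whitening(V)
  for (i in 1:5) {
    ab <- withr::with_seed(40 + i, matrix(rnorm(2 * 128), 2, 128))
    lhs <- apply_whitening(w, ab[1, ]) + apply_whitening(w, ab[2, ])
    rhs <- apply_whitening(w, ab[1, ] + ab[2, ] - w$mean)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_length(apply_whitening(w, V[3, ]), 128)
})

test_that("low-rank data whitens with zero reconstruction error in the kept components", {
  base <- withr::with_seed(5, matrix(rnorm(2 * 128), 2, 128))
  coef <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  pts <- coef %*% base
  w <- fit_whitening(pts, n_components = 2)
  z <- apply_whitening(w, pts)
  recon <- z %*% (t(w$projection) * w$component_sd) +
    rep(w$mean, each = 3)
  expect_equal(recon, pts, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("feature matrices round-trip through CSV", {
  recs <- list(standardize_recording(
    generate_recording(default_profiles()$ad, 2, "sX", "AD", seed = 3)))
  f <- extract_features(recs)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_features(f, tmp)
  back <- read_features(tmp)
  expect_equal(back$features, f$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$meta$subject_id, f$meta$subject_id)
  expect_equal(back$meta$label, f$meta$label)
})

test_that("extract_features composes the pipeline deterministically with aligned metadata", {
  recs <- list(
    standardize_recording(generate_recording(default_profiles()$ad, 3,
                                             "sA", "AD", seed = 1)),
    standardize_recording(generate_recording(default_profiles()$nonad, 2,
                                             "sB", "NONAD", seed = 2)))
  f1 <- extract_features(recs)
  expect_equal(nrow(f1$features), 3 + 2)   # floor(3 / 0.96) + floor(2 / 0.96)
  expect_equal(ncol(f1$features), 128)
  expect_equal(f1$meta$subject_id, c(rep("sA", 3), rep("sB", 2)))
  expect_equal(f1$meta$label, c(rep("AD", 3), rep("NONAD", 2)))
  f2 <- extract_features(recs)
  expect_identical(f1, f2)
  expect_error(extract_features(list()), "no recordings")
})
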