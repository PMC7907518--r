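test_that("all five classifiers separate well-separated clouds and stay at chance on coincident ones", {
  sep <- gaussian_cloud(200, sep = 6, seed = 1)
  same <- gaussian_cloud(200, sep = 0, seed = 2)
  test <- gaussian_cloud(200, sep = 6, seed = 3)
  null_test <- gaussian_cloud(200, sep = 0, seed = 4)
  for (kind in c("SVM_RBF", "LINEAR_SVM", "PERCEPTRON", "MLP", "NN1")) {
    m <- train_segment_classifier(sep$X, sep$y, classifier_spec(kind, seed = 5))
    acc <- mean(predict_segments(m, test$X) == test$y)
    expect_gte(acc, 0.95)
    m0 <- train_segment_classifier(same$X, same$y,
                                   classifier_spec(kind, seed = 5))
    acc0 <- mean(predict_segments(m0, null_test$X) == null_test$y)
    # 3 binomial SDs around chance for n = 400 decisions
    expect_lt(abs(acc0 - 0.5), 3 * sqrt(0.25 / 400))
  }
})

test_that("training is deterministic given the spec seed and validates its inputs", {
  cloud <- gaussian_cloud(50, sep = 2, seed = 9)
  for (kind in c("PERCEPTRON", "MLP")) {
    m1 <- train_segment_classifier(cloud$X, cloud$y,
                                   classifier_spec(kind, seed = 3))
    m2 <- train_segment_classifier(cloud$X, cloud$y,
                                   classifier_spec(kind, seed = 3))
    expect_identical(m1$fit, m2$fit)
  }
  expect_error(train_segment_classifier(cloud$X, rep("AD", 100),
                                        classifier_spec("NN1")),
               "both classes")
  m <- train_segment_classifier(cloud$X, cloud$y, classifier_spec("NN1"))
  expect_error(predict_segments(m, cloud$X[, 1:10]), "width")
  expect_error(predict_segments(list(), cloud$X), "segment_model")
})

test_that("the perceptron converges to zero training error on separable data", {
  cloud <- gaussian_cloud(100, sep = 8, seed = 12)
  m <- train_segment_classifier(cloud$X, cloud$y,
                                classifier_spec("PERCEPTRON", seed = 1))
  expect_equal(mean(predict_segments(m, cloud$X) == cloud$y), 1)
})

test_that("1-NN memorizes training points and follows the cosine definition", {
  a <- c(1, rep(0, 127)); b <- c(0, 1, rep(0, 126))
  m <- train_segment_classifier(rbind(a, b), c("AD", "NONAD"),
                                classifier_spec("NN1"))
  q <- c(0.9, 0.1, rep(0, 126)) # cosine-closer to a
  expect_equal(predict_segments(m, rbind(q)), "AD")
  expect_equal(predict_segments(m, rbind(a, b)), c("AD", "NONAD"))

  cloud <- gaussian_cloud(40, sep = 1, seed = 6)
  m2 <- train_segment_classifier(cloud$X, cloud$y, classifier_spec("NN1"))
  expect_equal(predict_segments(m2, cloud$X), cloud$y)
})

test_that("1-NN agrees with an independent brute-force cosine scan", {
  cos_dist <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) 2 else 1 - sum(u * v) / (nu * nv)
  }
  for (case in 1:200) {
    dat <- withr::with_seed(case, {
      n <- sample(2:8, 1)
      list(X = matrix(rnorm(n * 128), n, 128),
           y = c("AD", "NONAD", sample(c("AD", "NONAD"), n - 2,
                                       replace = TRUE)),
           q = matrix(rnorm(3 * 128), 3, 128))
    })
    m <- train_segment_classifier(dat$X, dat$y, classifier_spec("NN1"))
    got <- predict_segments(m, dat$q)
    want <- apply(dat$q, 1, function(q) {
      d <- apply(dat$X, 1, cos_dist, u = q)
      dat$y[which.min(d)]
    })
    expect_equal(got, want)
  }
})

test_that("the MLP runs its SGD budget deterministically with width-20 hidden layer", {
  cloud <- gaussian_cloud(60, sep = 4, seed = 21)
  spec <- classifier_spec("MLP", seed = 8)
  expect_equal(spec$hyperparameters$hidden, 20L)
  expect_equal(spec$hyperparameters$iterations, 600L)
  expect_equal(spec$hyperparameters$learning_rate, 0.001)
  m <- train_segment_classifier(cloud$X, cloud$y, spec)
  expect_equal(dim(m$fit$W1), c(128L, 20L))
  expect_identical(
    m$fit, train_segment_classifier(cloud$X, cloud$y, spec)$fit)
})
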