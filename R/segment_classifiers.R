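# Five segment-level classifiers on 128-D features: RBF SVM (scale-heuristic
# bandwidth), linear SVM, perceptron, an SGD-trained MLP (one hidden layer of
# width 20, 600 iterations, step 0.001) and cosine 1-NN. The SVMs go through
# e1071/libsvm; perceptron, MLP and 1-NN are implemented here (no installed
# package trains an MLP by plain SGD or does cosine 1-NN). Every decision tie
# breaks toward NONAD.

classifier_kinds <- c("SVM_RBF", "LINEAR_SVM", "PERCEPTRON", "MLP", "NN1")

#' Specify a segment classifier
#'
#' @param kind One of `"SVM_RBF"`, `"LINEAR_SVM"`, `"PERCEPTRON"`, `"MLP"`,
#'   `"NN1"`.
#' @param hyperparameters Named list overriding the kind-specific defaults:
#'   SVM_RBF/LINEAR_SVM `cost` (1); MLP `hidden` (20), `iterations` (600),
#'   `learning_rate` (0.001), `batch_size` (200); PERCEPTRON `max_epochs`
#'   (100). SVM_RBF's bandwidth uses the scale heuristic
#'   `gamma = 1 / (d * var(X))`.
#' @param seed Seed for any training-time randomness (shuffling, init).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind, hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind, classifier_kinds)
  defaults <- switch(kind,
    SVM_RBF = list(cost = 1),
    LINEAR_SVM = list(cost = 1),
    PERCEPTRON = list(max_epochs = 100L),
    MLP = list(hidden = 20L, iterations = 600L, learning_rate = 0.001,
               batch_size = 200L),
    NN1 = list())
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train a segment-level classifier
#'
#' @param features Numeric matrix, one 128-D feature row per segment.
#' @param labels Class labels (`"AD"`/`"NONAD"`), one per row.
#' @param spec A [classifier_spec()].
#' @return An object of class `segment_model`.
#' @export
train_segment_classifier <- function(features, labels, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  y <- as_label_factor(labels)
  if (anyNA(y)) stop("labels must be in {AD, NONAD}", call. = FALSE)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (nrow(features) != length(y)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$kind,
    SVM_RBF = {
      gam <- 1 / (ncol(features) * stats::var(as.vector(features)))
      with_local_seed(spec$seed,
        e1071::svm(features, y, kernel = "radial", gamma = gam,
                   cost = hp$cost, scale = FALSE))
    },
    LINEAR_SVM = with_local_seed(spec$seed,
      e1071::svm(features, y, kernel = "linear", cost = hp$cost,
                 scale = FALSE)),
    PERCEPTRON = fit_perceptron(features, y, hp$max_epochs, spec$seed),
    MLP = fit_mlp_sgd(features, y, hp, spec$seed),
    NN1 = list(exemplars = features, labels = y))
  structure(list(spec = spec, fit = fit, n_features = ncol(features),
                 classes = .labels),
            class = "segment_model")
}

#' Predict segment labels
#'
#' @param model A trained [train_segment_classifier()] model.
#' @param features Feature matrix with the training width.
#' @return Character vector of labels, one per row.
#' @export
predict_segments <- function(model, features) {
  if (!inherits(model, "segment_model")) {
    stop("model must be a trained segment_model", call. = FALSE)
  }
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop("feature width ", ncol(features), " does not match training width ",
         model$n_features, call. = FALSE)
  }
  out <- switch(model$spec$kind,
    SVM_RBF = ,
    LINEAR_SVM = as.character(predict(model$fit, features)),
    PERCEPTRON = predict_perceptron(model$fit, features),
    MLP = predict_mlp(model$fit, features),
    NN1 = predict_nn1(model$fit, features))
  unname(out)
}

# --- perceptron (Rosenblatt rule, tie -> NONAD) ---------------------------

fit_perceptron <- function(X, y, max_epochs, seed) {
  ypm <- ifelse(y == "AD", 1, -1)
  w <- numeric(ncol(X))
  b <- 0
  with_local_seed(seed, {
    for (ep in seq_len(max_epochs)) {
      mistakes <- 0L
      for (i in sample.int(nrow(X))) {
        if (ypm[i] * (sum(w * X[i, ]) + b) <= 0) {
          w <- w + ypm[i] * X[i, ]
          b <- b + ypm[i]
          mistakes <- mistakes + 1L
        }
      }
      if (mistakes == 0L) break
    }
  })
  list(w = w, b = b)
}

predict_perceptron <- function(fit, X) {
  s <- as.vector(X %*% fit$w) + fit$b
  ifelse(s > 0, "AD", "NONAD")
}

# --- MLP: one hidden ReLU layer, logistic output, minibatch SGD -----------

fit_mlp_sgd <- function(X, y, hp, seed) {
  d <- ncol(X); h <- hp$hidden
  t01 <- as.numeric(y == "AD")
  with_local_seed(seed, {
    W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
    b1 <- numeric(h)
    w2 <- stats::rnorm(h, sd = sqrt(1 / h))
    b2 <- 0
    n <- nrow(X)
    bs <- min(hp$batch_size, n)
    for (it in seq_len(hp$iterations)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        H <- pmax(Xb %*% W1 + rep(b1, each = length(idx)), 0)
        p <- stats::plogis(as.vector(H %*% w2) + b2)
        g <- (p - t01[idx]) / length(idx)          # dLoss/dlogit
        gw2 <- as.vector(crossprod(H, g))
        gH <- outer(g, w2) * (H > 0)
        lr <- hp$learning_rate
        W1 <- W1 - lr * crossprod(Xb, gH)
        b1 <- b1 - lr * colSums(gH)
        w2 <- w2 - lr * gw2
        b2 <- b2 - lr * sum(g)
      }
    }
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  })
}

predict_mlp <- function(fit, X) {
  H <- pmax(X %*% fit$W1 + rep(fit$b1, each = nrow(X)), 0)
  s <- as.vector(H %*% fit$w2) + fit$b2
  ifelse(s > 0, "AD", "NONAD")  # logistic score > 0 <=> p > 0.5
}

# --- cosine 1-NN ----------------------------------------------------------

# Cosine distance = 1 - cosine similarity; zero vectors get maximal
# distance 2. Distance ties break toward NONAD.
predict_nn1 <- function(fit, X) {
  Xn <- sqrt(rowSums(X^2))
  En <- sqrt(rowSums(fit$exemplars^2))
  sim <- (X %*% t(fit$exemplars)) / outer(Xn, En)
  sim[!is.finite(sim)] <- -1  # zero-norm vector => distance 2
  dist <- 1 - sim
  apply(dist, 1L, function(d) {
    tied <- which(d <= min(d) + 1e-12)
    lab <- as.character(fit$labels[tied])
    if ("NONAD" %in% lab && length(unique(lab)) > 1L) "NONAD" else lab[1L]
  })
}
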