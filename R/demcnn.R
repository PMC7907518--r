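# DemCNN: raw-waveform dementia classifier.
#
# Front-end: stagewise anti-aliased decimation (zero-phase low-pass at 0.9 x
# the new Nyquist, then keep every f-th sample) by factors (4, 4, 2), i.e.
# 16 kHz -> 500 Hz, followed by center-crop/zero-pad to a fixed input length
# (default 2^14 = 16384 samples, about 32.8 s at 500 Hz).
#
# Network: six blocks of [conv1d -> ReLU -> batch norm -> dropout], then
# global average pooling over time and a dense layer with 2 outputs trained
# with softmax cross-entropy. Convolutions are evaluated as im2col gathers
# followed by BLAS matrix products; a whole batch is stacked along the
# position axis so batch statistics for the batch-norm layers fall out of
# column means. All training is plain SGD.

#' DemCNN architecture configuration
#'
#' @param decimation_factors Integer decimation factors applied stagewise,
#'   default `c(4, 4, 2)` (composite factor 32).
#' @param input_len Fixed post-decimation input length in samples, default
#'   `2^14 = 16384`.
#' @param blocks Data frame with one row per conv block and columns
#'   `out_channels`, `kernel`, `stride`, `dropout`. Exactly 6 blocks; the
#'   dropout of blocks 5-6 must exceed that of blocks 1-4 (the larger late
#'   dropout is what keeps train and test accuracy close).
#' @param num_labels Number of output nodes; fixed at 2.
#' @param seed Seed for weight initialization.
#' @return An object of class `demcnn_config`.
#' @export
demcnn_config <- function(decimation_factors = c(4L, 4L, 2L),
                          input_len = 16384L,
                          blocks = default_demcnn_blocks(),
                          num_labels = 2L, seed = 1L) {
  stopifnot(all(decimation_factors >= 1), input_len > 0)
  if (nrow(blocks) != 6L) {
    stop("DemCNN has exactly 6 conv blocks, got ", nrow(blocks),
         call. = FALSE)
  }
  if (num_labels != 2L) stop("num_labels is fixed at 2", call. = FALSE)
  if (min(blocks$dropout[5:6]) <= max(blocks$dropout[1:4])) {
    stop("dropout of blocks 5-6 must exceed that of blocks 1-4",
         call. = FALSE)
  }
  structure(list(decimation_factors = as.integer(decimation_factors),
                 input_len = as.integer(input_len), blocks = blocks,
                 num_labels = 2L, seed = as.integer(seed)),
            class = "demcnn_config")
}

#' @rdname demcnn_config
#' @export
default_demcnn_blocks <- function() {
  data.frame(out_channels = c(16L, 32L, 32L, 64L, 64L, 128L),
             kernel = 9L, stride = 2L,
             dropout = c(0.1, 0.1, 0.1, 0.1, 0.3, 0.3))
}

#' Anti-aliased stagewise decimation
#'
#' For each factor `f`: low-pass at 0.9 x the new Nyquist with a zero-phase
#' 8th-order Butterworth filter (applied forward and backward, so the
#' effective attenuation is squared and no group delay is introduced), then
#' keep every `f`-th sample. The output rate is the input rate divided by
#' the product of the factors.
#'
#' @param rec A standardized [audio_recording()].
#' @param factors Integer decimation factors.
#' @return The decimated [audio_recording()].
#' @export
decimate_recording <- function(rec, factors = c(4L, 4L, 2L)) {
  stopifnot(inherits(rec, "audio_recording"), !is.matrix(rec$samples))
  x <- rec$samples
  rate <- rec$sample_rate_hz
  for (f in factors) {
    f <- as.integer(f)
    if (f == 1L) next
    if (length(x) <= 27L) {  # filtfilt needs > 3 x filter order
      stop("recording too short to decimate (", length(x), " samples)",
           call. = FALSE)
    }
    bf <- signal::butter(8, 0.9 / f, type = "low")
    x <- signal::filtfilt(bf, x)
    n_keep <- (length(x) %/% f) * f
    x <- x[seq.int(1L, n_keep, by = f)]
    rate <- rate %/% f
  }
  x <- pmax(-1, pmin(1, x))  # filtering can overshoot the unit interval
  audio_recording(x, rate, subject_id = rec$subject_id, label = rec$label)
}

#' Fix a decimated waveform to the network input length
#'
#' Center-crops when longer than `input_len`, symmetrically zero-pads when
#' shorter (left pad is the floor of the deficit halved).
#'
#' @param x Numeric vector (or [audio_recording()], whose samples are used).
#' @param input_len Target length.
#' @return Numeric vector of exactly `input_len` samples.
#' @export
prepare_input <- function(x, input_len = 16384L) {
  if (inherits(x, "audio_recording")) x <- x$samples
  n <- length(x)
  if (n == input_len) return(x)
  if (n > input_len) {
    start <- (n - input_len) %/% 2L
    x[start + seq_len(input_len)]
  } else {
    left <- (input_len - n) %/% 2L
    c(numeric(left), x, numeric(input_len - n - left))
  }
}

#' Decimate and length-normalize a set of recordings
#'
#' @param recs List of standardized [audio_recording()]s (or recordings
#'   already at the decimated rate, which skips the filter stage).
#' @param config A [demcnn_config()].
#' @return A `length(recs) x input_len` matrix, one prepared waveform per
#'   row, with subject ids as rownames.
#' @export
demcnn_prepare_batch <- function(recs, config = demcnn_config()) {
  X <- t(vapply(recs, function(r) {
    d <- if (prod(config$decimation_factors) > 1 &&
             r$sample_rate_hz > 16000 %/% prod(config$decimation_factors))
      decimate_recording(r, config$decimation_factors) else r
    prepare_input(d$samples, config$input_len)
  }, numeric(config$input_len)))
  rownames(X) <- vapply(recs, `[[`, "", "subject_id")
  X
}

# ---- geometry and parameter initialization -------------------------------

conv_out_len <- function(L, K, S) (L - K) %/% S + 1L

demcnn_geometry <- function(config) {
  L <- config$input_len
  C <- 1L
  geo <- vector("list", 6L)
  for (b in seq_len(6L)) {
    blk <- config$blocks[b, ]
    P <- conv_out_len(L, blk$kernel, blk$stride)
    if (P < 1L) stop("input too short for block ", b, call. = FALSE)
    geo[[b]] <- list(L_in = L, C_in = C, K = blk$kernel, S = blk$stride,
                     C_out = blk$out_channels, P = P,
                     dropout = blk$dropout)
    L <- P
    C <- blk$out_channels
  }
  geo
}

#' Build a DemCNN model with seeded initial weights
#'
#' He-initialized convolution weights, unit batch-norm scales and a small
#' dense head; identical config and seed give bit-identical weights.
#'
#' @param config A [demcnn_config()].
#' @return An object of class `demcnn_model`.
#' @export
build_demcnn <- function(config = demcnn_config()) {
  stopifnot(inherits(config, "demcnn_config"))
  geo <- demcnn_geometry(config)
  params <- with_local_seed(config$seed, {
    p <- list()
    for (b in seq_len(6L)) {
      g <- geo[[b]]
      fan_in <- g$K * g$C_in
      p[[paste0("W", b)]] <- matrix(
        stats::rnorm(fan_in * g$C_out, sd = sqrt(2 / fan_in)),
        fan_in, g$C_out)
      p[[paste0("b", b)]] <- numeric(g$C_out)
      p[[paste0("gamma", b)]] <- rep(1, g$C_out)
      p[[paste0("beta", b)]] <- numeric(g$C_out)
      p[[paste0("rmean", b)]] <- numeric(g$C_out)
      p[[paste0("rvar", b)]] <- rep(1, g$C_out)
    }
    C6 <- geo[[6L]]$C_out
    p$Wd <- matrix(stats::rnorm(C6 * 2L, sd = sqrt(1 / C6)), C6, 2L)
    p$bd <- numeric(2L)
    p
  })
  structure(list(config = config, geometry = geo, params = params,
                 cache = new.env(parent = emptyenv())),
            class = "demcnn_model")
}

# Activations live as C x (B * L) matrices (channels as rows, positions of
# all batch samples concatenated along columns). Channel-wise statistics are
# then row operations, and scaling by a per-channel vector is plain vector
# recycling down the columns — no sweep/aperm passes over the big matrices.

# im2col gather index for a whole batch, cached per (block geometry, B).
# Conceptually of shape (K * C_in) x (B * P): entry[(c-1)K + k, (b-1)P + p]
# addresses A[c, (b-1)L + (p-1)S + k] in the C x (B*L) activation matrix.
# Stored flattened (plus dims) so the hot path can subscript with a plain
# vector: matrix subscripts would be reinterpreted as coordinate pairs when
# the index happens to have two columns, and flattening on every call would
# copy the index.
conv_index <- function(model, b, B) {
  g <- model$geometry[[b]]
  key <- sprintf("I_%d_%d", b, B)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  row_off <- as.vector(vapply(seq_len(g$C_in), function(c)
    (seq_len(g$K) - 1L) * g$C_in + c, integer(g$K)))       # (c,k) -> vec
  col_pos <- rep((seq_len(B) - 1L) * g$L_in, each = g$P) +
    rep((seq_len(g$P) - 1L) * g$S, times = B)              # sample offsets
  I <- outer(row_off, col_pos * g$C_in, `+`)
  out <- list(idx = as.integer(I), nr = nrow(I), nc = ncol(I))
  model$cache[[key]] <- out
  out
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Forward pass over a batch. Returns output probabilities plus per-block
# caches when keep = TRUE (training).
demcnn_fwd <- function(model, X, training = FALSE, keep = FALSE,
                       calibrate = FALSE) {
  B <- nrow(X)
  p <- model$params
  A <- matrix(as.vector(t(X)), nrow = 1L)                # 1 x (B * L0)
  caches <- if (keep) vector("list", 6L)
  for (b in seq_len(6L)) {
    g <- model$geometry[[b]]
    I <- conv_index(model, b, B)
    Xcol <- A[I$idx]                                     # (K*C_in) x (B*P)
    dim(Xcol) <- c(I$nr, I$nc)
    Z <- crossprod(p[[paste0("W", b)]], Xcol) + p[[paste0("b", b)]]
    blk <- .k_fwd_block(Z, p[[paste0("gamma", b)]], p[[paste0("beta", b)]],
                        p[[paste0("rmean", b)]], p[[paste0("rvar", b)]],
                        bn_eps, g$dropout, training, calibrate, keep)
    if (calibrate) {
      model$params[[paste0("rmean", b)]] <- blk$mu
      model$params[[paste0("rvar", b)]] <- blk$var
    } else if (training) {
      model$params[[paste0("rmean", b)]] <-
        (1 - bn_momentum) * p[[paste0("rmean", b)]] + bn_momentum * blk$mu
      model$params[[paste0("rvar", b)]] <-
        (1 - bn_momentum) * p[[paste0("rvar", b)]] + bn_momentum * blk$var
    }
    if (keep) {
      caches[[b]] <- list(Xcol = Xcol, xhat = blk$xhat, mu = blk$mu,
                          invstd = blk$invstd, mask = blk$mask)
    }
    A <- blk$out
  }
  P6 <- model$geometry[[6L]]$P
  pool <- pool_matrix(model, B)
  G <- A %*% pool                                        # C6 x B averages
  logits <- crossprod(G, p$Wd) + rep(p$bd, each = B)     # B x 2
  m <- pmax(logits[, 1L], logits[, 2L])
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits, G = G, caches = caches, B = B,
       model = model)
}

# (B*P6) x B column-averaging matrix for the global average pool.
pool_matrix <- function(model, B) {
  key <- sprintf("pool_%d", B)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  P6 <- model$geometry[[6L]]$P
  M <- matrix(0, B * P6, B)
  M[cbind(seq_len(B * P6), rep(seq_len(B), each = P6))] <- 1 / P6
  model$cache[[key]] <- M
  M
}

# Full forward + backward; y01 is 0 (NONAD) / 1 (AD). Returns loss, batch
# accuracy and gradients keyed like params.
demcnn_fwd_bwd <- function(model, X, y01) {
  fw <- demcnn_fwd(model, X, training = TRUE, keep = TRUE)
  model <- fw$model  # carries updated running stats
  B <- fw$B
  p <- model$params
  Y <- cbind(1 - y01, y01)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(B), y01 + 1L)], 1e-12)))
  acc <- mean((fw$probs[, 2L] > fw$probs[, 1L]) == (y01 == 1L))
  grads <- list()
  dlogits <- (fw$probs - Y) / B
  grads$Wd <- tcrossprod(fw$G, t(dlogits))               # C6 x 2
  grads$bd <- colSums(dlogits)
  P6 <- model$geometry[[6L]]$P
  dG <- p$Wd %*% t(dlogits)                              # C6 x B
  dA <- dG[, rep(seq_len(B), each = P6), drop = FALSE] / P6
  for (b in 6L:1L) {
    g <- model$geometry[[b]]
    cc <- fw$caches[[b]]
    bk <- .k_bwd_block(dA, cc$xhat, p[[paste0("gamma", b)]], cc$mu,
                       cc$invstd, cc$mask)
    grads[[paste0("gamma", b)]] <- bk$dgamma
    grads[[paste0("beta", b)]] <- bk$dbeta
    dZ <- bk$dZ
    grads[[paste0("W", b)]] <- tcrossprod(cc$Xcol, dZ)   # (K*C_in) x C_out
    grads[[paste0("b", b)]] <- rowSums(dZ)
    if (b > 1L) {
      dXcol <- p[[paste0("W", b)]] %*% dZ                # (K*C_in) x (B*P)
      dA <- .k_col2im(dXcol, g$C_in, g$K, g$L_in, B, g$P, g$S)
    }
  }
  list(model = model, loss = loss, acc = acc, grads = grads)
}

# Re-estimate batch-norm population statistics after training: one
# dropout-free pass over the training set, each layer normalized by the
# statistics just estimated for it. Removes the train/inference mismatch
# left by momentum-averaged running statistics (which are accumulated under
# dropout noise and, in step 2, from batches of 2).
calibrate_bn <- function(model, X) {
  demcnn_fwd(model, X, training = FALSE, calibrate = TRUE)$model
}

sgd_update <- function(model, grads, lr) {
  for (nm in names(grads)) {
    model$params[[nm]] <- model$params[[nm]] - lr * grads[[nm]]
  }
  model
}

#' Class probabilities for prepared inputs
#'
#' Inference-mode forward pass (dropout off, batch-norm running statistics),
#' evaluated in chunks to bound memory.
#'
#' @param model A [build_demcnn()] (possibly trained) model.
#' @param X Matrix of prepared inputs, one row per recording.
#' @return An `nrow(X) x 2` matrix of class probabilities, columns
#'   `c("NONAD", "AD")`, each row summing to 1.
#' @export
forward_scores <- function(model, X) {
  stopifnot(inherits(model, "demcnn_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$config$input_len) {
    stop("inputs must have length ", model$config$input_len, ", got ",
         ncol(X), call. = FALSE)
  }
  chunks <- split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / 8))
  probs <- do.call(rbind, lapply(chunks, function(ix) {
    demcnn_fwd(model, X[ix, , drop = FALSE], training = FALSE)$probs
  }))
  colnames(probs) <- .labels
  rownames(probs) <- rownames(X)
  probs
}

#' Predict subject labels with DemCNN
#'
#' One whole-recording decision per row; a probability tie goes to NONAD.
#'
#' @inheritParams forward_scores
#' @return Character vector of labels.
#' @export
demcnn_predict <- function(model, X) {
  probs <- forward_scores(model, X)
  ifelse(probs[, "AD"] > probs[, "NONAD"], "AD", "NONAD")
}

#' Two-step training schedule
#'
#' Step 1 trains at batch size 32 at a fixed rate (default 0.1); step 2
#' continues at batch size 2 with a rate selected automatically from a
#' learning-rate range test (`"AUTO"`). Each step runs `cycles` cycles of
#' `cycle_len` epochs.
#'
#' @param step1_lr Step-1 learning rate.
#' @param step1_batch,step2_batch Minibatch sizes (32 and 2 by default).
#' @param step1_cycles,step1_cycle_len,step2_cycles,step2_cycle_len Cycle
#'   counts and lengths (epochs per cycle) per step.
#' @param step2_lr Either `"AUTO"` or a positive rate.
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(step1_lr = 0.1, step1_batch = 32L,
                           step1_cycles = 2L, step1_cycle_len = 8L,
                           step2_lr = "AUTO", step2_batch = 2L,
                           step2_cycles = 2L, step2_cycle_len = 8L) {
  stopifnot(step1_lr > 0, step1_batch >= 1, step2_batch >= 1,
            step1_cycles >= 1, step1_cycle_len >= 1,
            step2_cycles >= 1, step2_cycle_len >= 1)
  if (!identical(step2_lr, "AUTO")) stopifnot(step2_lr > 0)
  structure(list(
    step1 = list(lr = step1_lr, batch = as.integer(step1_batch),
                 cycles = as.integer(step1_cycles),
                 cycle_len = as.integer(step1_cycle_len)),
    step2 = list(lr = step2_lr, batch = as.integer(step2_batch),
                 cycles = as.integer(step2_cycles),
                 cycle_len = as.integer(step2_cycle_len)),
    loss = "cross-entropy"), class = "train_schedule")
}

#' Two-step training of DemCNN
#'
#' Step 1: SGD with cross-entropy at batch size 32 for
#' `cycles x cycle_len` epochs at the step-1 rate. Step 2: continues at
#' batch size 2; when the step-2 rate is `"AUTO"` it is chosen by
#' [select_lr()] on a [lr_range_test()] run against the step-1 model (with
#' a fallback to one tenth of the step-1 rate if no descending region is
#' found). After both steps the batch-norm population statistics are
#' re-estimated with one dropout-free pass over the training set. Shuffling
#' and dropout are seeded; a non-finite loss aborts with an error condition
#' carrying the finite history collected so far.
#'
#' @param model A [build_demcnn()] model.
#' @param X Prepared input matrix (one row per training recording).
#' @param labels Class labels (`"AD"`/`"NONAD"`), one per row.
#' @param schedule A [train_schedule()].
#' @param seed Seed for shuffling/dropout; defaults to the model seed.
#' @return List with `model` (trained), `history` (data.frame with one row
#'   per epoch: step, cycle, epoch, lr, loss, train_acc) and `selected_lr`
#'   (the step-2 rate actually used).
#' @export
fit_two_step <- function(model, X, labels, schedule = train_schedule(),
                         seed = NULL) {
  stopifnot(inherits(model, "demcnn_model"),
            inherits(schedule, "train_schedule"))
  y <- as_label_factor(labels)
  if (anyNA(y) || nlevels(droplevels(y)) < 2L) {
    stop("training labels must contain both AD and NONAD", call. = FALSE)
  }
  y01 <- as.integer(y == "AD")
  seed <- seed %||% model$config$seed
  history <- data.frame(step = integer(), cycle = integer(),
                        epoch = integer(), lr = numeric(), loss = numeric(),
                        train_acc = numeric())
  selected_lr <- NA_real_
  with_local_seed(seed, {
    for (step_i in 1:2) {
      st <- schedule[[paste0("step", step_i)]]
      lr <- st$lr
      if (identical(lr, "AUTO")) {
        curve <- lr_range_test(model, X = X, y01 = y01,
                               batch_size = st$batch)
        lr <- tryCatch(select_lr(curve), error = function(e) {
          warning("automatic rate selection failed (", conditionMessage(e),
                  "); falling back to step-1 rate / 10", call. = FALSE)
          schedule$step1$lr / 10
        })
        selected_lr <- lr
      } else if (step_i == 2L) selected_lr <- lr
      epoch_global <- 0L
      for (cyc in seq_len(st$cycles)) {
        for (ep in seq_len(st$cycle_len)) {
          epoch_global <- epoch_global + 1L
          ord <- sample.int(nrow(X))
          losses <- c(); accs <- c()
          for (start in seq(1L, nrow(X), by = st$batch)) {
            ix <- ord[start:min(start + st$batch - 1L, nrow(X))]
            res <- demcnn_fwd_bwd(model, X[ix, , drop = FALSE], y01[ix])
            if (!is.finite(res$loss)) {
              stop(errorCondition(
                sprintf("training diverged (non-finite loss) at step %d epoch %d",
                        step_i, epoch_global),
                history = history, class = "demscreen_divergence"))
            }
            model <- sgd_update(res$model, res$grads, lr)
            losses <- c(losses, res$loss)
            accs <- c(accs, res$acc)
          }
          history <- rbind(history, data.frame(
            step = step_i, cycle = cyc, epoch = epoch_global, lr = lr,
            loss = mean(losses), train_acc = mean(accs)))
        }
      }
    }
    model <- calibrate_bn(model, X)
  })
  list(model = model, history = history, selected_lr = selected_lr)
}
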