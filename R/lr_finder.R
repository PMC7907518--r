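# Learning-rate range test and automated rate selection: a short sweep of
# exponentially increasing rates, one mini-batch SGD step per rate on a
# transient copy of the model, then pick the rate with the steepest descent
# of smoothed loss against log-rate, before the curve's minimum.

#' Learning-rate curve
#'
#' @param rates Strictly increasing positive rates.
#' @param losses Losses recorded at those rates (same length).
#' @return An object of class `lr_curve`.
#' @export
lr_curve <- function(rates, losses) {
  stopifnot(length(rates) == length(losses), all(rates > 0),
            all(diff(rates) > 0))
  structure(list(rates = as.numeric(rates), losses = as.numeric(losses)),
            class = "lr_curve")
}

#' Learning-rate range test
#'
#' Sweeps `steps` exponentially spaced rates between `rate_bounds`, taking
#' one mini-batch gradient step per rate on a transient copy, and records
#' the mini-batch loss observed at each rate. The object passed in is never
#' modified. The sweep stops early at the first non-finite loss; an error is
#' raised if fewer than 3 points were collected (widen the bounds).
#'
#' @param object A trainable object; methods exist for `demcnn_model` and
#'   for the convex [quadratic_problem()] used to validate the machinery.
#' @param ... Method-specific data (for `demcnn_model`: `X`, `y01`,
#'   `batch_size`).
#' @param rate_bounds `(low, high)` positive rate bounds, low < high.
#' @param steps Number of rates swept.
#' @return An [lr_curve()].
#' @export
lr_range_test <- function(object, ..., rate_bounds = c(1e-6, 1),
                          steps = 25L) {
  stopifnot(rate_bounds[1] > 0, rate_bounds[1] < rate_bounds[2], steps >= 3)
  UseMethod("lr_range_test")
}

#' @export
lr_range_test.demcnn_model <- function(object, X, y01, batch_size = 2L,
                                       ..., rate_bounds = c(1e-6, 1),
                                       steps = 25L) {
  rates <- exp(seq(log(rate_bounds[1]), log(rate_bounds[2]),
                   length.out = steps))
  trial <- object  # transient copy: R copy-on-modify isolates the original
  n <- nrow(X)
  ord <- sample.int(n)
  pos <- 1L
  losses <- numeric(0)
  for (r in rates) {
    ix <- ord[pos:min(pos + batch_size - 1L, n)]
    pos <- if (pos + batch_size > n) 1L else pos + batch_size
    res <- demcnn_fwd_bwd(trial, X[ix, , drop = FALSE], y01[ix])
    if (!is.finite(res$loss)) break
    losses <- c(losses, res$loss)
    trial <- sgd_update(res$model, res$grads, r)
  }
  if (length(losses) < 3L) {
    stop("loss became non-finite almost immediately; widen rate_bounds ",
         "downward", call. = FALSE)
  }
  lr_curve(rates[seq_along(losses)], losses)
}

#' Convex quadratic surrogate problem
#'
#' Loss `0.5 * curvature * w^2` minimized by gradient descent, whose exact
#' stability threshold is `2 / curvature`: rates below it contract the
#' iterate, rates above it diverge. Used to validate the range-test and
#' rate-selection machinery against a closed form.
#'
#' @param curvature Positive curvature of the quadratic.
#' @param w0 Starting iterate.
#' @return An object of class `quadratic_problem`.
#' @export
quadratic_problem <- function(curvature, w0 = 1) {
  stopifnot(curvature > 0)
  structure(list(curvature = curvature, w0 = w0),
            class = "quadratic_problem")
}

#' @export
lr_range_test.quadratic_problem <- function(object, ...,
                                            rate_bounds = c(1e-4, 10),
                                            steps = 40L) {
  rates <- exp(seq(log(rate_bounds[1]), log(rate_bounds[2]),
                   length.out = steps))
  a <- object$curvature
  w <- object$w0
  losses <- numeric(0)
  for (r in rates) {
    loss <- 0.5 * a * w^2
    if (!is.finite(loss) || loss > 1e12) break
    losses <- c(losses, loss)
    w <- w - r * a * w  # one gradient step at this rate
  }
  if (length(losses) < 3L) {
    stop("quadratic surrogate diverged immediately; widen rate_bounds",
         call. = FALSE)
  }
  lr_curve(rates[seq_along(losses)], losses)
}

#' Select a learning rate from a range-test curve
#'
#' Smooths the losses with a centered moving average, then returns the rate
#' at which the smoothed loss has its steepest negative slope against
#' log-rate, restricted to rates strictly below the smoothed-loss minimum
#' (the region at and beyond the minimum precedes divergence and is
#' excluded). Deterministic.
#'
#' @param curve An [lr_curve()] with at least 5 points.
#' @param smooth_window Odd moving-average window, default 3.
#' @return The selected rate.
#' @export
select_lr <- function(curve, smooth_window = 3L) {
  stopifnot(inherits(curve, "lr_curve"))
  n <- length(curve$rates)
  if (n < 5L) stop("need at least 5 curve points to select a rate",
                   call. = FALSE)
  half <- smooth_window %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(curve$losses[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  imin <- which.min(sm)
  if (imin < 3L) {
    stop("no trainable region: loss is non-decreasing over the sweep",
         call. = FALSE)
  }
  slopes <- diff(sm) / diff(log(curve$rates))
  cand <- seq_len(imin - 1L)  # slope i spans rates i..i+1, ends at the min
  if (all(slopes[cand] >= 0)) {
    stop("no trainable region: no descending stretch before the minimum",
         call. = FALSE)
  }
  best <- cand[which.min(slopes[cand])]
  curve$rates[best]
}
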