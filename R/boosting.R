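#' Weighted misclassification error
#'
#' \eqn{\epsilon = \sum_j w_j 1[pred_j \ne truth_j]} over an already
#' normalised weight distribution (weights sum to 1).
#'
#' @param pred,truth Equal-length label vectors.
#' @param weights Non-negative weights summing to 1.
#' @return Scalar in \[0, 1\].
#' @export
weighted_error <- function(pred, truth, weights) {
  if (length(pred) != length(truth) || length(pred) != length(weights))
    stop("pred, truth and weights must have equal length")
  sum(weights * (as.character(pred) != as.character(truth)))
}

#' AdaBoost round coefficient
#'
#' \eqn{\varsigma = \frac12 \log((1-\epsilon)/\epsilon)} for two classes;
#' for `n_classes > 2` the SAMME form
#' \eqn{\log((1-\epsilon)/\epsilon) + \log(K-1)} is used. The error rate
#' is clipped to \[1e-10, 1 - 1e-10\] before the logarithm, so endpoint
#' errors yield large finite coefficients instead of infinities.
#'
#' @param error Weighted error rate in \[0, 1\].
#' @param n_classes Number of classes (default 2).
#' @return Round coefficient (negative when `error` exceeds chance).
#' @export
round_coefficient <- function(error, n_classes = 2) {
  stopifnot(error >= 0, error <= 1)
  e <- min(max(error, 1e-10), 1 - 1e-10)
  if (n_classes > 2) log((1 - e) / e) + log(n_classes - 1)
  else 0.5 * log((1 - e) / e)
}

#' AdaBoost sample-weight update
#'
#' Multiplies correctly classified samples by \eqn{e^{-\varsigma}} and
#' misclassified ones by \eqn{e^{\varsigma}}, then renormalises to sum 1.
#' The pre-normalisation total is attached as attribute `normalizer`.
#'
#' @param weights Current weights (summing to 1).
#' @param coefficient Round coefficient \eqn{\varsigma}.
#' @param pred,truth Label vectors for the round's predictions.
#' @return Updated weight vector summing to 1.
#' @export
update_sample_weights <- function(weights, coefficient, pred, truth) {
  wrong <- as.character(pred) != as.character(truth)
  w <- weights * exp(ifelse(wrong, coefficient, -coefficient))
  s <- sum(w)
  structure(w / s, normalizer = s)
}

fit_stump <- function(X, y, w) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- X[, j]
    u <- sort(unique(xs))
    qs <- if (length(u) <= 256) (u[-1] + u[-length(u)]) / 2
          else unique(quantile(xs, probs = seq(0.01, 0.99, length.out = 255),
                               names = FALSE, type = 7))
    for (thr in qs) {
      left <- xs <= thr
      if (!any(left) || all(left)) next
      cl_left  <- classes[which.max(vapply(classes, function(c)
        sum(w[left & y == c]), 0))]
      cl_right <- classes[which.max(vapply(classes, function(c)
        sum(w[!left & y == c]), 0))]
      pred <- ifelse(left, cl_left, cl_right)
      err <- sum(w * (pred != as.character(y)))
      if (is.null(best) || err < best$error)
        best <- list(feature = j, threshold = thr, left = cl_left,
                     right = cl_right, error = err)
    }
  }
  if (is.null(best)) stop("degenerate data: no stump split available")
  structure(best, class = "decision_stump")
}

predict_stump <- function(stump, X) {
  X <- as.matrix(X)
  ifelse(X[, stump$feature] <= stump$threshold, stump$left, stump$right)
}

fit_base_learner <- function(X, y, w, base, L, penalty, seed) {
  if (base == "stump") {
    model <- fit_stump(X, y, w)
    list(model = model, pred = predict_stump(model, X))
  } else {
    hidden <- elm_hidden_layer(ncol(as.matrix(X)), L, seed)
    # rescale weights to mean 1 so the ridge penalty keeps its meaning
    model <- train_weighted_elm(X, plain_targets(y), w / mean(w), hidden, penalty)
    list(model = model, pred = predict(model, X)$class)
  }
}

predict_base_learner <- function(model, X) {
  if (inherits(model, "decision_stump")) predict_stump(model, X)
  else predict(model, X)$class
}

#' Train a classic AdaBoost ensemble
#'
#' Sequentially fits base learners on reweighted data, each round's vote
#' weighted by [round_coefficient()]. Training stops early when a round's
#' error reaches the chance level `1 - 1/K` (the offending round is
#' discarded unless it is the first), or when a base learner degenerates
#' to a constant prediction.
#'
#' @param X `n x d` feature matrix.
#' @param y Class labels (two or more classes).
#' @param rounds Maximum boosting rounds (>= 1).
#' @param base `"stump"` (weighted decision stump) or `"elm"` (weighted
#'   ELM with plus/minus-one targets).
#' @param L,penalty ELM base-learner size and ridge penalty.
#' @param seed Base seed; round `t` uses `seed + t`.
#' @return An `adaboost` object with per-round models, coefficients and
#'   error rates.
#' @export
train_adaboost <- function(X, y, rounds = 10, base = c("stump", "elm"),
                           L = 25, penalty = 1, seed = 1) {
  base <- match.arg(base)
  stopifnot(rounds >= 1)
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X)
  classes <- sort(unique(y))
  K <- length(classes)
  w <- rep(1 / n, n)
  ensemble <- list()
  for (t in seq_len(rounds)) {
    fit <- fit_base_learner(X, y, w, base, L, penalty, seed + t)
    eps <- weighted_error(fit$pred, y, w)
    if (length(unique(fit$pred)) == 1) {
      warning("base learner degenerated to a constant prediction; stopping")
      if (t == 1)
        ensemble[[1]] <- list(model = fit$model,
                              coefficient = round_coefficient(eps, K),
                              error_rate = eps)
      break
    }
    if (eps >= 1 - 1 / K && t > 1) break
    coefficient <- round_coefficient(eps, K)
    ensemble[[t]] <- list(model = fit$model, coefficient = coefficient,
                          error_rate = eps)
    if (eps >= 1 - 1 / K) break
    w <- update_sample_weights(w, coefficient, fit$pred, y)
  }
  structure(list(rounds = ensemble, classes = classes, base = base),
            class = "adaboost")
}

#' Predict from an AdaBoost ensemble
#'
#' Coefficient-weighted vote: each round adds its coefficient to the
#' score of the class it predicts; ties go to the lowest class index.
#'
#' @param object An `adaboost` object.
#' @param newdata `n x d` matrix.
#' @param ... Unused.
#' @return List with `class` and the `K x n` vote `scores`.
#' @export
predict.adaboost <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  K <- length(object$classes)
  votes <- matrix(0, nrow = n, ncol = K,
                  dimnames = list(NULL, object$classes))
  for (rd in object$rounds) {
    p <- predict_base_learner(rd$model, newdata)
    for (k in seq_len(K))
      votes[, k] <- votes[, k] + rd$coefficient * (p == object$classes[k])
  }
  list(class = object$classes[argmax_rows(votes)], scores = t(votes))
}
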