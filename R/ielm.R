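# The imbalance-aware boosted ELM (IELM).
#
# The c-class single-label task is recast as q = c binary labels by
# one-hot coding, so every class contributes one label with a positive
# (member) and a negative (non-member) side. The boosting weight
# distribution is an n x q matrix partitioned into 2q (label, class)
# blocks; every block carries total mass 1/(2q) after initialisation and
# after every update, so the grand total is always 1.

as_label_matrix <- function(y, classes = NULL) {
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  Y <- matrix(0L, nrow = length(y), ncol = length(classes),
              dimnames = list(NULL, classes))
  for (j in seq_along(classes)) Y[y == classes[j], j] <- 1L
  Y
}

block_index <- function(Y, l, j) {
  j <- match.arg(j, c("pos", "neg"))
  if (j == "pos") Y[, l] == 1 else Y[, l] == 0
}

#' Per-label imbalance ratio
#'
#' For label `j`, the ratio of the larger to the smaller of its positive
#' and negative sample counts: `max(S+, S-) / min(S+, S-)`, always >= 1
#' and symmetric in which side is the minority.
#'
#' @param Y `n x q` binary label matrix (see [train_ielm()] for how a
#'   class vector is one-hot coded into one).
#' @param j Label (column) index.
#' @return Scalar ratio >= 1.
#' @export
imbalance_ratio <- function(Y, j) {
  Y <- as.matrix(Y)
  np <- sum(Y[, j] == 1); nn <- sum(Y[, j] == 0)
  if (np == 0 || nn == 0)
    stop("label ", colnames(Y)[j] %||% j, " has an empty class")
  max(np, nn) / min(np, nn)
}

#' Imbalance-aware initial weight distribution
#'
#' Samples on the minority side of each label receive raw weight
#' \eqn{\sqrt{R_j}} (majority side 1), then each (label, class) block is
#' normalised to total mass `1/(2q)`. The square root damps the raw
#' ratio, which would otherwise concentrate nearly all mass on the
#' minority side. With `sqrt_ratio = FALSE` the raw ratio \eqn{R_j} is
#' used instead.
#'
#' @param Y `n x q` binary label matrix.
#' @param sqrt_ratio Use \eqn{\sqrt{R_j}} (default) rather than
#'   \eqn{R_j}.
#' @return `n x q` weight matrix with grand total 1.
#' @export
initial_weight_distribution <- function(Y, sqrt_ratio = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y)
  W <- matrix(0, n, q, dimnames = dimnames(Y))
  for (l in seq_len(q)) {
    R <- imbalance_ratio(Y, l)
    minority_pos <- sum(Y[, l] == 1) < sum(Y[, l] == 0)
    raw_ratio <- if (sqrt_ratio) sqrt(R) else R
    raw <- ifelse(Y[, l] == 1,
                  if (minority_pos) raw_ratio else 1,
                  if (minority_pos) 1 else raw_ratio)
    for (j in c("pos", "neg")) {
      blk <- block_index(Y, l, j)
      W[blk, l] <- raw[blk] / sum(raw[blk]) / (2 * q)
    }
  }
  W
}

#' Weighted error of one (label, class) block
#'
#' Sum of the current weights of the samples in class `j` of label `l`
#' that the round's base learner misclassifies on that label. At most the
#' full block mass `1/(2q)`.
#'
#' @param pred `n x q` matrix of predicted signs (+1/-1) per label.
#' @param Y `n x q` binary label matrix.
#' @param W `n x q` weight distribution.
#' @param l Label index.
#' @param j Block class, `"pos"` or `"neg"`.
#' @return Scalar error mass.
#' @export
label_class_error <- function(pred, Y, W, l, j = c("pos", "neg")) {
  j <- match.arg(j)
  blk <- block_index(Y, l, j)
  if (!any(blk)) stop("empty (label, class) block: label ", l, ", ", j)
  truth_sign <- 2 * Y[blk, l] - 1
  sum(W[blk, l][pred[blk, l] != truth_sign])
}

#' Coefficient of one (label, class) block
#'
#' Half the log of the correctly classified block mass over the
#' misclassified block mass, both masses clipped below at 1e-10, so a
#' perfectly classified block yields a large finite positive value.
#'
#' @inheritParams label_class_error
#' @return Scalar coefficient.
#' @export
label_class_coefficient <- function(pred, Y, W, l, j = c("pos", "neg")) {
  j <- match.arg(j)
  blk <- block_index(Y, l, j)
  if (!any(blk)) stop("empty (label, class) block: label ", l, ", ", j)
  wrong <- label_class_error(pred, Y, W, l, j)
  correct <- sum(W[blk, l]) - wrong
  0.5 * log(max(correct, 1e-10) / max(wrong, 1e-10))
}

#' Per-block boosting weight update
#'
#' Within each (label, class) block, correctly classified samples are
#' multiplied by \eqn{e^{-\varsigma^{lj}}} and misclassified ones by
#' \eqn{e^{+\varsigma^{lj}}}, after which the block is renormalised to
#' its fixed mass `1/(2q)` — so a block never loses or gains mass and the
#' ensemble stays focused on the within-label imbalance.
#'
#' @param W `n x q` current weight distribution.
#' @param coefficients `q x 2` matrix of block coefficients (columns
#'   `pos`, `neg`).
#' @param pred `n x q` matrix of predicted signs.
#' @param Y `n x q` binary label matrix.
#' @return The updated `n x q` distribution.
#' @export
update_weight_distribution <- function(W, coefficients, pred, Y) {
  Y <- as.matrix(Y)
  q <- ncol(Y)
  W2 <- W
  for (l in seq_len(q)) {
    truth_sign <- 2 * Y[, l] - 1
    wrong <- pred[, l] != truth_sign
    for (j in c("pos", "neg")) {
      blk <- block_index(Y, l, j)
      cf <- coefficients[l, j]
      w <- W[blk, l] * exp(ifelse(wrong[blk], cf, -cf))
      W2[blk, l] <- w / sum(w) / (2 * q)
    }
  }
  W2
}

#' Whole-round ensemble coefficient
#'
#' Half the log of the total correctly classified mass over the total
#' misclassified mass, summed over all labels (clipped as in
#' [label_class_coefficient()]). This is the vote weight of the round's
#' base learner.
#'
#' @inheritParams update_weight_distribution
#' @return Scalar coefficient.
#' @export
ensemble_coefficient <- function(pred, Y, W) {
  Y <- as.matrix(Y)
  truth_sign <- 2 * Y - 1
  wrong <- pred != truth_sign
  w_wrong <- sum(W[wrong]); w_correct <- sum(W[!wrong])
  0.5 * log(max(w_correct, 1e-10) / max(w_wrong, 1e-10))
}

#' Train an imbalance-aware boosted ELM ensemble (IELM)
#'
#' Boosting over label-weighted ELM base learners with an
#' imbalance-aware weight distribution:
#'
#' 1. one-hot code the class vector into an `n x q` label matrix and
#'    initialise weights with [initial_weight_distribution()];
#' 2. each round draws a fresh hidden layer (seed `seed + t`) and solves
#'    each label's output column by a cost-weighted ridge solve, the
#'    diagonal costs being that label's current sample weights (rescaled
#'    to mean 1) and the targets the label-weighted coding of
#'    [label_weighted_targets()];
#' 3. block coefficients ([label_class_coefficient()]) and the round's
#'    vote weight ([ensemble_coefficient()]) are computed from the
#'    signed predictions, and the distribution advances with
#'    [update_weight_distribution()].
#'
#' Training stops early once a round classifies every sample on every
#' label correctly (all block coefficients at the clip ceiling), since
#' the weight update would no longer change anything.
#'
#' @param X `n x d` feature matrix.
#' @param y Class labels (>= 2 classes).
#' @param rounds Maximum boosting rounds (default 10).
#' @param L Hidden nodes per base ELM (default 100).
#' @param penalty Ridge penalty (default 1).
#' @param seed Base seed; round `t` uses `seed + t`.
#' @param scheme Label-weighting scheme for the base-ELM targets.
#' @param sqrt_ratio Passed to [initial_weight_distribution()].
#' @return An `ielm` object: per-round models with their coefficients,
#'   the class set, and the full weight-distribution history (element
#'   `t` of `weight_history` is the distribution the round-`t` learner
#'   was trained under).
#' @export
train_ielm <- function(X, y, rounds = 10, L = 100, penalty = 1, seed = 1,
                       scheme = "ratio", sqrt_ratio = TRUE) {
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(rounds >= 1)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes")
  q <- length(classes)
  Y <- as_label_matrix(y, classes)
  targets <- label_weighted_targets(factor(y, levels = classes), scheme)
  W <- initial_weight_distribution(Y, sqrt_ratio = sqrt_ratio)
  history <- list()
  ens <- list()
  for (t in seq_len(rounds)) {
    history[[t]] <- W
    hidden <- elm_hidden_layer(ncol(X), L, seed + t)
    H <- hidden_activations(hidden, X)
    beta <- matrix(0, nrow = L, ncol = q, dimnames = list(NULL, classes))
    for (l in seq_len(q)) {
      wl <- W[, l] / mean(W[, l])
      A <- diag(L) / penalty + crossprod(H, wl * H)
      beta[, l] <- solve(A, crossprod(H, wl * targets[l, ]))
    }
    S <- H %*% beta
    pred <- ifelse(S >= 0, 1, -1)
    coefs <- matrix(0, nrow = q, ncol = 2,
                    dimnames = list(classes, c("pos", "neg")))
    for (l in seq_len(q))
      for (j in c("pos", "neg"))
        coefs[l, j] <- label_class_coefficient(pred, Y, W, l, j)
    model <- structure(list(hidden = hidden, beta = beta, penalty = penalty,
                            classes = classes), class = "elm_model")
    ens[[t]] <- list(model = model,
                     coefficient = ensemble_coefficient(pred, Y, W),
                     label_class_coefficients = coefs)
    ceiling_cf <- 0.5 * log((0.5 / q) / 1e-10)
    if (all(coefs >= ceiling_cf - 1e-6)) {
      message("round ", t, ": all blocks perfectly classified; stopping early")
      break
    }
    W <- update_weight_distribution(W, coefs, pred, Y)
  }
  structure(list(rounds = ens, classes = classes, q = q,
                 weight_history = history,
                 config = list(L = L, penalty = penalty, seed = seed,
                               scheme = scheme, sqrt_ratio = sqrt_ratio)),
            class = "ielm")
}

#' @export
print.ielm <- function(x, ...) {
  cat("<ielm> ", length(x$rounds), " boosting round(s), classes: ",
      paste(x$classes, collapse = "/"), ", L = ", x$config$L,
      ", scheme = ", x$config$scheme, "\n", sep = "")
  cat("  round coefficients:",
      paste(sprintf("%.3f", vapply(x$rounds, `[[`, 0, "coefficient")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict from an IELM ensemble
#'
#' Each label's score is the coefficient-weighted sum of the per-round
#' signed outputs, \eqn{score_l(x) = \sum_t \varsigma_t\,
#' \mathrm{sign}(H_t(x)\beta_t)_l}; the predicted class is the label with
#' the highest score, exact ties going to the lowest class index.
#'
#' @param object An `ielm` object.
#' @param newdata `n x d` matrix.
#' @param ... Unused.
#' @return List with `class` and the `q x n` score matrix.
#' @export
predict.ielm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$rounds[[1]]$model$hidden$d)
    stop("feature dimension mismatch: got ", ncol(newdata), ", expected ",
         object$rounds[[1]]$model$hidden$d)
  scores <- matrix(0, nrow = nrow(newdata), ncol = object$q,
                   dimnames = list(NULL, object$classes))
  for (rd in object$rounds) {
    H <- hidden_activations(rd$model$hidden, newdata)
    S <- H %*% rd$model$beta
    scores <- scores + rd$coefficient * ifelse(S >= 0, 1, -1)
  }
  list(class = object$classes[argmax_rows(scores)], scores = t(scores))
}
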