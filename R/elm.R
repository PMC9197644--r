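#' Build the random hidden layer of an ELM
#'
#' Extreme learning machines fix a random single hidden layer and solve
#' only the output weights. Input weights and biases are drawn uniformly
#' on \[-1, 1\] from a seeded generator, so a layer is fully reproducible
#' from `(d, L, seed)`.
#'
#' @param d Input dimension.
#' @param L Number of hidden nodes.
#' @param seed Integer seed.
#' @param activation Hidden activation; only `"sigmoid"` is provided.
#' @return An `elm_hidden_layer` object.
#' @export
elm_hidden_layer <- function(d, L, seed, activation = "sigmoid") {
  stopifnot(d >= 1, L >= 1)
  activation <- match.arg(activation, "sigmoid")
  w <- with_seed(seed, {
    W <- matrix(runif(L * d, -1, 1), nrow = L, ncol = d)
    b <- runif(L, -1, 1)
    list(W = W, b = b)
  })
  structure(list(W = w$W, b = w$b, d = d, L = L, seed = seed,
                 activation = activation),
            class = "elm_hidden_layer")
}

#' Hidden-layer output matrix
#'
#' Maps an `n x d` input matrix through the random layer:
#' `H = sigmoid(X W' + b)`, an `n x L` matrix.
#'
#' @param hidden An [elm_hidden_layer()].
#' @param X Numeric matrix (rows = samples).
#' @return The `n x L` activation matrix.
#' @export
hidden_activations <- function(hidden, X) {
  stopifnot(inherits(hidden, "elm_hidden_layer"))
  X <- as.matrix(X)
  if (ncol(X) != hidden$d)
    stop("input has ", ncol(X), " columns but the hidden layer expects ", hidden$d)
  sigmoid(sweep(X %*% t(hidden$W), 2, hidden$b, `+`))
}

#' Label-weighted target matrix
#'
#' Builds the `m x n` expected-output matrix for an ELM where, instead of
#' weighting samples, the positive target of each class is inflated by
#' its inverse class frequency: a sample of class `i` gets positive
#' target `n_major / n_i` (`"ratio"`) or `(n_major / n_i)^2`
#' (`"ratio_squared"`), and -1 in all other rows. Majority-class positive
#' targets are therefore exactly 1, and on balanced data the matrix
#' degenerates to plain plus/minus-one coding.
#'
#' @param labels Factor or character vector of class labels (at least two
#'   classes present; a factor level with zero samples is an error).
#' @param scheme `"ratio"` or `"ratio_squared"`.
#' @return An `m x n` numeric matrix with class names as row names and
#'   attribute `classes`.
#' @examples
#' label_weighted_targets(rep(c("a", "b", "c"), c(6, 3, 1)))
#' @export
label_weighted_targets <- function(labels, scheme = c("ratio", "ratio_squared")) {
  scheme <- match.arg(scheme)
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  cnt <- table(factor(labels, levels = classes))
  if (any(cnt == 0))
    stop("class with zero samples: ", paste(names(cnt)[cnt == 0], collapse = ", "))
  if (length(classes) < 2) stop("need at least two classes")
  pos <- as.numeric(max(cnt) / cnt)
  if (scheme == "ratio_squared") pos <- pos^2
  T <- matrix(-1, nrow = length(classes), ncol = length(labels),
              dimnames = list(classes, NULL))
  for (i in seq_along(classes))
    T[i, labels == classes[i]] <- pos[i]
  attr(T, "classes") <- classes
  T
}

#' Plus/minus-one target matrix
#'
#' Standard one-vs-rest ELM coding: +1 in the row of the sample's class,
#' -1 elsewhere. Equals [label_weighted_targets()] on balanced data.
#'
#' @inheritParams label_weighted_targets
#' @return An `m x n` numeric matrix with attribute `classes`.
#' @export
plain_targets <- function(labels) {
  classes <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  T <- matrix(-1, nrow = length(classes), ncol = length(labels),
              dimnames = list(classes, NULL))
  for (i in seq_along(classes)) T[i, labels == classes[i]] <- 1
  attr(T, "classes") <- classes
  T
}

#' Train an ELM by a ridge-regularised least-squares solve
#'
#' Solves the output weights in closed form,
#' \eqn{\beta = (I/\gamma + H'H)^{-1} H' T'}, where `H` is the hidden
#' output matrix and `T` the `m x n` target matrix. Large `penalty`
#' approaches the pseudo-inverse (interpolation) limit.
#'
#' @param X `n x d` training matrix.
#' @param targets `m x n` target matrix (see [label_weighted_targets()],
#'   [plain_targets()]).
#' @param hidden An [elm_hidden_layer()].
#' @param penalty Ridge penalty factor \eqn{\gamma > 0} (default 1).
#' @return An `elm_model` with fields `hidden`, `beta` (`L x m`),
#'   `penalty`, `classes`.
#' @export
train_elm <- function(X, targets, hidden, penalty = 1) {
  train_weighted_elm(X, targets, rep(1, nrow(as.matrix(X))), hidden, penalty)
}

#' Train a cost-weighted ELM
#'
#' Same closed-form solve as [train_elm()] with a diagonal per-sample
#' cost matrix `W = diag(weights)` in the squared-error term:
#' \eqn{\beta = (I/\gamma + H'WH)^{-1} H'W T'}. All-ones weights recover
#' the unweighted solve exactly.
#'
#' @inheritParams train_elm
#' @param weights Non-negative sample weights (not all zero).
#' @return An `elm_model`.
#' @export
train_weighted_elm <- function(X, targets, weights, hidden, penalty = 1) {
  X <- as.matrix(X)
  stopifnot(inherits(hidden, "elm_hidden_layer"), penalty > 0)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(X)) stop("one weight per sample required")
  if (any(weights < 0)) stop("negative sample weight")
  if (all(weights == 0)) stop("all sample weights are zero")
  if (ncol(targets) != nrow(X)) stop("targets must have one column per sample")
  H <- hidden_activations(hidden, X)
  A <- diag(hidden$L) / penalty + crossprod(H, weights * H)
  beta <- tryCatch(solve(A, crossprod(H, weights * t(targets))),
                   error = function(e) stop("singular ELM system: ",
                                            conditionMessage(e)))
  structure(list(hidden = hidden, beta = beta, penalty = penalty,
                 classes = attr(targets, "classes") %||% rownames(targets)),
            class = "elm_model")
}

#' Train a label-weighted ELM in one call
#'
#' Convenience wrapper: builds a hidden layer, label-weighted targets and
#' the ridge solve. With `scheme = NULL` plain plus/minus-one targets are
#' used (a standard ELM).
#'
#' @param X `n x d` training matrix.
#' @param y Class labels.
#' @param L Hidden nodes (default 100).
#' @param penalty Ridge penalty (default 1).
#' @param seed Hidden-layer seed.
#' @param scheme Label weighting scheme passed to
#'   [label_weighted_targets()], or `NULL` for plain targets.
#' @return An `elm_model`.
#' @export
lw_elm <- function(X, y, L = 100, penalty = 1, seed = 1, scheme = "ratio") {
  X <- as.matrix(X)
  targets <- if (is.null(scheme)) plain_targets(y)
             else label_weighted_targets(y, scheme)
  train_elm(X, targets, elm_hidden_layer(ncol(X), L, seed), penalty)
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model> L =", x$hidden$L, "hidden nodes, d =", x$hidden$d,
      ", classes:", paste(x$classes, collapse = "/"),
      ", penalty =", x$penalty, "\n")
  invisible(x)
}

#' Predict classes and scores from an ELM
#'
#' Scores are `(H beta)'` (`m x n`); the predicted class is the row-wise
#' argmax, with exact ties broken toward the lowest class index.
#'
#' @param object An `elm_model`.
#' @param newdata `n x d` matrix.
#' @param ... Unused.
#' @return List with `class` (character vector) and `scores`
#'   (`m x n` matrix with class row names).
#' @export
predict.elm_model <- function(object, newdata, ...) {
  H <- hidden_activations(object$hidden, as.matrix(newdata))
  S <- H %*% object$beta      # n x m
  cls <- object$classes %||% as.character(seq_len(ncol(S)))
  list(class = cls[argmax_rows(S)],
       scores = structure(t(S), dimnames = list(cls, NULL)))
}

#' Serialize / restore a trained model
#'
#' Round-trips any model object of this package (ELM, AdaBoost or IELM
#' ensembles) bit-exactly, including hidden-layer seeds and all solved
#' matrices.
#'
#' @param model The model object.
#' @param path Destination file.
#' @return `write_model` invisibly returns `path`; `read_model` returns
#'   the restored object.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  readRDS(path)
}
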