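# Accuracy-driven linear feature weighting and per-band fusion.
#
# Each band's four features are weighted by their single-feature
# classification accuracies, w_i = f_i / (f_1 + f_2 + f_3 + f_4), so
# weights are convex and ordered like the accuracies.

fusion_feature_names <- function() c("hurst", "fluct", "sampen", "permen")

#' Accuracy-proportional feature weights for one band
#'
#' Normalises the four single-feature accuracies of a band to convex
#' weights `w_i = f_i / sum(f)`. Full-precision weights are kept for
#' computation; a half-up 4-decimal rounding is attached for display,
#' matching how such weight tables are conventionally printed.
#'
#' @param accuracies Four positive accuracies, ordered (Hurst,
#'   fluctuation, sample entropy, permutation entropy).
#' @param band Optional band name carried along for display.
#' @return A `feature_weights` object: `band`, `weights` (full
#'   precision, summing to 1), `rounded`, `accuracies`.
#' @examples
#' compute_feature_weights(c(0.7778, 0.8134, 0.7190, 0.7327), "alpha")
#' @export
compute_feature_weights <- function(accuracies, band = NA_character_) {
  accuracies <- as.numeric(accuracies)
  if (length(accuracies) != 4) stop("exactly four accuracies required")
  if (any(!is.finite(accuracies)) || any(accuracies <= 0))
    stop("accuracies must be positive")
  w <- accuracies / sum(accuracies)
  names(w) <- fusion_feature_names()
  structure(list(band = band, weights = w,
                 rounded = round_half_up(w, 4),
                 accuracies = stats::setNames(accuracies, fusion_feature_names())),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat("<feature_weights>", if (!is.na(x$band)) paste0("band ", x$band), "\n")
  print(x$rounded)
  invisible(x)
}

#' Weight table from a feature-by-band accuracy table
#'
#' Applies [compute_feature_weights()] column-wise to a 4 features x 5
#' bands accuracy table, yielding the matching table of convex weights.
#'
#' @param acc Numeric 4 x 5 matrix or data frame: rows (Hurst,
#'   fluctuation, sample entropy, permutation entropy), columns the five
#'   bands. A missing cell is an error naming (feature, band).
#' @return 4 x 5 full-precision weight matrix (columns sum to 1) with
#'   attribute `rounded` (half-up, 4 decimals).
#' @export
weight_table_from_accuracy_table <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) != 4 || ncol(acc) != 5)
    stop("expected a 4 features x 5 bands accuracy table, got ",
         nrow(acc), " x ", ncol(acc))
  if (anyNA(acc)) {
    miss <- which(is.na(acc), arr.ind = TRUE)[1, ]
    stop("missing accuracy for (",
         rownames(acc)[miss[1]] %||% miss[1], ", ",
         colnames(acc)[miss[2]] %||% miss[2], ")")
  }
  W <- apply(acc, 2, function(col) compute_feature_weights(col)$weights)
  dimnames(W) <- dimnames(acc)
  if (is.null(rownames(W))) rownames(W) <- fusion_feature_names()
  attr(W, "rounded") <- round_half_up(W, 4)
  W
}

#' Combine a segment's band features with per-band weights
#'
#' Two fusion outputs from one 20-entry feature vector: the five convex
#' combinations \eqn{F_{band} = \sum_i w_i P_i} (one scalar per band),
#' and the element-wise weighted 20-entry vector `w_i * P_i`, which is
#' the representation fed to classifiers (a single scalar per band would
#' discard too much information).
#'
#' @param v Named numeric vector of the 20 band features
#'   (`<band>_<feature>` names as produced by
#'   [extract_feature_table()]), or a one-row slice of such a table.
#' @param weights 4 x 5 weight matrix from
#'   [weight_table_from_accuracy_table()], or a named list of
#'   `feature_weights`, one per band.
#' @return List with `scores` (5 named band scalars) and `weighted`
#'   (20 named values).
#' @export
combine_band_features <- function(v, weights) {
  if (is.data.frame(v)) v <- unlist(v[1, band_feature_names()])
  v <- v[band_feature_names()]
  if (anyNA(v)) stop("feature vector must contain all 20 band features")
  if (is.list(weights) && !is.matrix(weights)) {
    W <- vapply(eeg_bands()$band, function(b) {
      if (is.null(weights[[b]])) stop("missing weights for band ", b)
      weights[[b]]$weights
    }, numeric(4))
  } else {
    W <- as.matrix(weights)
    missing_b <- setdiff(eeg_bands()$band, colnames(W))
    if (length(missing_b) > 0)
      stop("missing weights for band ", paste(missing_b, collapse = ", "))
    W <- W[, eeg_bands()$band]
  }
  feats <- fusion_feature_names()
  weighted <- v
  scores <- stats::setNames(numeric(5), eeg_bands()$band)
  for (b in eeg_bands()$band) {
    idx <- paste(b, feats, sep = "_")
    weighted[idx] <- v[idx] * W[feats, b]
    scores[b] <- sum(v[idx] * W[feats, b])
  }
  list(scores = scores, weighted = weighted)
}

#' Apply per-band feature weighting to a whole feature table
#'
#' Maps [combine_band_features()] over the rows of a feature table,
#' returning either the element-wise weighted 20-column table (default)
#' or the 5-column table of band scores.
#'
#' @param tab Feature table from [extract_feature_table()].
#' @param weights As in [combine_band_features()].
#' @param mode `"weighted"` (20 columns) or `"scores"` (5 columns).
#' @return Data frame with the same id/label columns and fused features.
#' @export
fuse_feature_table <- function(tab, weights, mode = c("weighted", "scores")) {
  mode <- match.arg(mode)
  meta <- tab[, intersect(c("segment_id", "subject_id", "label"), names(tab)),
              drop = FALSE]
  out <- t(apply(tab[, band_feature_names()], 1, function(v) {
    cb <- combine_band_features(v, weights)
    if (mode == "weighted") cb$weighted else cb$scores
  }))
  cbind(meta, as.data.frame(out))
}

#' Read / write a weight table
#'
#' Delimited round-trip of a 4 x 5 weight (or accuracy) table: first
#' column `feature`, then one column per band.
#'
#' @param x Matrix with feature row names and band column names.
#' @param path File path.
#' @return `read_weight_table` returns the numeric matrix.
#' @export
write_weight_table <- function(x, path) {
  df <- data.frame(feature = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
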