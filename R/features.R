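#' Hurst exponent by rescaled-range analysis
#'
#' Classic R/S estimate of long-range dependence: the series is cut into
#' blocks of logarithmically spaced sizes, the rescaled range R/S is
#' averaged over blocks at each size, and the Hurst exponent is the
#' least-squares slope of log(R/S) against log(block size). White noise
#' gives values near 0.5 (the small-sample R/S bias pushes it slightly
#' above), persistent signals approach 1.
#'
#' @param x Numeric vector, length at least 100.
#' @param min_window Smallest block size (default 16).
#' @param n_windows Number of logarithmically spaced block sizes
#'   (default 10, minimum 8).
#' @return The estimated Hurst exponent (typically in (0, 1.2)).
#' @examples
#' hurst_exponent(rnorm(1000))
#' @export
hurst_exponent <- function(x, min_window = 16, n_windows = 10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100) stop("need at least 100 samples, got ", n)
  if (sd(x) == 0) stop("zero variance: Hurst exponent undefined for a constant sequence")
  n_windows <- max(8, n_windows)
  sizes <- unique(round(exp(seq(log(min_window), log(floor(n / 2)),
                                length.out = n_windows))))
  rs <- vapply(sizes, function(w) {
    nb <- floor(n / w)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1) * w + 1):(b * w)]
      s <- sd(seg)
      if (s == 0) return(NA_real_)
      cs <- cumsum(seg - mean(seg))
      (max(cs) - min(cs)) / s
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2) stop("too few valid block sizes for R/S regression")
  unname(coef(lm(log(rs[keep]) ~ log(sizes[keep])))[2])
}

#' Fluctuation index
#'
#' Mean absolute first difference of the signal,
#' \eqn{(1/(N-1)) \sum_i |x_{i+1} - x_i|}: a simple volatility measure
#' that grows with both amplitude and dominant frequency of the band
#' content.
#'
#' @param x Numeric vector, length at least 2.
#' @return Non-negative scalar.
#' @examples
#' fluctuation_index(c(0, 1, 3, 2)) # 4/3
#' @export
fluctuation_index <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 samples to compute fluctuations")
  mean(abs(diff(x)))
}

#' Sample entropy
#'
#' \eqn{-\log(A/B)} where B counts pairs of length-`m` templates and A
#' pairs of length-`m+1` templates that match within Chebyshev tolerance
#' `r * sd(x)`, self-matches excluded (Richman & Moorman convention: the
#' first `n - m` points index templates of both lengths). A constant
#' sequence returns 0 by convention (every template matches). When no
#' extended template matches (A = 0) the entropy is unbounded and `Inf`
#' is returned.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of the SD of `x` (default 0.2).
#' @return Non-negative scalar (possibly `Inf`).
#' @examples
#' sample_entropy(rnorm(200))
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  x <- as.numeric(x)
  if (m < 1) stop("embedding dimension m must be >= 1")
  if (r <= 0) stop("tolerance fraction r must be > 0")
  if (length(x) < m + 2) stop("sequence too short for embedding dimension ", m)
  s <- sd(x)
  if (s == 0) return(0)
  cnt <- sampen_counts(x, as.integer(m), r * s)
  if (cnt[["B"]] == 0) return(Inf)
  if (cnt[["A"]] == 0) return(Inf)
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of the embedded
#' series, normalised by \eqn{\log(order!)} so the result lies in
#' \[0, 1\]. Ties within a pattern are broken by temporal position
#' (stable ranking). Invariant under strictly increasing transforms of
#' the signal.
#'
#' @param x Numeric vector, length at least `order * delay + 10`.
#' @param order Pattern length, between 3 and 7 (default 3).
#' @param delay Embedding delay in samples (default 1).
#' @return Scalar in \[0, 1\].
#' @examples
#' permutation_entropy(seq_len(100)) # 0: a single ordinal pattern
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  x <- as.numeric(x)
  if (order < 3 || order > 7) stop("order must be in 3..7")
  if (delay < 1) stop("delay must be >= 1")
  if (length(x) < order * delay + 10)
    stop("sequence too short: need at least ", order * delay + 10, " samples")
  n_pat <- length(x) - (order - 1) * delay
  idx <- outer(seq_len(n_pat), (0:(order - 1)) * delay, `+`)
  emb <- matrix(x[idx], nrow = n_pat)
  codes <- apply(emb, 1, function(row) paste(order(row), collapse = "."))
  p <- tabulate(factor(codes))
  p <- p / sum(p)
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

band_feature_names <- function() {
  bands <- eeg_bands()$band
  feats <- c("hurst", "fluct", "sampen", "permen")
  as.vector(t(outer(bands, feats, paste, sep = "_")))
}

#' Extract the per-band feature table from EEG segments
#'
#' Runs each segment through [preprocess()] and [decompose_bands()], then
#' computes the four nonlinear features (Hurst exponent, fluctuation
#' index, sample entropy, permutation entropy) on each of the five band
#' signals, giving 20 feature columns in fixed band-major order
#' (`delta_hurst`, `delta_fluct`, ..., `gamma_permen`). Segments whose
#' extraction fails (e.g. constant signal) are dropped with a single
#' warning listing them.
#'
#' @param segments List of [eeg_segment()] objects.
#' @param clip_sd Preprocessing clip threshold, see [preprocess()].
#' @param m,r Sample entropy parameters, see [sample_entropy()].
#' @param order,delay Permutation entropy parameters, see
#'   [permutation_entropy()].
#' @return Data frame with columns `segment_id`, `subject_id`, `label`
#'   and the 20 feature columns; all feature values finite.
#' @export
extract_feature_table <- function(segments, clip_sd = 5, m = 2, r = 0.2,
                                  order = 3, delay = 1) {
  cols <- band_feature_names()
  rows <- list(); failed <- character()
  for (seg in segments) {
    row <- tryCatch({
      pre <- preprocess(seg, clip_sd = clip_sd)
      if (sd(pre$samples) == 0) stop("zero variance")
      bands <- decompose_bands(pre)
      vals <- unlist(lapply(bands, function(b) {
        c(hurst  = hurst_exponent(b$samples),
          fluct  = fluctuation_index(b$samples),
          sampen = sample_entropy(b$samples, m = m, r = r),
          permen = permutation_entropy(b$samples, order = order, delay = delay))
      }))
      names(vals) <- cols
      if (!all(is.finite(vals))) stop("non-finite feature value")
      vals
    }, error = function(e) e, warning = function(w) w)
    if (inherits(row, "condition")) {
      failed <- c(failed, paste0(seg$segment_id, " (", conditionMessage(row), ")"))
    } else {
      rows[[seg$segment_id]] <- data.frame(
        segment_id = seg$segment_id, subject_id = seg$subject_id,
        label = seg$label, t(row), stringsAsFactors = FALSE)
    }
  }
  if (length(failed) > 0)
    warning("dropped ", length(failed), " segment(s): ",
            paste(failed, collapse = "; "))
  if (length(rows) == 0) stop("no segments survived feature extraction")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Min-max feature scaling fitted on a training split
#'
#' ELMs with sigmoid activations are scale-sensitive, so feature columns
#' are mapped to \[0, 1\] using ranges estimated on the training split
#' only; the same affine map is then applied to held-out data (values may
#' fall slightly outside \[0, 1\] there).
#'
#' @param train Numeric matrix or data frame of training features.
#' @param ... Further matrices/data frames to transform with the ranges
#'   fitted on `train`.
#' @return If `...` is empty, the scaled training matrix (with the fitted
#'   ranges as attributes `low`/`high`); otherwise a list of the scaled
#'   training matrix followed by the transformed sets.
#' @export
minmax_scale <- function(train, ...) {
  train <- as.matrix(train)
  lo <- apply(train, 2, min); hi <- apply(train, 2, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  tr <- sweep(sweep(train, 2, lo), 2, span, "/")
  attr(tr, "low") <- lo; attr(tr, "high") <- hi
  rest <- list(...)
  if (length(rest) == 0) return(tr)
  c(list(tr), lapply(rest, function(x)
    sweep(sweep(as.matrix(x), 2, lo), 2, span, "/")))
}
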