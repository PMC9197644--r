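# Independent brute-force oracles and small fixture builders. The
# oracles deliberately share no code with the package implementations.

# Sample entropy by direct template enumeration (Chebyshev distance,
# self-matches excluded, first n - m points index both template lengths).
sampen_oracle <- function(x, m = 2, r = 0.2) {
  n <- length(x)
  tol <- r * sd(x)
  A <- 0; B <- 0
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= tol) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= tol) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

# Permutation entropy by explicit pattern tabulation over all order!
# patterns (stable ranking for ties).
permen_oracle <- function(x, ord = 3, delay = 1) {
  n_pat <- length(x) - (ord - 1) * delay
  pats <- character(n_pat)
  for (i in seq_len(n_pat)) {
    w <- x[i + (0:(ord - 1)) * delay]
    pats[i] <- paste(sort.list(w), collapse = "-")
  }
  tab <- table(pats)
  p <- as.numeric(tab) / n_pat
  -sum(p * log(p)) / log(factorial(ord))
}

# Weighted ridge normal equations by explicit matrix inversion.
ridge_oracle <- function(H, targets_t, penalty, w = NULL) {
  L <- ncol(H)
  if (is.null(w)) w <- rep(1, nrow(H))
  Wm <- diag(w, nrow = nrow(H))
  solve(diag(L) / penalty + t(H) %*% Wm %*% H) %*% (t(H) %*% Wm %*% targets_t)
}

# Gaussian clusters with EXACT per-class counts (the generator draws
# labels multinomially; degeneracy fixtures need R_j = 1 exactly).
make_clusters <- function(n_per_class, means, seed, sd = 1) {
  classes <- names(means)
  set.seed(seed)
  X <- do.call(rbind, lapply(classes, function(cl) {
    d <- length(means[[cl]])
    matrix(rnorm(n_per_class[[cl]] * d, sd = sd), ncol = d,
           byrow = TRUE) + rep(means[[cl]], each = n_per_class[[cl]])
  }))
  y <- rep(classes, times = unlist(n_per_class))
  perm <- sample(length(y))
  list(X = X[perm, , drop = FALSE], y = y[perm])
}

# A short sine-plus-noise EEG segment for signal tests.
make_segment <- function(freq = 10, fs = 256, dur = 10, amp = 1,
                         noise = 0, seed = 1, id = "seg1", label = NA) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t) + rnorm(length(t), sd = noise)
  eeg_segment(x, fs, segment_id = id, label = label)
}
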