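# Seeded synthetic data: band-structured EEG segments and Gaussian
# feature-space fixtures with the stress-class imbalance the classifiers
# are built for (high stress a ~12% minority).

#' Fractional Gaussian noise
#'
#' Exact simulation by circulant embedding (Davies-Harte): the fGn
#' autocovariance \eqn{\rho(k) = \frac12(|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})} is embedded in a circulant matrix whose eigenvalues are
#' obtained by FFT, giving a draw with exactly the target covariance.
#' `H = 0.5` reduces to white noise; `H > 0.5` gives persistent,
#' positively autocorrelated noise with lag-1 autocorrelation
#' \eqn{2^{2H-1} - 1}.
#'
#' @param n Length of the series.
#' @param H Hurst parameter, strictly in (0, 1).
#' @param seed Optional seed for a reproducible draw.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @export
fgn <- function(n, H, seed = NULL) {
  if (!is.numeric(H) || H <= 0 || H >= 1)
    stop("Hurst parameter H must lie strictly in (0, 1)")
  gen <- function() {
    k <- 0:(n - 1)
    r <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
    lam <- Re(stats::fft(c(r, 0, rev(r[-1]))))
    lam <- pmax(lam, 0)   # tiny negative values are FFT round-off
    m <- 2 * n
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n]
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

default_band_amplitudes <- function() {
  # RMS microvolts per band and class. Stress raises fast (beta, gamma)
  # activity and suppresses alpha; slow rhythms are kept class-neutral.
  rbind(
    low      = c(delta = 20, theta = 10, alpha = 18, beta = 6,  gamma = 3),
    moderate = c(delta = 20, theta = 10, alpha = 14, beta = 9,  gamma = 4.5),
    high     = c(delta = 20, theta = 10, alpha = 10, beta = 13, gamma = 7)
  )
}

#' Configuration for the synthetic EEG generator
#'
#' Bundles and validates the generator's knobs. Defaults describe the
#' study conditions the package targets: a 12/46/42% high/moderate/low
#' class mix, 10-second single-channel segments at 256 Hz, class-
#' dependent beta/gamma amplitudes (arousal raises fast activity and
#' suppresses alpha), class-dependent long-range dependence of the
#' broadband background, and four segments per subject.
#'
#' @param n_segments Number of segments (>= 10).
#' @param class_proportions Named proportions for high/moderate/low,
#'   summing to 1.
#' @param sampling_rate Hz (default 256).
#' @param duration_s Segment length in seconds (default 10).
#' @param band_amplitudes 3 x 5 matrix of per-class band RMS amplitudes
#'   (microvolts), rows low/moderate/high.
#' @param hurst Named per-class Hurst targets of the broadband
#'   background, each in (0, 1).
#' @param noise_sd SD (microvolts) of the fractional-noise background.
#' @param segments_per_subject Segments sharing one subject id.
#' @param seed Integer seed governing all draws.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_segments = 60,
                             class_proportions = c(high = 0.12,
                                                   moderate = 0.46,
                                                   low = 0.42),
                             sampling_rate = 256, duration_s = 10,
                             band_amplitudes = default_band_amplitudes(),
                             hurst = c(low = 0.78, moderate = 0.70,
                                       high = 0.62),
                             noise_sd = 5, segments_per_subject = 4,
                             seed = 1) {
  if (n_segments < 10) stop("n_segments must be >= 10")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (!all(stress_levels() %in% names(class_proportions)))
    stop("class_proportions must be named with ", paste(stress_levels(), collapse = ", "))
  if (any(band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  if (any(rowSums(band_amplitudes) == 0))
    warning("class with all-zero band amplitudes: segments are pure background noise")
  stopifnot(all(hurst > 0 & hurst < 1))
  structure(list(n_segments = n_segments,
                 class_proportions = class_proportions,
                 sampling_rate = sampling_rate, duration_s = duration_s,
                 band_amplitudes = band_amplitudes, hurst = hurst,
                 noise_sd = noise_sd,
                 segments_per_subject = segments_per_subject,
                 seed = seed),
            class = "synthetic_config")
}

#' Generate labelled synthetic EEG segments
#'
#' Each segment is the sum of five band-limited noise processes (unit-
#' variance white noise passed through the band filters of
#' [decompose_bands()], scaled to the class's RMS amplitude) plus a
#' fractional Gaussian noise background with the class's Hurst target.
#' Labels are drawn independently per segment from the configured class
#' proportions; subject ids group consecutive segments. Bit-reproducible
#' from `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @return List of labelled [eeg_segment()] objects.
#' @export
generate_segments <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_samp <- round(config$sampling_rate * config$duration_s)
  bands <- eeg_bands()
  with_seed(config$seed, {
    labels <- sample(names(config$class_proportions), config$n_segments,
                     replace = TRUE, prob = config$class_proportions)
    lapply(seq_len(config$n_segments), function(i) {
      cls <- labels[i]
      x <- config$noise_sd * fgn(n_samp, config$hurst[[cls]])
      for (b in seq_len(nrow(bands))) {
        amp <- config$band_amplitudes[cls, bands$band[b]]
        if (amp > 0) {
          bn <- band_filter(rnorm(n_samp), config$sampling_rate,
                            bands$low_hz[b], bands$high_hz[b])
          x <- x + amp * bn / sd(bn)
        }
      }
      eeg_segment(x, config$sampling_rate,
                  segment_id = sprintf("seg%04d", i),
                  subject_id = sprintf("subj%03d",
                                       ceiling(i / config$segments_per_subject)),
                  label = cls)
    })
  })
}

#' Generate a Gaussian feature-space dataset
#'
#' Direct classifier fixtures bypassing signal simulation: 20-dimensional
#' Gaussian class clusters with unit within-class variance. Class mean
#' vectors are drawn once (from the same seed) with expected norm
#' `separation`, so `separation = 0` is the null configuration and larger
#' values give cleaner classes. Labels are drawn from `proportions`.
#'
#' @param n Number of rows.
#' @param proportions Named class proportions (default the 12/46/42
#'   high/moderate/low stress mix).
#' @param separation Expected norm of each class mean (>= 0, default 2).
#' @param seed Integer seed.
#' @param d Feature dimension (default 20, matching the band-feature
#'   table).
#' @return Data frame: `segment_id`, `label`, and `d` feature columns
#'   named like [extract_feature_table()] output when `d = 20`.
#' @export
generate_feature_dataset <- function(n,
                                     proportions = c(high = 0.12,
                                                     moderate = 0.46,
                                                     low = 0.42),
                                     separation = 2, seed = 1, d = 20) {
  stopifnot(separation >= 0, n >= 1)
  classes <- names(proportions)
  with_seed(seed, {
    mu <- matrix(rnorm(length(classes) * d, sd = separation / sqrt(d)),
                 nrow = length(classes), dimnames = list(classes, NULL))
    labels <- sample(classes, n, replace = TRUE, prob = proportions)
    X <- matrix(rnorm(n * d), nrow = n) + mu[labels, , drop = FALSE]
    colnames(X) <- if (d == 20) band_feature_names()
                   else paste0("f", seq_len(d))
    data.frame(segment_id = sprintf("row%04d", seq_len(n)), label = labels,
               X, stringsAsFactors = FALSE)
  })
}

#' Stratified train/test split
#'
#' Seeded split keeping each class's train fraction close to
#' `train_frac`. When `subjects` is given, whole subjects are assigned to
#' one side (grouped split), stratifying on each subject's first label.
#'
#' @param labels Class labels.
#' @param train_frac Fraction in the training split (default 0.7).
#' @param seed Integer seed.
#' @param subjects Optional subject ids for grouped splitting.
#' @return Logical vector, `TRUE` for training rows.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1,
                             subjects = NULL) {
  labels <- as.character(labels)
  with_seed(seed, {
    train <- logical(length(labels))
    if (is.null(subjects)) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        k <- max(1, round(train_frac * length(idx)))
        train[sample(idx, k)] <- TRUE
      }
    } else {
      subjects <- as.character(subjects)
      first_lab <- tapply(labels, subjects, `[`, 1)
      for (cl in unique(first_lab)) {
        sub <- names(first_lab)[first_lab == cl]
        k <- max(1, round(train_frac * length(sub)))
        train[subjects %in% sample(sub, k)] <- TRUE
      }
    }
    train
  })
}
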