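#' EEG rhythm band definitions
#'
#' The five canonical scalp-EEG rhythm bands used throughout the package.
#' The delta band is the half-open interval \[0.5, 4) Hz; the remaining
#' bands are closed intervals with small unassigned gaps between them
#' (7--8, 15--16 and 31--32 Hz), which are deliberately not filled in:
#' features are computed per band independently.
#'
#' @return A data frame with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    band    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(0.5, 4, 8, 16, 32),
    high_hz = c(4, 7, 15, 31, 45),
    stringsAsFactors = FALSE
  )
}

#' Stress class labels
#'
#' The three stress states recognised by the classifiers, ordered from
#' least to most stressed. `"high"` is the minority class in the default
#' synthetic class mix.
#'
#' @return Character vector `c("low", "moderate", "high")`.
#' @export
stress_levels <- function() c("low", "moderate", "high")

#' Construct a labelled EEG segment
#'
#' A segment is a single-channel stretch of EEG (microvolts) at a known
#' sampling rate, optionally tagged with a subject id and a stress label.
#'
#' @param samples Numeric vector of samples (microvolts).
#' @param sampling_rate Sampling rate in Hz. Must be at least 90 Hz so
#'   that the gamma band upper edge (45 Hz) is below Nyquist.
#' @param segment_id Segment identifier.
#' @param subject_id Optional subject identifier.
#' @param label Optional stress label, one of [stress_levels()].
#' @return An object of class `eeg_segment`.
#' @examples
#' seg <- eeg_segment(sin(2 * pi * 10 * seq(0, 10, by = 1 / 256)), 256, "seg1")
#' seg
#' @export
eeg_segment <- function(samples, sampling_rate, segment_id = "seg",
                        subject_id = NA_character_, label = NA_character_) {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("segment '", segment_id, "': non-numeric or missing sample")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar (Hz)")
  if (sampling_rate < 2 * 45)
    stop("sampling_rate ", sampling_rate,
         " Hz is below 90 Hz; the gamma band (32-45 Hz) would alias")
  if (length(samples) < 2 * sampling_rate)
    stop("segment '", segment_id, "': need at least 2 s of signal (",
         2 * sampling_rate, " samples), got ", length(samples))
  if (!is.na(label) && !label %in% stress_levels())
    stop("label must be one of: ", paste(stress_levels(), collapse = ", "))
  structure(
    list(segment_id = as.character(segment_id),
         subject_id = as.character(subject_id),
         samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         label = as.character(label)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat("<eeg_segment> ", x$segment_id, ": ", length(x$samples), " samples @ ",
      x$sampling_rate, " Hz (", round(length(x$samples) / x$sampling_rate, 2),
      " s), label = ", x$label, "\n", sep = "")
  invisible(x)
}

#' Read EEG segments from delimited text files
#'
#' Each segment lives in its own plain-text file: comment lines starting
#' with `#` carry metadata (`# fs=<Hz>` is mandatory, `# subject=<id>`
#' optional), followed by one sample value per line. The segment id is
#' the file name without extension. Labels may be joined from a
#' two-column delimited table `segment_id,label`.
#'
#' @param path A directory containing `.txt` segment files, or a
#'   character vector of file paths.
#' @param label_path Optional path to a `segment_id,label` table. Label
#'   rows whose id matches no segment are skipped with a warning.
#' @return A list of [eeg_segment()] objects.
#' @seealso [write_segments()]
#' @export
read_segments <- function(path, label_path = NULL) {
  files <- path
  if (length(path) == 1 && dir.exists(path))
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop("no segment files found under ", path)
  segs <- lapply(files, read_one_segment)
  names(segs) <- vapply(segs, `[[`, "", "segment_id")
  if (!is.null(label_path)) {
    lab <- read.csv(label_path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(lab) < 2) stop("label table must have columns segment_id,label")
    unknown <- setdiff(lab[[1]], names(segs))
    if (length(unknown) > 0)
      warning("label table ids with no matching segment, skipped: ",
              paste(unknown, collapse = ", "))
    for (k in which(lab[[1]] %in% names(segs)))
      segs[[lab[[1]][k]]]$label <- lab[[2]][k]
  }
  segs
}

read_one_segment <- function(file) {
  if (!file.exists(file)) stop("segment file not found: ", file)
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no samples in ", file)
  fs_line <- grep("fs\\s*=", hdr, value = TRUE)
  if (length(fs_line) == 0) stop("missing sampling rate header '# fs=<Hz>' in ", file)
  fs <- as.numeric(sub(".*fs\\s*=\\s*([0-9.]+).*", "\\1", fs_line[1]))
  if (is.na(fs)) stop("unparseable sampling rate in ", file)
  subj_line <- grep("subject\\s*=", hdr, value = TRUE)
  subj <- if (length(subj_line))
    sub(".*subject\\s*=\\s*(\\S+).*", "\\1", subj_line[1]) else NA_character_
  x <- suppressWarnings(as.numeric(body))
  if (anyNA(x))
    stop("non-numeric sample at data row ", which(is.na(x))[1], " of ", file)
  eeg_segment(x, fs, segment_id = sub("\\.[^.]*$", "", basename(file)),
              subject_id = subj)
}

#' Write EEG segments to delimited text files
#'
#' Inverse of [read_segments()]: one file per segment with a `# fs=` header
#' and full-precision samples, plus a `labels.csv` table for any labelled
#' segments.
#'
#' @param segments List of [eeg_segment()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written segment file paths.
#' @export
write_segments <- function(segments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(segments, function(s) {
    p <- file.path(dir, paste0(s$segment_id, ".txt"))
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.10g", s$sampling_rate), con)
    if (!is.na(s$subject_id))
      writeLines(paste0("# subject=", s$subject_id), con)
    writeLines(format(s$samples, digits = 17, scientific = TRUE, trim = TRUE), con)
    p
  }, "")
  lab <- data.frame(
    segment_id = vapply(segments, `[[`, "", "segment_id"),
    label = vapply(segments, `[[`, "", "label"),
    stringsAsFactors = FALSE
  )
  lab <- lab[!is.na(lab$label) & lab$label != "NA", ]
  if (nrow(lab) > 0)
    write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Preprocess a raw EEG segment
#'
#' Removes the mean and any linear drift, then clips extreme excursions at
#' `clip_sd` standard deviations of the detrended signal as a crude
#' artifact guard. An all-constant signal is returned unchanged with a
#' warning.
#'
#' @param seg An [eeg_segment()].
#' @param clip_sd Clipping threshold in SD units (default 5).
#' @return The preprocessed `eeg_segment` (same length).
#' @export
preprocess <- function(seg, clip_sd = 5) {
  stopifnot(inherits(seg, "eeg_segment"))
  x <- seg$samples
  if (sd(x) == 0) {
    warning("segment '", seg$segment_id, "' is constant; returned unchanged")
    return(seg)
  }
  n <- length(x)
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, t), x)
  x <- fit$residuals
  s <- sd(x)
  x <- pmin(pmax(x, -clip_sd * s), clip_sd * s)
  seg$samples <- as.numeric(x)
  seg
}

# Exactly zero-phase band-pass: multiply the spectrum by a real,
# cosine-tapered amplitude response. Transition half-width `h` (Hz) is
# narrow so that touching bands (delta/theta at 4 Hz) split power
# complementarily and refiltering a band changes its variance by well
# under 5%.
band_filter <- function(x, fs, low_hz, high_hz, h = 0.15) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  rise <- function(f, edge) {
    ifelse(f <= edge - h, 0,
           ifelse(f >= edge + h, 1,
                  0.5 * (1 - cos(pi * (f - (edge - h)) / (2 * h)))))
  }
  power <- rise(f, low_hz) * (1 - rise(f, high_hz))
  Re(stats::fft(stats::fft(x) * sqrt(power), inverse = TRUE)) / n
}

#' Decompose a segment into the five rhythm bands
#'
#' Applies a zero-phase band-pass filter per band of [eeg_bands()],
#' returning one band-limited copy of the segment for each of delta,
#' theta, alpha, beta and gamma. Output lengths equal the input length,
#' and phase is untouched, so ordinal-pattern features downstream are not
#' distorted.
#'
#' @param seg A (preferably preprocessed) [eeg_segment()].
#' @return Named list of five `band_signal` objects (fields `segment_id`,
#'   `band`, `samples`, `sampling_rate`).
#' @export
decompose_bands <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  bands <- eeg_bands()
  bad <- bands$band[bands$high_hz * 2 > seg$sampling_rate]
  if (length(bad) > 0)
    stop("sampling rate ", seg$sampling_rate, " Hz too low for band(s): ",
         paste(bad, collapse = ", "))
  out <- lapply(seq_len(nrow(bands)), function(i) {
    structure(
      list(segment_id = seg$segment_id,
           band = bands$band[i],
           samples = band_filter(seg$samples, seg$sampling_rate,
                                 bands$low_hz[i], bands$high_hz[i]),
           sampling_rate = seg$sampling_rate),
      class = "band_signal"
    )
  })
  names(out) <- bands$band
  out
}
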