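#' Canonical channel montage and attention conditions
#'
#' The eight dry-electrode sites used throughout the package, in the fixed
#' order that feature vectors and result tables follow: temporal (T7, T8),
#' posterior temporal (P7, P8), central (Cz), frontal (Fz) and parietal
#' (P3, P4). The three attention conditions are Rest (eyes closed, no
#' stimulus), AOA1 (attention to auditory object 1) and AOA2 (attention to
#' auditory object 2).
#'
#' @return A character vector of channel labels, or of condition levels.
#' @export
#' @examples
#' eeg_channels()
#' attention_levels()
eeg_channels <- function() {
  c("T7", "T8", "P7", "P8", "Cz", "Fz", "P3", "P4")
}

#' @rdname eeg_channels
#' @export
attention_levels <- function() {
  c("Rest", "AOA1", "AOA2")
}

#' Construct a single labelled EEG trial
#'
#' An `eeg_trial` bundles one multichannel recording with its sampling rate
#' and attention label. Sample values are in arbitrary microvolt-scale units;
#' every complexity measure in the package uses a tolerance proportional to
#' the per-channel standard deviation, so the absolute scale is immaterial.
#'
#' @param samples Numeric matrix, channels x time. Row names, if present,
#'   must match `channels`.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier (integer or character).
#' @param condition One of `attention_levels()` (case-insensitive).
#' @param channels Ordered channel labels; defaults to the canonical montage.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(samples, fs, subject_id, condition,
                      channels = eeg_channels()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("`samples` must be a numeric matrix with no non-finite values",
         call. = FALSE)
  }
  if (nrow(samples) != length(channels)) {
    stop(sprintf("expected %d channels, got %d rows",
                 length(channels), nrow(samples)), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  condition <- normalize_condition(condition)
  rownames(samples) <- channels
  structure(
    list(samples = samples, fs = fs, channels = channels,
         subject_id = subject_id, condition = condition),
    class = "eeg_trial"
  )
}

normalize_condition <- function(condition) {
  stopifnot(length(condition) == 1L)
  idx <- match(toupper(condition), toupper(attention_levels()))
  if (is.na(idx)) {
    stop(sprintf("unknown condition '%s'; expected one of %s", condition,
                 paste(attention_levels(), collapse = ", ")), call. = FALSE)
  }
  attention_levels()[idx]
}

condition_factor <- function(x) {
  factor(vapply(as.character(x), normalize_condition, character(1)),
         levels = attention_levels())
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> subject %s, %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$condition, nrow(x$samples), ncol(x$samples),
              x$fs))
  invisible(x)
}

#' Assemble a tibble of trials
#'
#' Most pipeline functions operate on a *trial table*: a tibble with columns
#' `subject`, `condition` (factor over [attention_levels()]), `fs` and a
#' `trial` list-column of [eeg_trial] objects.
#'
#' @param trials A list of `eeg_trial` objects.
#' @return A tibble with one row per trial.
#' @export
trial_table <- function(trials) {
  stopifnot(length(trials) > 0,
            all(vapply(trials, inherits, logical(1), "eeg_trial")))
  tibble::tibble(
    subject = vapply(trials, function(t) as.character(t$subject_id),
                     character(1)),
    condition = condition_factor(
      vapply(trials, function(t) t$condition, character(1))),
    fs = vapply(trials, function(t) t$fs, numeric(1)),
    trial = trials
  )
}
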