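# Seeded synthetic-EEG generator. Trials are built as band-limited
# oscillations riding on a broadband stochastic component whose spectral
# slope is governed by a per-condition "complexity" knob, so that downstream
# entropy features recover a known condition ordering.

#' Configuration for the synthetic-EEG generator
#'
#' The generator emulates the study geometry (8 channels, 500 Hz, 60-s
#' trials, 13 subjects x 3 conditions = 39 trials) and injects a
#' condition-dependent complexity difference: each condition's broadband
#' component is 1/f^alpha noise with `alpha = 2 * (1 - complexity)`, so a
#' larger complexity value gives a flatter spectrum and a more irregular
#' signal. Sample entropy is monotone in this knob, which is what makes the
#' generated data decodable. Defaults order the conditions
#' AOA1 > AOA2 > Rest in complexity, the ordering reported for SampEn and
#' composite multiscale entropy in the attention study this pipeline targets.
#'
#' @param n_subjects Number of subjects (default 13; each contributes one
#'   trial per condition).
#' @param complexity Named numeric in `[0, 1]`, one entry per condition.
#' @param oscillation Named amplitudes (relative to the unit-variance
#'   broadband component) of the delta/theta/alpha/beta rhythms.
#' @param noise_floor Relative amplitude of the white measurement noise.
#' @param mixing Weight in `[0, 1]` of a common broadband source shared by
#'   all channels; the remainder is channel-independent, so per-channel
#'   features are correlated but not identical.
#' @param fs Sampling rate in Hz (500 for study-faithful runs).
#' @param duration Trial length in seconds (60 for study-faithful runs).
#' @param seed Master seed; all per-subject and per-trial random streams are
#'   derived from it by stable integer hashing, so any subset of the dataset
#'   is reproducible in isolation.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, duration = 4)
#' generate_dataset(cfg)
sim_config <- function(n_subjects = 13,
                       complexity = c(Rest = 0.30, AOA1 = 0.65, AOA2 = 0.45),
                       oscillation = c(delta = 1.0, theta = 0.8,
                                       alpha = 1.2, beta = 0.5),
                       noise_floor = 0.05,
                       mixing = 0.3,
                       fs = 500,
                       duration = 60,
                       seed = 1L) {
  stopifnot(n_subjects >= 2, fs > 0, duration > 0,
            mixing >= 0, mixing <= 1, noise_floor >= 0)
  if (!all(attention_levels() %in% names(complexity))) {
    stop("`complexity` must name every condition: ",
         paste(attention_levels(), collapse = ", "), call. = FALSE)
  }
  complexity <- complexity[attention_levels()]
  if (any(complexity < 0 | complexity > 1)) {
    stop("complexity values must lie in [0, 1]", call. = FALSE)
  }
  bands <- c("delta", "theta", "alpha", "beta")
  if (!all(bands %in% names(oscillation))) {
    stop("`oscillation` must name delta, theta, alpha and beta", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), complexity = complexity,
         oscillation = oscillation[bands], noise_floor = noise_floor,
         mixing = mixing, fs = fs, duration = duration,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Frequency edges of the classic EEG rhythms (Hz); each rhythm is rendered
# as a sinusoid at a subject-specific frequency inside its band.
rhythm_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# Stable hash of a small integer sequence onto [1, 2^31 - 2]; products stay
# below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(...) {
  s <- 104729
  for (k in c(...)) {
    s <- (s * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  }
  as.integer(s + 1)
}

subject_index <- function(subject_id) {
  if (is.numeric(subject_id)) return(as.integer(subject_id))
  sum(utf8ToInt(as.character(subject_id)) * 31^(seq_along(
    utf8ToInt(as.character(subject_id))) %% 7)) %% 1000003L
}

# 1/f^alpha Gaussian noise via spectral synthesis, unit SD.
colored_noise <- function(n, alpha) {
  freqs <- seq_len(floor(n / 2))
  amp <- freqs^(-alpha / 2)
  re <- rnorm(length(freqs)) * amp
  im <- rnorm(length(freqs)) * amp
  spec <- complex(real = c(0, re), imaginary = c(0, im))
  full <- c(spec, Conj(rev(spec[2:(length(spec) - if (n %% 2 == 0) 1 else 0)])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

# Subject-level draws shared across that subject's three conditions: overall
# gain (+/-20%) and the rhythm frequencies and phases for each channel.
# Complexity jitter is drawn per trial (not per subject): trial-level
# jitter keeps leave-one-trial-out honest, whereas a subject-level jitter
# would make each subject's three equal-complexity trials near-duplicates
# and bias null-data cross-validation far below chance (the held-out
# trial's nearest neighbours would carry the two wrong labels).
subject_profile <- function(config, subject_id) {
  n_ch <- length(eeg_channels())
  bands <- rhythm_bands()
  withr::with_seed(
    derive_seed(config$seed, 7741, subject_index(subject_id)), {
      list(
        gain = runif(1, 0.8, 1.2),
        freqs = vapply(bands, function(b) runif(1, b[1], b[2]), numeric(1)),
        phases = matrix(runif(n_ch * length(bands), 0, 2 * pi),
                        nrow = n_ch)
      )
    })
}

#' Generate one synthetic EEG trial
#'
#' Deterministic given `(config$seed, subject_id, condition, trial_seed)`;
#' the same arguments always reproduce the same sample matrix. A subject's
#' gain and rhythm frequencies are shared across that subject's conditions,
#' so only signal irregularity (plus independent noise realizations)
#' separates the classes; a small complexity jitter (+/- 0.05) is drawn
#' independently per trial.
#'
#' @param subject_id Subject identifier.
#' @param condition One of [attention_levels()].
#' @param config A [sim_config()].
#' @param trial_seed Extra stream offset, for generating replicate trials.
#' @return An [eeg_trial].
#' @export
generate_trial <- function(subject_id, condition, config = sim_config(),
                           trial_seed = 0L) {
  stopifnot(inherits(config, "sim_config"))
  condition <- normalize_condition(condition)
  prof <- subject_profile(config, subject_id)
  n <- round(config$fs * config$duration)
  n_ch <- length(eeg_channels())
  cond_idx <- match(condition, attention_levels())

  samples <- withr::with_seed(
    derive_seed(config$seed, subject_index(subject_id), cond_idx, trial_seed), {
      jitter <- runif(1, -0.05, 0.05)
      cx <- min(max(config$complexity[[condition]] + jitter, 0.02), 0.98)
      alpha <- 2 * (1 - cx)
      common <- colored_noise(n, alpha)
      tt <- seq_len(n) / config$fs
      osc_amp <- config$oscillation * 0.35
      out <- matrix(0, nrow = n_ch, ncol = n)
      for (ch in seq_len(n_ch)) {
        own <- colored_noise(n, alpha)
        broadband <- config$mixing * common + (1 - config$mixing) * own
        osc <- rep(0, n)
        for (b in seq_along(prof$freqs)) {
          osc <- osc + osc_amp[[b]] *
            sin(2 * pi * prof$freqs[[b]] * tt + prof$phases[ch, b])
        }
        out[ch, ] <- prof$gain * 20 *
          (broadband + osc + config$noise_floor * rnorm(n))
      }
      out
    })
  eeg_trial(samples, fs = config$fs, subject_id = subject_id,
            condition = condition)
}

#' Generate a full labelled dataset
#'
#' One trial per subject per condition; with the default 13 subjects this is
#' the 39-trial design evaluated under leave-one-out cross-validation.
#'
#' @inheritParams generate_trial
#' @return A trial table (see [trial_table()]) with `n_subjects * 3` rows,
#'   ordered by subject then condition.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- expand.grid(condition = attention_levels(),
                      subject = seq_len(config$n_subjects),
                      stringsAsFactors = FALSE)
  trials <- purrr::map2(grid$subject, grid$condition,
                        function(s, cond) generate_trial(s, cond, config))
  trial_table(trials)
}
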