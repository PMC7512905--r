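# Detrending and 9-level db4 wavelet denoising. The discrete wavelet
# transform is implemented directly (orthogonal periodized pyramid after
# symmetric padding): perfect reconstruction follows from the orthonormality
# of the Daubechies filter bank and is enforced by the test suite.

#' Preprocessing configuration
#'
#' Defaults reproduce the study-faithful chain: degree-1 polynomial
#' detrending, then a 9-level db4 decomposition in which the two finest
#' detail bands D1 (125-250 Hz at fs = 500) and D2 (62.5-125 Hz) and the
#' coarsest approximation A9 (0-0.49 Hz) are treated as noise and zeroed,
#' leaving an effective 0.5-62.5 Hz passband.
#'
#' @param detrend_degree Polynomial degree of the trend removed per channel.
#' @param wavelet Wavelet family; only `"db4"` is provided.
#' @param levels Decomposition depth.
#' @param drop_bands Subband names to zero; subset of `D1..D<levels>`, `A<levels>`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(detrend_degree = 1L, wavelet = "db4",
                              levels = 9L, drop_bands = c("D1", "D2", "A9")) {
  stopifnot(detrend_degree >= 0, levels >= 1)
  if (!identical(wavelet, "db4")) {
    stop("only the db4 wavelet is supported", call. = FALSE)
  }
  valid <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  bad <- setdiff(drop_bands, valid)
  if (length(bad)) {
    stop("unknown subband name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(detrend_degree = as.integer(detrend_degree),
                 wavelet = wavelet, levels = as.integer(levels),
                 drop_bands = drop_bands),
            class = "preprocess_config")
}

#' Remove a polynomial trend
#'
#' Subtracts the least-squares polynomial fit of the given degree; degree 1
#' is ordinary linear detrending and leaves a zero-mean signal.
#'
#' @param x Numeric vector.
#' @param degree Polynomial degree (>= 0).
#' @return The detrended vector.
#' @export
detrend_signal <- function(x, degree = 1L) {
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  if (length(x) < degree + 1) {
    stop("signal shorter than degree + 1", call. = FALSE)
  }
  if (degree == 0L) return(x - mean(x))
  tt <- seq_along(x) / length(x)   # scaled abscissa for conditioning
  basis <- outer(tt, 0:degree, `^`)
  stats::lsfit(basis, x, intercept = FALSE)$residuals
}

# db4 scaling (reconstruction low-pass) filter; 4 vanishing moments, 8 taps.
db4_rec_lo <- c(
   0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
  -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
   0.032883011666982945, -0.010597401784997278
)

db4_filters <- function() {
  rec_lo <- db4_rec_lo
  dec_lo <- rev(rec_lo)
  # quadrature mirror: alternate signs on the reversed low-pass
  dec_hi <- rev(rec_lo) * rep_len(c(-1, 1), length(rec_lo))
  dec_hi <- rev(dec_hi)
  list(lo = dec_lo, hi = dec_hi)
}

# One analysis step of the periodized orthogonal DWT (length must be even).
dwt_step <- function(x, f) {
  L <- length(x)
  half <- L / 2L
  starts <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  for (j in seq_along(f$lo)) {
    idx <- (starts + j - 1L) %% L + 1L
    a <- a + f$lo[j] * x[idx]
    d <- d + f$hi[j] * x[idx]
  }
  list(a = a, d = d)
}

# Synthesis step: transpose of the (orthogonal) analysis operator.
idwt_step <- function(a, d, f) {
  half <- length(a)
  L <- 2L * half
  x <- numeric(L)
  starts <- 2L * (seq_len(half) - 1L)
  for (j in seq_along(f$lo)) {
    idx <- (starts + j - 1L) %% L + 1L
    x[idx] <- x[idx] + a * f$lo[j] + d * f$hi[j]
  }
  x
}

# Full decomposition into details D1..Dlevels and approximation A<levels>.
dwt_pyramid <- function(x, levels) {
  f <- db4_filters()
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    step <- dwt_step(a, f)
    details[[lev]] <- step$d
    a <- step$a
  }
  list(details = details, approx = a)
}

idwt_pyramid <- function(decomp) {
  f <- db4_filters()
  a <- decomp$approx
  for (lev in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[lev]], f)
  }
  a
}

#' Wavelet denoising of one channel
#'
#' Decomposes the signal to `config$levels` db4 subbands, zeroes the bands in
#' `config$drop_bands`, and inverts the transform. The signal is first
#' reflect-padded to a multiple of `2^levels` so every pyramid level has even
#' length; the output is truncated back to the input length.
#'
#' @param x Numeric vector; must be at least `2^levels` samples long.
#' @param config A [preprocess_config()].
#' @return Denoised vector of the same length as `x`.
#' @export
wavelet_denoise <- function(x, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  n <- length(x)
  block <- 2^config$levels
  if (n < block) {
    stop(sprintf("signal too short for a %d-level decomposition",
                 config$levels), call. = FALSE)
  }
  padded_len <- as.integer(ceiling(n / block) * block)
  pad <- padded_len - n
  xp <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  decomp <- dwt_pyramid(xp, config$levels)
  for (band in config$drop_bands) {
    if (startsWith(band, "D")) {
      lev <- as.integer(substring(band, 2))
      decomp$details[[lev]] <- numeric(length(decomp$details[[lev]]))
    } else {
      decomp$approx <- numeric(length(decomp$approx))
    }
  }
  idwt_pyramid(decomp)[seq_len(n)]
}

#' Preprocess trials (detrend + wavelet denoise)
#'
#' Applies [detrend_signal()] then [wavelet_denoise()] independently to each
#' channel of each trial; labels, shape and sampling rate are preserved.
#'
#' @param trials A trial table (see [trial_table()]) or a single [eeg_trial].
#' @param config A [preprocess_config()].
#' @param denoise Set `FALSE` to detrend only (ablation).
#' @return Object of the same kind as `trials`, preprocessed.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, duration = 2)
#' preprocess_trials(generate_dataset(cfg))
preprocess_trials <- function(trials, config = preprocess_config(),
                              denoise = TRUE) {
  if (inherits(trials, "eeg_trial")) {
    samples <- trials$samples
    for (ch in seq_len(nrow(samples))) {
      y <- detrend_signal(samples[ch, ], config$detrend_degree)
      if (denoise) y <- wavelet_denoise(y, config)
      samples[ch, ] <- y
    }
    return(eeg_trial(samples, trials$fs, trials$subject_id, trials$condition,
                     trials$channels))
  }
  stopifnot(is.data.frame(trials), "trial" %in% names(trials))
  dplyr::mutate(trials, trial = purrr::map(.data$trial, preprocess_trials,
                                           config = config,
                                           denoise = denoise))
}
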