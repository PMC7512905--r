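# Complexity features: approximate, sample, composite multiscale, fuzzy and
# permutation entropy. Heavy pair counting is in C++; every fast path is
# pinned to a naive O(N^2) oracle in the test suite.

#' Entropy parameter set
#'
#' The parameterization shared by all regularity measures: embedding
#' dimension `m`, time delay `t`, tolerance `r` as a multiple of the
#' signal's standard deviation, coarse-graining scale `tau` (composite
#' multiscale entropy only) and the fuzzy membership exponent `fuzzy_power`.
#' Study-faithful values are `m = 2`, `t = 1`, `r = 0.15`, `tau = 30`.
#'
#' @param m Embedding dimension (>= 1).
#' @param t Time delay (>= 1).
#' @param r Tolerance coefficient, multiplied by the per-signal SD.
#' @param tau Coarse-graining scale factor for [cmpmse()].
#' @param fuzzy_power Exponent of the exponential membership function in
#'   [fuzzyen()]; the canonical fuzzy-entropy formulation uses 2.
#' @return An `entropy_params` list.
#' @export
entropy_params <- function(m = 2L, t = 1L, r = 0.15, tau = 1L,
                           fuzzy_power = 2) {
  stopifnot(m >= 1, t >= 1, r > 0, tau >= 1, fuzzy_power > 0)
  structure(list(m = as.integer(m), t = as.integer(t), r = r,
                 tau = as.integer(tau), fuzzy_power = fuzzy_power),
            class = "entropy_params")
}

resolve_tolerance <- function(x, r, r_abs) {
  if (!is.null(r_abs)) {
    stopifnot(r_abs > 0)
    return(r_abs)
  }
  s <- sd(x)
  if (s == 0) {
    stop("constant input: entropy tolerance r * SD is zero; ",
         "supply an absolute tolerance `r_abs`", call. = FALSE)
  }
  r * s
}

check_series <- function(x, min_len) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("input must be a finite numeric vector", call. = FALSE)
  }
  if (length(x) < min_len) {
    stop(sprintf("series of length %d too short (need >= %d)",
                 length(x), min_len), call. = FALSE)
  }
}

#' Approximate entropy
#'
#' Regularity statistic comparing template-match frequencies at embedding
#' dimensions `m` and `m + 1` under the Chebyshev distance, self-matches
#' included. Templates at both dimensions are indexed over `1..N - m*t` with
#' denominator `N - m*t`, so the conditional counts are nested: the result
#' is exactly non-negative and a constant series (with an absolute
#' tolerance) scores exactly zero.
#'
#' @param x Numeric series.
#' @param params An [entropy_params()]; `tau` is ignored.
#' @param r_abs Absolute tolerance overriding `params$r * sd(x)`; required
#'   for constant input.
#' @return A single non-negative number.
#' @export
#' @examples
#' set.seed(1)
#' apen(rnorm(500))
apen <- function(x, params = entropy_params(), r_abs = NULL) {
  check_series(x, params$m * params$t + 1)
  apen_cpp(x, params$m, params$t, resolve_tolerance(x, params$r, r_abs))
}

#' Sample entropy
#'
#' `-log(A / B)` where `B` counts template pairs (i < j) within tolerance at
#' dimension `m` and `A` the same pairs still matching at `m + 1`;
#' Chebyshev distance, self-matches excluded. Errors (carrying the counts)
#' when either count is zero, in which case the statistic is undefined.
#'
#' @inheritParams apen
#' @return A single non-negative number.
#' @export
sampen <- function(x, params = entropy_params(), r_abs = NULL) {
  check_series(x, params$m * params$t + 2)
  counts <- sampen_counts_cpp(x, params$m, params$t,
                              resolve_tolerance(x, params$r, r_abs))
  sampen_from_counts(counts)
}

sampen_from_counts <- function(counts) {
  if (counts[["B"]] == 0 || counts[["A"]] == 0) {
    stop(sprintf("sample entropy undefined: A = %g, B = %g template pairs",
                 counts[["A"]], counts[["B"]]), call. = FALSE)
  }
  -log(counts[["A"]] / counts[["B"]])
}

#' Fuzzy entropy
#'
#' Sample-entropy-like statistic in which the hard tolerance threshold is
#' replaced by the exponential membership `exp(-(d / r_abs)^n)` of the
#' Chebyshev distance `d` between baseline-removed templates (each template
#' has its own mean subtracted); normalizing the distance by the tolerance
#' keeps the statistic exactly invariant under affine transforms when
#' `r_abs` is a multiple of the signal SD. Returns
#' `log(phi_m) - log(phi_{m+1})` where `phi` is the mean pairwise
#' similarity, self-pairs excluded.
#'
#' @inheritParams apen
#' @return A single non-negative number.
#' @export
fuzzyen <- function(x, params = entropy_params(), r_abs = NULL) {
  check_series(x, params$m * params$t + 2)
  fuzzyen_cpp(x, params$m, params$t,
              resolve_tolerance(x, params$r, r_abs), params$fuzzy_power)
}

#' Composite coarse-graining
#'
#' For scale `tau`, returns the `tau` phase-shifted coarse-grained series:
#' the k-th series (k = 1..tau) averages consecutive non-overlapping
#' length-`tau` blocks starting at sample k, and has length
#' `floor((N - k + 1) / tau)`.
#'
#' @param x Numeric series of length >= `2 * tau`.
#' @param tau Scale factor (>= 1).
#' @return A list of `tau` numeric vectors.
#' @export
#' @examples
#' composite_coarse_grain(1:6, 2)
composite_coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  stopifnot(tau >= 1)
  check_series(x, 2 * tau)
  n <- length(x)
  lapply(seq_len(tau), function(k) {
    len <- (n - k + 1) %/% tau
    idx <- k + seq_len(len * tau) - 1L
    colMeans(matrix(x[idx], nrow = tau))
  })
}

#' Composite multiscale entropy
#'
#' Mean sample entropy over the `tau` composite coarse-grained series. The
#' absolute tolerance is anchored to the ORIGINAL (scale-1) series:
#' `r_abs = r * sd(x)`, reused at every scale, following multiscale-entropy
#' convention (set `per_scale_sd = TRUE` to re-anchor per scale for
#' sensitivity analyses). Coarse-grained series whose sample entropy is
#' undefined (zero match counts) are skipped with a warning; an error is
#' raised only if all `tau` are undefined. At `tau = 1` the value equals
#' [sampen()] exactly.
#'
#' @inheritParams apen
#' @param per_scale_sd Anchor the tolerance to each coarse-grained series'
#'   own SD instead of the original SD.
#' @return A single number.
#' @export
cmpmse <- function(x, params = entropy_params(tau = 30L), r_abs = NULL,
                   per_scale_sd = FALSE) {
  check_series(x, max(2 * params$tau, params$m * params$t + 2))
  base_r <- if (per_scale_sd) NULL else resolve_tolerance(x, params$r, r_abs)
  series <- composite_coarse_grain(x, params$tau)
  vals <- vapply(series, function(y) {
    tryCatch(sampen(y, params, r_abs = base_r), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(vals))) {
    stop("composite multiscale entropy undefined: sample entropy undefined ",
         "for every coarse-grained series", call. = FALSE)
  }
  if (anyNA(vals)) {
    warning(sprintf("%d of %d coarse-grained series had undefined sample %s",
                    sum(is.na(vals)), params$tau,
                    "entropy; averaging over the rest"), call. = FALSE)
  }
  mean(vals, na.rm = TRUE)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution, normalized by
#' `log(order!)` to `[0, 1]`. Ties are broken by order of occurrence. The
#' source study reports this measure only as a lower-performing comparison
#' feature; defaults (`order = 3`, `delay = 1`) are this package's choice.
#'
#' @param x Numeric series.
#' @param order Pattern length (>= 2).
#' @param delay Lag between pattern elements.
#' @return Normalized entropy in `[0, 1]`.
#' @export
perm_entropy <- function(x, order = 3L, delay = 1L) {
  order <- as.integer(order); delay <- as.integer(delay)
  stopifnot(order >= 2, delay >= 1)
  check_series(x, order * delay)
  n_pat <- length(x) - (order - 1L) * delay
  emb <- vapply(seq_len(order),
                function(k) x[seq_len(n_pat) + (k - 1L) * delay],
                numeric(n_pat))
  codes <- apply(emb, 1L, function(row) {
    paste(rank(row, ties.method = "first"), collapse = "")
  })
  p <- tabulate(factor(codes)) / n_pat
  -sum(p * log(p)) / log(factorial(order))
}

entropy_measures <- function() {
  c("apen", "sampen", "cmpmse", "fuzzyen", "permen")
}

entropy_fun <- function(measure) {
  switch(measure,
         apen = function(x, params) apen(x, params),
         sampen = function(x, params) sampen(x, params),
         cmpmse = function(x, params) cmpmse(x, params),
         fuzzyen = function(x, params) fuzzyen(x, params),
         permen = function(x, params) perm_entropy(x),
         stop("unknown measure '", measure, "'", call. = FALSE))
}

#' Extract per-channel entropy features from trials
#'
#' Computes the requested complexity measure on every (trial, channel) pair
#' and returns a feature table: one row per trial with `subject`,
#' `condition` and one numeric column per channel, named
#' `<measure>_<channel>`. Trials are expected to be preprocessed
#' (see [preprocess_trials()]). A trial/channel whose entropy is undefined
#' yields `NA` with a warning.
#'
#' @param trials A trial table.
#' @param measure One of `"apen"`, `"sampen"`, `"cmpmse"`, `"fuzzyen"`,
#'   `"permen"`.
#' @param params An [entropy_params()].
#' @param channels Channel subset (defaults to all eight).
#' @return A tibble with `nrow(trials)` rows.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, duration = 2)
#' trials <- preprocess_trials(generate_dataset(cfg))
#' extract_features(trials, "sampen")
extract_features <- function(trials, measure = "sampen",
                             params = entropy_params(),
                             channels = eeg_channels()) {
  measure <- match.arg(measure, entropy_measures())
  stopifnot(is.data.frame(trials), "trial" %in% names(trials))
  bad <- setdiff(channels, eeg_channels())
  if (length(bad)) {
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fun <- entropy_fun(measure)
  feats <- purrr::map(trials$trial, function(tr) {
    vapply(channels, function(ch) {
      tryCatch(fun(tr$samples[ch, ], params),
               error = function(e) {
                 warning(sprintf("undefined %s for subject %s/%s channel %s",
                                 measure, tr$subject_id, tr$condition, ch),
                         call. = FALSE)
                 NA_real_
               })
    }, numeric(1))
  })
  mat <- do.call(rbind, feats)
  colnames(mat) <- paste0(measure, "_", channels)
  dplyr::bind_cols(
    tibble::tibble(subject = trials$subject, condition = trials$condition),
    tibble::as_tibble(mat)
  )
}
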