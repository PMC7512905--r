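# Naive, vectorized-in-R reference implementations of the regularity
# statistics, kept deliberately independent of the package's C++ counting
# (full distance matrices, no windowing or pruning).

oracle_templates <- function(x, m, t, nt) {
  vapply(seq_len(m), function(k) x[seq_len(nt) + (k - 1L) * t], numeric(nt))
}

# Chebyshev distance matrix between rows of E
oracle_chebmat <- function(E) {
  d <- matrix(0, nrow(E), nrow(E))
  for (k in seq_len(ncol(E))) {
    d <- pmax(d, abs(outer(E[, k], E[, k], "-")))
  }
  d
}

oracle_apen <- function(x, m = 2L, t = 1L, r) {
  nt <- length(x) - m * t
  dm <- oracle_chebmat(oracle_templates(x, m, t, nt))
  dm1 <- oracle_chebmat(oracle_templates(x, m + 1L, t, nt))
  phi <- function(d) mean(log(rowSums(d <= r) / nt))
  phi(dm) - phi(pmax(dm, dm1))
}

oracle_sampen_counts <- function(x, m = 2L, t = 1L, r) {
  nt <- length(x) - m * t
  dm <- oracle_chebmat(oracle_templates(x, m, t, nt))
  dm1 <- pmax(dm, oracle_chebmat(oracle_templates(x, m + 1L, t, nt)))
  up <- upper.tri(dm)
  c(A = sum(dm1[up] <= r), B = sum(dm[up] <= r))
}

oracle_sampen <- function(x, m = 2L, t = 1L, r) {
  counts <- oracle_sampen_counts(x, m, t, r)
  -log(counts[["A"]] / counts[["B"]])
}

oracle_fuzzyen <- function(x, m = 2L, t = 1L, r, n = 2) {
  nt <- length(x) - m * t
  phi <- function(mm) {
    E <- oracle_templates(x, mm, t, nt)
    E <- E - rowMeans(E)
    d <- oracle_chebmat(E)
    mu <- exp(-(d / r)^n)
    diag(mu) <- 0
    sum(mu) / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1L))
}

# Tiny trial tables for structural tests (fast to generate)
small_trials <- function(n_subjects = 2, duration = 2, seed = 1, ...) {
  generate_dataset(sim_config(n_subjects = n_subjects, duration = duration,
                              seed = seed, ...))
}

# Well-separated 3-class Gaussian features in the feature-table layout
blob_features <- function(n_per_class = 13, d = 2, sep = 10, sd = 0.5,
                          seed = 1) {
  withr::with_seed(seed, {
    # class centers spaced along the main diagonal: every feature carries
    # signal, so none is standardized into pure noise
    centers <- sep / sqrt(d) * matrix(c(0, 1, 2), 3, d)
    x <- do.call(rbind, lapply(1:3, function(cl) {
      matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
        matrix(centers[cl, ], n_per_class, d, byrow = TRUE)
    }))
    tibble::tibble(
      subject = as.character(rep(seq_len(n_per_class), 3)),
      condition = factor(rep(attention_levels(), each = n_per_class),
                         levels = attention_levels())
    ) |>
      dplyr::bind_cols(tibble::as_tibble(
        stats::setNames(as.data.frame(x), paste0("f", seq_len(d)))))
  })
}

# 1/f^alpha Gaussian noise via spectral synthesis (test fixture; independent
# of the package generator's internals)
pink_noise <- function(n, alpha = 1) {
  freqs <- seq_len(floor(n / 2))
  amp <- freqs^(-alpha / 2)
  spec <- complex(real = c(0, stats::rnorm(length(freqs)) * amp),
                  imaginary = c(0, stats::rnorm(length(freqs)) * amp))
  tail_idx <- 2:(length(spec) - if (n %% 2 == 0) 1 else 0)
  full <- c(spec, Conj(rev(spec[tail_idx])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}
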