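test_that("polynomial detrending removes the fitted trend exactly", {
  tt <- seq_len(500)
  line <- 3.2 * tt + 40
  expect_lt(max(abs(detrend_signal(line, 1))), 1e-8)
  expect_equal(detrend_signal(rep(5, 100), 0), rep(0, 100))

  # degree-1 residuals must match an independent normal-equations fit
  withr::with_seed(4, {
    y <- 1e-6 * tt^3 - 0.02 * tt + rnorm(500)
  })
  X <- cbind(1, tt)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(max(abs(detrend_signal(y, 1) - (y - X %*% beta))), 1e-8)

  expect_lt(abs(mean(detrend_signal(y, 2))), 1e-8)
  expect_error(detrend_signal(c(1, NA, 3), 1), "non-finite")
  expect_error(detrend_signal(c(1), 1), "shorter")
})

test_that("the db4 pyramid reconstructs perfectly when no band is dropped", {
  withr::with_seed(5, x <- rnorm(4096))
  cfg <- preprocess_config(drop_bands = character(0))
  expect_lt(max(abs(wavelet_denoise(x, cfg) - x)), 1e-8)
  # non-dyadic length: reflect-padded, still size-preserving and accurate
  y <- x[seq_len(3000)]
  rec <- wavelet_denoise(y, cfg)
  expect_length(rec, 3000)
  expect_lt(max(abs(rec - y)) / stats::sd(y), 1e-6)
})

test_that("dropping D1, D2 and A9 suppresses out-of-band energy", {
  fs <- 500
  tt <- seq_len(5000) / fs
  cfg <- preprocess_config()
  rms <- function(v) sqrt(mean(v^2))
  s90 <- sin(2 * pi * 90 * tt)    # inside D2 (62.5-125 Hz)
  s10 <- sin(2 * pi * 10 * tt)    # inside the retained band
  expect_lt(rms(wavelet_denoise(s90, cfg)) / rms(s90), 0.2)
  expect_gt(rms(wavelet_denoise(s10, cfg)) / rms(s10), 0.9)
  s110 <- sin(2 * pi * 110 * tt)  # deeper into D2
  expect_lt(rms(wavelet_denoise(s110, cfg)) / rms(s110), 0.01)
  expect_equal(wavelet_denoise(rep(0, 2048), cfg), rep(0, 2048))
})

test_that("wavelet denoising is linear and near-idempotent", {
  withr::with_seed(6, {
    x <- rnorm(2048)
    y <- rnorm(2048)
  })
  cfg <- preprocess_config()
  lhs <- wavelet_denoise(2 * x - 3 * y, cfg)
  rhs <- 2 * wavelet_denoise(x, cfg) - 3 * wavelet_denoise(y, cfg)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)

  once <- wavelet_denoise(x, cfg)
  twice <- wavelet_denoise(once, cfg)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(twice) - rms(once)) / rms(once), 0.01)
})

test_that("full-length signals keep their length through denoising", {
  withr::with_seed(7, x <- rnorm(30000))
  expect_length(wavelet_denoise(x, preprocess_config()), 30000)
})

test_that("preprocessing config validates its inputs", {
  expect_error(preprocess_config(wavelet = "haar"), "db4")
  expect_error(preprocess_config(drop_bands = "D12"), "unknown subband")
  expect_error(wavelet_denoise(rnorm(100), preprocess_config()), "too short")
})

test_that("trials are preprocessed per channel, preserving labels and shape", {
  trials <- small_trials(n_subjects = 2, duration = 2, seed = 2)
  out <- preprocess_trials(trials)
  expect_identical(out$condition, trials$condition)
  expect_identical(out$subject, trials$subject)
  expect_identical(dim(out$trial[[1]]$samples), dim(trials$trial[[1]]$samples))

  # per-channel independence: permuting channels commutes with preprocessing
  tr <- trials$trial[[1]]
  perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
  permuted <- eeg_trial(tr$samples[perm, ], tr$fs, tr$subject_id,
                        tr$condition, channels = tr$channels[perm])
  direct <- preprocess_trials(permuted)
  straight <- preprocess_trials(tr)
  expect_equal(unname(direct$samples), unname(straight$samples[perm, ]),
               tolerance = 1e-12)

  zeros <- eeg_trial(matrix(0, 8, 1024), 500, "z", "Rest")
  expect_equal(preprocess_trials(zeros)$samples, zeros$samples)
})
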