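test_that("fast entropy paths match the naive oracles", {
  # a spread of lengths, tolerances and lags; exact count agreement expected
  for (k in 1:6) {
    withr::with_seed(100 + k, x <- rnorm(120 + 40 * k))
    r_coef <- c(0.1, 0.15, 0.2, 0.25, 0.15, 0.2)[k]
    t_lag <- c(1, 1, 1, 2, 1, 3)[k]
    p <- entropy_params(t = t_lag, r = r_coef)
    r_abs <- r_coef * sd(x)
    expect_equal(apen(x, p), oracle_apen(x, 2, t_lag, r_abs),
                 tolerance = 1e-10)
    expect_equal(sampen(x, p), oracle_sampen(x, 2, t_lag, r_abs),
                 tolerance = 1e-10)
    expect_equal(fuzzyen(x, p), oracle_fuzzyen(x, 2, t_lag, r_abs, 2),
                 tolerance = 1e-10)
  }
  # uniform noise and higher embedding dimension
  withr::with_seed(200, u <- runif(300))
  p3 <- entropy_params(m = 3, r = 0.2)
  expect_equal(apen(u, p3), oracle_apen(u, 3, 1, 0.2 * sd(u)),
               tolerance = 1e-10)
  expect_equal(sampen(u, p3), oracle_sampen(u, 3, 1, 0.2 * sd(u)),
               tolerance = 1e-10)
})

test_that("degenerate and structured inputs behave as the definitions say", {
  const <- rep(2.5, 120)
  expect_equal(apen(const, r_abs = 0.1), 0)
  expect_equal(fuzzyen(const, r_abs = 0.1), 0)
  expect_error(apen(const), "constant input")
  expect_error(sampen(const), "constant input")

  # strictly alternating series: every m-match extends to m+1
  alt <- rep(c(1, 2), 50)
  expect_equal(sampen(alt, r_abs = 0.1), 0)

  # undefined sample entropy carries its counts
  expect_error(sampen(c(1, 5, 9, 2, 8, 4), r_abs = 1e-6),
               "A = 0.*B = 0|undefined")
})

test_that("relative tolerance makes entropies affine-invariant", {
  withr::with_seed(9, x <- rnorm(250))
  p <- entropy_params()
  for (f in list(apen, sampen, fuzzyen)) {
    expect_equal(f(5 * x, p), f(x, p), tolerance = 1e-10)
    expect_equal(f(x + 100, p), f(x, p), tolerance = 1e-10)
    expect_equal(f(-2 * x + 7, p), f(x, p), tolerance = 1e-10)
  }
})

test_that("entropies are non-negative and non-increasing in tolerance", {
  rs <- c(0.10, 0.15, 0.20, 0.25)
  for (seed in 1:5) {
    withr::with_seed(300 + seed, x <- rnorm(300))
    se <- vapply(rs, function(r) sampen(x, entropy_params(r = r)), numeric(1))
    fe <- vapply(rs, function(r) fuzzyen(x, entropy_params(r = r)), numeric(1))
    ae <- vapply(rs, function(r) apen(x, entropy_params(r = r)), numeric(1))
    expect_true(all(diff(se) <= 0))
    expect_true(all(diff(fe) <= 0))
    expect_true(all(se >= 0), info = "SampEn >= 0")
    expect_true(all(fe >= 0), info = "FuzzyEn >= 0")
    expect_true(all(ae >= 0), info = "ApEn >= 0")
  }
  # doubling the absolute tolerance strictly lowers fuzzy entropy
  withr::with_seed(310, y <- rnorm(300))
  expect_lt(fuzzyen(y, r_abs = 0.3 * sd(y)), fuzzyen(y, r_abs = 0.15 * sd(y)))
})

test_that("composite coarse-graining produces all tau phase-shifted series", {
  expect_equal(composite_coarse_grain(1:6, 2),
               list(c(1.5, 3.5, 5.5), c(2.5, 4.5)))
  expect_equal(composite_coarse_grain(1:10, 1), list(as.numeric(1:10)))
  withr::with_seed(11, x <- rnorm(101))
  cg <- composite_coarse_grain(x, 3)
  expect_equal(lengths(cg),
               vapply(1:3, function(k) as.integer((101 - k + 1) %/% 3),
                      integer(1)))
  expect_error(composite_coarse_grain(1:3, 0))
})

test_that("composite multiscale entropy composes sample entropy", {
  withr::with_seed(12, x <- rnorm(2000))
  p1 <- entropy_params(tau = 1)
  expect_identical(cmpmse(x, p1), sampen(x, p1))

  p5 <- entropy_params(tau = 5)
  r_abs <- 0.15 * sd(x)
  expected <- mean(vapply(composite_coarse_grain(x, 5), oracle_sampen,
                          numeric(1), m = 2, t = 1, r = r_abs))
  expect_equal(cmpmse(x, p5), expected, tolerance = 1e-10)
})

test_that("multiscale entropy separates white from long-memory noise", {
  # hallmark multiscale behaviour: white-noise entropy collapses with
  # scale, 1/f noise retains structure and overtakes it at large scale
  p1 <- entropy_params(tau = 1)
  p10 <- entropy_params(tau = 10)
  contrasts <- vapply(1:20, function(seed) {
    withr::with_seed(400 + seed, {
      w <- rnorm(1500)
      pink <- pink_noise(1500, 1)
    })
    c(decline = cmpmse(w, p1) - cmpmse(w, p10),
      pink_vs_white = cmpmse(pink, p10) - cmpmse(w, p10))
  }, numeric(2))
  expect_gt(mean(contrasts["decline", ]), 0)
  expect_gt(mean(contrasts["pink_vs_white", ]), 0)
})

test_that("permutation entropy spans its normalized range", {
  expect_equal(perm_entropy(seq_len(100)), 0)
  withr::with_seed(13, u <- runif(10000))
  expect_lt(abs(perm_entropy(u, 3) - 1), 0.01)
  # reversing and negating preserves the pattern distribution's entropy
  withr::with_seed(14, v <- rnorm(500))
  expect_equal(perm_entropy(v, 3), perm_entropy(rev(-v), 3), tolerance = 1e-12)
  expect_error(perm_entropy(rnorm(50), order = 1))
})

test_that("feature extraction yields aligned, labelled tables", {
  trials <- preprocess_trials(small_trials(n_subjects = 2, duration = 2))
  feats <- extract_features(trials, "sampen")
  expect_s3_class(feats, "tbl_df")
  expect_equal(dim(feats), c(6L, 10L))
  expect_named(feats, c("subject", "condition",
                        paste0("sampen_", eeg_channels())))
  expect_false(anyNA(feats))
  expect_identical(feats$condition, trials$condition)

  one <- extract_features(trials, "apen", channels = "Cz")
  expect_named(one, c("subject", "condition", "apen_Cz"))

  # duplicated trials give duplicated rows
  dup <- trials[c(1, 1), ]
  fd <- extract_features(dup, "sampen")
  expect_identical(fd[1, -1], fd[2, -1])

  expect_error(extract_features(trials, "sampen", channels = "Oz"),
               "unknown channel")
})
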