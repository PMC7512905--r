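test_that("LDA separates well-separated classes and matches MASS", {
  feats <- blob_features(n_per_class = 13, d = 2, sep = 8, sd = 0.6)
  x <- as.matrix(feats[, c("f1", "f2")])
  y <- feats$condition
  model <- lda_train(x, y)
  expect_false(model$ridged)
  expect_equal(as.character(predict(model, x)), as.character(y))

  # harder problem: predictions must agree with MASS::lda (equal priors)
  withr::with_seed(31, {
    x2 <- x + matrix(rnorm(length(x), sd = 3), nrow(x))
  })
  model2 <- lda_train(x2, y)
  ref <- MASS::lda(x2, grouping = y, prior = rep(1 / 3, 3))
  expect_equal(as.character(predict(model2, x2)),
               as.character(predict(ref, x2)$class))

  # discriminant scores match the pooled-covariance formula directly
  pooled <- Reduce(`+`, lapply(levels(y), function(cl) {
    xc <- scale(x2[y == cl, ], scale = FALSE)
    crossprod(xc)
  })) / (nrow(x2) - 3)
  mu <- t(sapply(levels(y), function(cl) colMeans(x2[y == cl, ])))
  oracle_scores <- x2 %*% solve(pooled) %*% t(mu) -
    matrix(0.5 * rowSums((mu %*% solve(pooled)) * mu), nrow(x2), 3,
           byrow = TRUE)
  expect_equal(as.character(predict(model2, x2)),
               levels(y)[apply(oracle_scores, 1, which.max)])
})

test_that("LDA is equivariant under label permutation", {
  feats <- blob_features(n_per_class = 10, d = 2, sep = 6, sd = 1, seed = 5)
  x <- as.matrix(feats[, c("f1", "f2")])
  y <- feats$condition
  perm <- c(Rest = "AOA2", AOA1 = "Rest", AOA2 = "AOA1")
  y_perm <- factor(unname(perm[as.character(y)]), levels = levels(y))
  pred <- predict(lda_train(x, y), x)
  pred_perm <- predict(lda_train(x, y_perm), x)
  expect_equal(unname(perm[as.character(pred)]), as.character(pred_perm))
})

test_that("singular pooled covariance triggers the ridge fallback", {
  feats <- blob_features(n_per_class = 5, d = 2, sep = 5, sd = 0.5, seed = 9)
  x <- as.matrix(feats[, c("f1", "f2")])
  x <- cbind(x, x[, 1])   # exactly collinear feature
  model <- lda_train(x, feats$condition)
  expect_true(model$ridged)
  expect_s3_class(predict(model, x), "factor")
})

test_that("the RBF SVM solves non-linear layouts where LDA cannot", {
  # XOR-style layout folded into two of three classes
  withr::with_seed(32, {
    n <- 10
    quad <- rbind(
      cbind(rnorm(n, 2, 0.4), rnorm(n, 2, 0.4)),
      cbind(rnorm(n, -2, 0.4), rnorm(n, -2, 0.4)),
      cbind(rnorm(n, -2, 0.4), rnorm(n, 2, 0.4)),
      cbind(rnorm(n, 2, 0.4), rnorm(n, -2, 0.4)),
      cbind(rnorm(n, 0, 0.3), rnorm(n, 6, 0.3))
    )
  })
  labels <- rep(c("Rest", "Rest", "AOA1", "AOA1", "AOA2"), each = 10)
  # subsample to balance: 10 Rest, 10 AOA1, 10 AOA2
  keep <- c(1:5, 11:15, 21:25, 31:35, 41:50)
  feats <- tibble::tibble(subject = as.character(seq_along(keep)),
                          condition = factor(labels[keep],
                                             levels = attention_levels()),
                          f1 = quad[keep, 1], f2 = quad[keep, 2])
  svm_res <- loocv(feats, "svm", gamma = 1)
  lda_res <- loocv(feats, "lda")
  expect_gt(svm_res$average_rate, 90)
  expect_lte(lda_res$average_rate, 60)
})

test_that("LOOCV is deterministic, balanced and self-consistent", {
  feats <- blob_features(n_per_class = 13, d = 3, sep = 4, sd = 2, seed = 7)
  a <- loocv(feats, "svm")
  b <- loocv(feats, "svm")
  expect_identical(a$confusion, b$confusion)
  expect_equal(unname(rowSums(a$confusion)), rep(13, 3))
  expect_equal(a$chi2_p, chi2_vs_chance(diag(a$confusion), 13)$p_value)
  expect_equal(a$average_rate, mean(a$per_class_rate))

  perfect <- loocv(blob_features(13, 2, sep = 6, sd = 0.5, seed = 8), "svm")
  expect_equal(unname(perfect$per_class_rate), c(100, 100, 100))

  unbal <- feats[-1, ]
  expect_error(loocv(unbal, "lda"), "unbalanced")

  # all-identical features collapse to a single predicted class
  flat <- feats
  flat[, c("f1", "f2", "f3")] <- 1
  flat_res <- loocv(flat, "lda", standardize = TRUE)
  expect_equal(sum(colSums(flat_res$confusion) > 0), 1L)
  expect_lte(flat_res$average_rate, 34)
})

test_that("label-shuffled features classify at chance", {
  feats <- blob_features(n_per_class = 13, d = 4, sep = 0, sd = 1, seed = 10)
  rates <- withr::with_seed(33, {
    vapply(1:30, function(i) {
      shuffled <- feats
      shuffled$condition <- sample(feats$condition)
      loocv(shuffled, "lda")$average_rate
    }, numeric(1))
  })
  band <- 100 * stats::qbinom(c(0.025, 0.975), 39, 1 / 3) / 39
  expect_gte(median(rates), band[1])
  expect_lte(median(rates), band[2])
})

test_that("fold standardization uses training rows only", {
  # mirror LOOCV with explicit training-only scaling; an extreme held-out
  # outlier must leave every fold's confusion identical to the package's
  feats <- blob_features(n_per_class = 4, d = 2, sep = 5, sd = 1, seed = 12)
  feats$f1[1] <- 1e6   # extreme outlier, held out in fold 1
  x <- as.matrix(feats[, c("f1", "f2")])
  y <- factor(feats$condition, levels = attention_levels())
  manual <- matrix(0L, 3, 3, dimnames = list(levels(y), levels(y)))
  for (i in seq_len(nrow(x))) {
    mu <- colMeans(x[-i, , drop = FALSE])
    sdev <- apply(x[-i, , drop = FALSE], 2, sd)
    xtr <- scale(x[-i, , drop = FALSE], mu, sdev)
    xte <- scale(x[i, , drop = FALSE], mu, sdev)
    pred <- as.character(predict(lda_train(xtr, y[-i]), xte))
    manual[as.character(y[i]), pred] <- manual[as.character(y[i]), pred] + 1L
  }
  pkg_confusion <- loocv(feats, "lda")$confusion
  expect_equal(unname(pkg_confusion), unname(manual))
})

test_that("tidy, glance and autoplot expose the result surface", {
  res <- loocv(blob_features(5, 2, sep = 6, seed = 3), "lda")
  td <- tidy(res)
  expect_equal(nrow(td), 3L)
  expect_equal(td$n_correct, unname(diag(res$confusion)))
  gl <- glance(res)
  expect_equal(gl$average_rate, res$average_rate)
  expect_equal(gl$classifier, "lda")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("sweeps return one result row per setting, in order", {
  base <- blob_features(4, 2, sep = 5, seed = 2)
  settings <- stats::setNames(rep(list(base), 9), paste0("tau_", 1:9))
  sw <- sweep_classify(settings, "lda")
  expect_equal(nrow(sw), 9L)
  expect_equal(sw$setting, paste0("tau_", 1:9))
  expect_s3_class(sw$results[[1]], "attention_clf")
  expect_error(sweep_classify(list()), "empty")
})
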