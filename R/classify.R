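# Three-class attention classifiers: pooled-covariance Gaussian LDA
# (implemented directly, cross-checked against MASS::lda in the tests) and
# a libsvm RBF SVM via e1071, both evaluated under leave-one-out
# cross-validation with per-training-fold feature standardization.

#' Train a pooled-covariance Gaussian LDA classifier
#'
#' Equal priors; the discriminant score of class c at feature vector x is
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2` with `S` the pooled within-class
#' covariance. When `S` is numerically singular a ridge
#' `lambda * tr(S)/d * I` is added and the model is flagged.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Class labels (coerced to a factor over [attention_levels()] when
#'   they match the attention conditions).
#' @param lambda Ridge coefficient used only on singular pooled covariance.
#' @return An `lda_model`.
#' @export
lda_train <- function(x, y, lambda = 1e-6) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  stopifnot(nrow(x) == length(y), all(table(y) >= 2), all(is.finite(x)))
  classes <- levels(y)
  d <- ncol(x)
  means <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                    numeric(d)))
  centered <- x - means[as.integer(y), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(x) - length(classes))
  ridged <- FALSE
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(inv) || rcond(pooled) < 1e-12) {
    ridge <- lambda * sum(diag(pooled)) / d
    if (ridge <= 0) ridge <- lambda   # zero covariance: pure ridge
    pooled <- pooled + ridge * diag(d)
    inv <- solve(pooled)
    ridged <- TRUE
  }
  structure(list(means = means, cov_inv = inv, classes = classes,
                 ridged = ridged),
            class = "lda_model")
}

as_class_factor <- function(y) {
  if (is.factor(y)) return(droplevels(y))
  if (all(toupper(as.character(y)) %in% toupper(attention_levels()))) {
    return(condition_factor(y))
  }
  factor(y)
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- newdata %*% object$cov_inv %*% t(object$means) -
    matrix(0.5 * rowSums((object$means %*% object$cov_inv) * object$means),
           nrow(newdata), length(object$classes), byrow = TRUE)
  colnames(scores) <- object$classes
  # ties broken by class order
  idx <- apply(scores, 1L, which.max)
  factor(object$classes[idx], levels = object$classes)
}

#' Train an RBF-kernel SVM classifier (libsvm via e1071)
#'
#' Soft-margin C-classification with the radial kernel and one-vs-one
#' multiclass voting, the libsvm defaults: `cost = 1`,
#' `gamma = 1/ncol(x)`. Feature standardization is handled by the caller
#' (see [loocv()]), not inside libsvm.
#'
#' @inheritParams lda_train
#' @param cost Soft-margin penalty C.
#' @param gamma RBF kernel width; default `1/ncol(x)`.
#' @return An `svm_model` wrapping the e1071 fit.
#' @export
svm_train <- function(x, y, cost = 1, gamma = NULL) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  stopifnot(nrow(x) == length(y), all(is.finite(x)))
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- e1071::svm(x = x, y = y, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, classes = levels(y)), class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  pred <- predict(object$fit, newdata, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  cls <- object$classes
  if (length(cls) < 3 || is.null(dv)) {
    return(factor(as.character(pred), levels = cls))
  }
  # re-derive one-vs-one votes so ties break by aggregate decision-value
  # margin, then by class order
  out <- character(nrow(newdata))
  pair_names <- strsplit(colnames(dv), "/", fixed = TRUE)
  for (i in seq_len(nrow(newdata))) {
    votes <- stats::setNames(numeric(length(cls)), cls)
    margin <- stats::setNames(numeric(length(cls)), cls)
    for (p in seq_along(pair_names)) {
      a <- pair_names[[p]][1]; b <- pair_names[[p]][2]
      v <- dv[i, p]
      winner <- if (v > 0) a else b
      votes[winner] <- votes[winner] + 1
      margin[a] <- margin[a] + v
      margin[b] <- margin[b] - v
    }
    best <- names(votes)[votes == max(votes)]
    if (length(best) > 1) best <- best[which.max(margin[best])]
    out[i] <- best[1]
  }
  factor(out, levels = cls)
}

train_classifier <- function(x, y, classifier, cost = 1, gamma = NULL,
                             lambda = 1e-6) {
  switch(classifier,
         lda = lda_train(x, y, lambda = lambda),
         svm = svm_train(x, y, cost = cost, gamma = gamma))
}

#' Leave-one-out cross-validated attention classification
#'
#' For each trial, trains on the remaining `n - 1` trials and predicts the
#' held-out one; accumulates the 3x3 confusion matrix, per-class and
#' average identification rates, and the chi-squared test of the diagonal
#' counts against the 33.3% chance level. Labels must be balanced. When
#' `standardize = TRUE` (default) features are z-scored using the training
#' fold's statistics only, so no information leaks from the held-out trial.
#'
#' @param features A feature table: `subject`, `condition`, then numeric
#'   feature columns (see [extract_features()]).
#' @param classifier `"lda"` or `"svm"`.
#' @param standardize Z-score features per training fold.
#' @param cost,gamma SVM hyperparameters (see [svm_train()]).
#' @return An `attention_clf` object; see [tidy.attention_clf()],
#'   [glance.attention_clf()] and [autoplot.attention_clf()].
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 4, duration = 2)
#' feats <- extract_features(preprocess_trials(generate_dataset(cfg)), "sampen")
#' loocv(feats, "svm")
loocv <- function(features, classifier = c("svm", "lda"),
                  standardize = TRUE, cost = 1, gamma = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(all(c("subject", "condition") %in% names(features)))
  cols <- feature_columns(features)
  if (!length(cols)) stop("no numeric feature columns", call. = FALSE)
  x <- as.matrix(features[, cols, drop = FALSE])
  if (any(!is.finite(x))) {
    stop("non-finite feature values; inspect the feature table", call. = FALSE)
  }
  y <- condition_factor(features$condition)
  counts <- table(y)
  if (length(unique(counts)) != 1L) {
    stop("unbalanced labels: chance level is only defined for balanced ",
         "classes (counts: ", paste(counts, collapse = ", "), ")",
         call. = FALSE)
  }
  n_per_class <- unname(counts[1])
  lv <- levels(y)
  confusion <- matrix(0L, 3, 3, dimnames = list(true = lv, predicted = lv))
  for (i in seq_len(nrow(x))) {
    xtr <- x[-i, , drop = FALSE]
    xte <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sdev <- apply(xtr, 2, sd)
      sdev[sdev == 0] <- 1
      xtr <- scale(xtr, center = mu, scale = sdev)
      xte <- scale(xte, center = mu, scale = sdev)
    }
    model <- train_classifier(xtr, y[-i], classifier, cost = cost,
                              gamma = gamma)
    pred <- as.character(predict(model, xte))
    confusion[as.character(y[i]), pred] <- confusion[as.character(y[i]), pred] + 1L
  }
  per_class <- 100 * diag(confusion) / n_per_class
  chi2 <- chi2_vs_chance(diag(confusion), n_per_class)
  structure(
    list(confusion = confusion,
         per_class_rate = per_class,
         average_rate = mean(per_class),
         chi2_statistic = chi2$statistic,
         chi2_p = chi2$p_value,
         classifier = classifier,
         n_per_class = n_per_class,
         feature_cols = cols),
    class = "attention_clf")
}

#' @export
print.attention_clf <- function(x, ...) {
  cat(sprintf("<attention_clf> %s, %d features, LOOCV over %d trials\n",
              toupper(x$classifier), length(x$feature_cols),
              3 * x$n_per_class))
  print(x$confusion)
  cat(sprintf("per-class rates: %s %%\n",
              paste(sprintf("%.1f", x$per_class_rate), collapse = " / ")))
  cat(sprintf("average identification rate: %.1f %% (chi-squared vs 33.3%%: p = %.3g)\n",
              x$average_rate, x$chi2_p))
  invisible(x)
}

#' Tidy an attention classifier result
#'
#' One row per condition: correct count, trials per class and
#' identification rate (percent).
#'
#' @param x An `attention_clf` from [loocv()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.attention_clf <- function(x, ...) {
  tibble::tibble(
    condition = factor(rownames(x$confusion), levels = attention_levels()),
    n_correct = unname(diag(x$confusion)),
    n = x$n_per_class,
    rate = unname(x$per_class_rate)
  )
}

#' One-row summary of an attention classifier result
#'
#' @inheritParams tidy.attention_clf
#' @return A tibble with the classifier kind, average identification rate
#'   and the chi-squared-vs-chance statistic and p-value.
#' @exportS3Method generics::glance
glance.attention_clf <- function(x, ...) {
  tibble::tibble(
    classifier = x$classifier,
    n_features = length(x$feature_cols),
    average_rate = x$average_rate,
    chi2_statistic = x$chi2_statistic,
    chi2_p = x$chi2_p
  )
}

#' Confusion-matrix heatmap for an attention classifier
#'
#' @param object An `attention_clf` from [loocv()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.attention_clf <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s LOOCV confusion (average rate %.1f%%, p = %.3g)",
                      toupper(object$classifier), object$average_rate,
                      object$chi2_p),
      x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Run LOOCV across a sweep of feature settings
#'
#' @param features_by_setting Named list of feature tables (one per setting,
#'   e.g. per scale factor or per channel).
#' @param classifier `"lda"` or `"svm"`.
#' @param ... Passed to [loocv()].
#' @return A tibble: one [glance.attention_clf()] row per setting, in the
#'   given order, with a `setting` column; the fitted results are attached
#'   as the `results` list-column.
#' @export
sweep_classify <- function(features_by_setting, classifier = "svm", ...) {
  if (!length(features_by_setting)) stop("empty sweep", call. = FALSE)
  if (is.null(names(features_by_setting))) {
    names(features_by_setting) <- seq_along(features_by_setting)
  }
  results <- purrr::map(features_by_setting, loocv, classifier = classifier,
                        ...)
  out <- dplyr::bind_rows(purrr::map(results, glance))
  out <- dplyr::bind_cols(
    tibble::tibble(setting = names(features_by_setting)), out)
  out$results <- unname(results)
  out
}
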