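# Statistical comparison cascade: Bartlett equal-variance and Shapiro-Wilk
# normality screens, ANOVA / Kruskal-Wallis dispatch, pairwise comparisons
# under the Bonferroni 0.05/3 criterion, and the chi-squared test of
# identification rates against the three-class chance level.

condition_pairs <- function() {
  list(c("Rest", "AOA1"), c("Rest", "AOA2"), c("AOA1", "AOA2"))
}

as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) == 3)
  if (is.null(names(groups))) names(groups) <- attention_levels()
  lapply(groups, as.numeric)
}

#' Bartlett test of equal variances across the three conditions
#'
#' @param groups List of three numeric vectors (Rest, AOA1, AOA2).
#' @return The upper-tail p-value of Bartlett's chi-squared statistic.
#' @export
equal_variance_test <- function(groups) {
  groups <- as_group_list(groups)
  stopifnot(all(lengths(groups) >= 2))
  if (any(vapply(groups, sd, numeric(1)) == 0)) {
    stop("zero variance in at least one group", call. = FALSE)
  }
  bartlett.test(groups)$p.value
}

#' Shapiro-Wilk normality test
#'
#' @param group Numeric vector, 3 <= n <= 5000.
#' @return The p-value of the Shapiro-Wilk W statistic.
#' @export
normality_test <- function(group) {
  stopifnot(length(group) >= 3, length(group) <= 5000)
  if (sd(group) == 0) stop("constant group", call. = FALSE)
  shapiro.test(group)$p.value
}

#' Omnibus three-group comparison with parametric/non-parametric dispatch
#'
#' Runs classic one-way ANOVA when all three groups passed the normality
#' screen AND the equal-variance screen; otherwise the Kruskal-Wallis rank
#' test. The dispatch is a pure function of the two flags - the data are
#' not re-inspected.
#'
#' @inheritParams equal_variance_test
#' @param all_normal Did every group pass Shapiro-Wilk?
#' @param equal_var Did the groups pass Bartlett?
#' @return A list with `kind` (`"anova"` or `"kruskal"`) and `p`.
#' @export
omnibus_compare <- function(groups, all_normal, equal_var) {
  groups <- as_group_list(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (isTRUE(all_normal) && isTRUE(equal_var)) {
    list(kind = "anova", p = oneway.test(y ~ g, var.equal = TRUE)$p.value)
  } else {
    list(kind = "kruskal", p = kruskal.test(y, g)$p.value)
  }
}

#' Pairwise comparisons consistent with the omnibus test
#'
#' Parametric branch: pooled-SD pairwise t contrasts; non-parametric branch:
#' pairwise Wilcoxon rank-sum tests. No additional p adjustment is applied;
#' the Bonferroni correction enters through the `threshold` (0.05/3 for the
#' three condition pairs).
#'
#' @inheritParams equal_variance_test
#' @param kind `"anova"` or `"kruskal"` (from [omnibus_compare()]).
#' @param threshold Significance threshold for the `significant` flags.
#' @return A tibble with columns `comparison`, `p_value`, `significant`.
#' @export
pairwise_compare <- function(groups, kind = c("anova", "kruskal"),
                             threshold = 0.05 / 3) {
  kind <- match.arg(kind)
  groups <- as_group_list(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pmat <- if (kind == "anova") {
    pairwise.t.test(y, g, p.adjust.method = "none", pool.sd = TRUE)$p.value
  } else {
    suppressWarnings(
      pairwise.wilcox.test(y, g, p.adjust.method = "none")$p.value)
  }
  # rows of pmat are levels 2..3, columns levels 1..2; every canonical pair
  # (earlier, later) is addressed as pmat[later, earlier]
  p <- vapply(condition_pairs(), function(pair) pmat[pair[2], pair[1]],
              numeric(1))
  tibble::tibble(
    comparison = vapply(condition_pairs(), paste, character(1),
                        collapse = " vs "),
    p_value = p,
    significant = p < threshold
  )
}

#' Full per-feature statistical cascade across conditions
#'
#' For every feature column of a feature table (see [extract_features()]):
#' Bartlett equal-variance screen, Shapiro-Wilk per condition, omnibus
#' ANOVA / Kruskal-Wallis dispatch (ANOVA only when every condition's group
#' is normal and variances are equal at `alpha`), and - when the omnibus is
#' significant at `alpha` - the three pairwise comparisons flagged at the
#' Bonferroni threshold.
#'
#' @param features A feature table: `subject`, `condition`, then numeric
#'   feature columns.
#' @param alpha Screen/omnibus significance level.
#' @param threshold Pairwise Bonferroni threshold.
#' @return A tibble with one row per feature column.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 5, duration = 2)
#' feats <- extract_features(preprocess_trials(generate_dataset(cfg)), "sampen")
#' compare_conditions(feats)
compare_conditions <- function(features, alpha = 0.05,
                               threshold = 0.05 / 3) {
  stopifnot(all(c("subject", "condition") %in% names(features)))
  feat_cols <- feature_columns(features)
  rows <- purrr::map(feat_cols, function(col) {
    groups <- split(features[[col]], features$condition)[attention_levels()]
    shapiro_p <- vapply(groups, normality_test, numeric(1))
    bartlett_p <- equal_variance_test(groups)
    omni <- omnibus_compare(groups,
                            all_normal = all(shapiro_p > alpha),
                            equal_var = bartlett_p > alpha)
    base <- tibble::tibble(
      feature = col,
      bartlett_p = bartlett_p,
      shapiro_rest = shapiro_p[["Rest"]],
      shapiro_aoa1 = shapiro_p[["AOA1"]],
      shapiro_aoa2 = shapiro_p[["AOA2"]],
      omnibus_kind = omni$kind,
      omnibus_p = omni$p
    )
    if (omni$p < alpha) {
      pw <- pairwise_compare(groups, omni$kind, threshold)
      base$p_rest_aoa1 <- pw$p_value[1]
      base$p_rest_aoa2 <- pw$p_value[2]
      base$p_aoa1_aoa2 <- pw$p_value[3]
      base$sig_rest_aoa1 <- pw$significant[1]
      base$sig_rest_aoa2 <- pw$significant[2]
      base$sig_aoa1_aoa2 <- pw$significant[3]
    } else {
      base[c("p_rest_aoa1", "p_rest_aoa2", "p_aoa1_aoa2")] <- NA_real_
      base[c("sig_rest_aoa1", "sig_rest_aoa2", "sig_aoa1_aoa2")] <- NA
    }
    base
  })
  dplyr::bind_rows(rows)
}

feature_columns <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          c("subject", "fs"))
}

#' Chi-squared test of identification rates against chance
#'
#' Three-cell goodness-of-fit of the per-class correct counts against the
#' uniform expectation `n_per_class / 3` per class (random guessing among
#' three balanced classes, chance level 33.3%):
#' `chi2 = sum((O_c - E)^2 / E)` with `E = n_per_class / 3`, df = 2,
#' upper-tail p.
#'
#' @param correct_counts Integer vector of length 3: correctly identified
#'   trials for Rest, AOA1, AOA2.
#' @param n_per_class Trials per class (13 in the study design).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' chi2_vs_chance(c(9, 10, 8), 13)  # optimal CmpMSE tau = 10 setting
chi2_vs_chance <- function(correct_counts, n_per_class) {
  stopifnot(length(correct_counts) == 3, n_per_class >= 1)
  if (any(correct_counts < 0) || any(correct_counts > n_per_class)) {
    stop("counts must lie in [0, n_per_class]", call. = FALSE)
  }
  expected <- n_per_class / 3
  statistic <- sum((correct_counts - expected)^2 / expected)
  list(statistic = statistic, df = 2L,
       p_value = pchisq(statistic, df = 2, lower.tail = FALSE))
}
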