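#' Two-sided p-value from the t distribution
#'
#' Symmetric two-sided tail probability `2 P(T_df >= |t|)`; equals 1 at
#' `t = 0` and decreases monotonically in `|t|`.
#'
#' @param t Observed statistic.
#' @param df Degrees of freedom (>= 1); the 5x2 CV statistic uses 5.
#' @return A p-value in \[0, 1\].
#' @export
t_p_value <- function(t, df = 5) {
  if (df < 1) tn_stop("argument_error", "df must be >= 1")
  2 * stats::pt(-abs(t), df = df)
}

#' 5x2 cross-validation paired t-test for two classifiers
#'
#' Dietterich's comparison: five seeded random 50/50 splits of the data;
#' within each split both models are trained on half A and tested on half B
#' and vice versa. Per fold the accuracy difference between the two models
#' is recorded; per iteration the mean difference and the (two-point)
#' variance; the statistic is the first iteration's first-fold difference
#' divided by the root mean of the five iteration variances, referred to a
#' t distribution with 5 degrees of freedom (two-sided).
#'
#' If the pooled variance is zero the models are reported as
#' `"indistinguishable"` with p = 1 (the statistic is undefined) — this
#' covers the identical-model case.
#'
#' A split that leaves a half without both classes is redrawn, up to 20
#' seeded attempts.
#'
#' @param factory_1,factory_2 Model factories: functions
#'   `function(x, y, fold_seed)` returning an object whose
#'   `predict(model, x)` yields class labels.
#' @param x Feature matrix.
#' @param y Labels (two classes).
#' @param seed Integer seed driving the five splits and the fold seeds
#'   handed to the factories.
#' @param alpha Significance level for the decision (default 0.05).
#' @return A `cv_comparison`: per-iteration fold accuracies for both
#'   models (`acc_1`, `acc_2`, 5 x 2 matrices), fold differences `diffs`,
#'   iteration means and variances, `t`, `p_value` and `decision`
#'   (`"Null hypothesis rejection"` / `"No null hypothesis rejection"` /
#'   `"indistinguishable"`).
#' @export
five_by_two_cv <- function(factory_1, factory_2, x, y, seed = 1L, alpha = 0.05) {
  if (is.null(dim(x))) x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (length(y) != n) tn_stop("contract_error", "x and y lengths differ")
  acc_1 <- matrix(NA_real_, 5, 2)
  acc_2 <- matrix(NA_real_, 5, 2)
  for (it in 1:5) {
    halves <- withr::with_seed(derive_seed(seed, it), draw_halves(y, n))
    for (fold in 1:2) {
      train_idx <- if (fold == 1) halves$a else halves$b
      test_idx <- if (fold == 1) halves$b else halves$a
      fold_seed <- derive_seed(seed, 100 + it * 2 + fold)
      m1 <- factory_1(x[train_idx, , drop = FALSE], y[train_idx], fold_seed)
      m2 <- factory_2(x[train_idx, , drop = FALSE], y[train_idx], fold_seed)
      p1 <- as.character(predict(m1, x[test_idx, , drop = FALSE]))
      p2 <- as.character(predict(m2, x[test_idx, , drop = FALSE]))
      acc_1[it, fold] <- mean(p1 == y[test_idx])
      acc_2[it, fold] <- mean(p2 == y[test_idx])
    }
  }
  five_by_two_stat(acc_1, acc_2, alpha)
}

# retry up to 20 seeded attempts for halves containing both classes
draw_halves <- function(y, n) {
  n_a <- floor(n / 2)
  for (attempt in 1:20) {
    perm <- sample.int(n)
    a <- perm[seq_len(n_a)]
    b <- perm[(n_a + 1):n]
    if (length(unique(y[a])) >= 2 && length(unique(y[b])) >= 2) {
      return(list(a = a, b = b))
    }
  }
  tn_stop("data_error", "could not draw half-splits containing both classes")
}

#' 5x2 CV statistic from precomputed fold accuracies
#'
#' Computes the paired statistic directly from the 5 x 2 fold-accuracy
#' matrices (or difference matrix), bypassing training — useful for
#' testing the arithmetic and for externally evaluated models.
#'
#' @param acc_1,acc_2 5 x 2 matrices of fold accuracies for each model, or
#'   pass the 5 x 2 difference matrix as `acc_1` with `acc_2 = NULL`.
#' @param alpha Significance level.
#' @return A `cv_comparison` (see [five_by_two_cv()]).
#' @export
five_by_two_stat <- function(acc_1, acc_2 = NULL, alpha = 0.05) {
  diffs <- if (is.null(acc_2)) acc_1 else acc_1 - acc_2
  if (!all(dim(diffs) == c(5, 2))) {
    tn_stop("contract_error", "expected 5 x 2 fold accuracies")
  }
  means <- rowMeans(diffs)
  vars <- (diffs[, 1] - means)^2 + (diffs[, 2] - means)^2
  pooled <- mean(vars)
  if (pooled <= 0) {
    t <- NA_real_
    p <- 1
    decision <- "indistinguishable"
  } else {
    t <- diffs[1, 1] / sqrt(pooled)
    p <- t_p_value(t, df = 5)
    decision <- if (p < alpha) "Null hypothesis rejection" else "No null hypothesis rejection"
  }
  structure(list(acc_1 = if (is.null(acc_2)) NULL else acc_1,
                 acc_2 = acc_2, diffs = diffs, means = means,
                 variances = vars, t = t, p_value = p,
                 alpha = alpha, decision = decision),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat("5x2 CV paired t-test\n")
  if (is.na(x$t)) {
    cat("  zero pooled variance: models indistinguishable (p = 1)\n")
  } else {
    cat(sprintf("  t = %.4f (5 df), p = %.4f\n", x$t, x$p_value))
    cat(sprintf("  decision at alpha = %g: %s\n", x$alpha, x$decision))
  }
  invisible(x)
}

#' Write a 5x2 CV comparison as JSON
#'
#' Per-fold difference table, statistic, p-value and decision string.
#'
#' @param comparison A `cv_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_comparison <- function(comparison, path) {
  doc <- list(
    folds = as.data.frame(cbind(iteration = 1:5, comparison$diffs)),
    iteration_means = comparison$means,
    iteration_variances = comparison$variances,
    t = comparison$t,
    p_value = comparison$p_value,
    alpha = comparison$alpha,
    decision = comparison$decision
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
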