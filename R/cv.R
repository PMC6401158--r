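#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with midrank tie handling; used in the cross-validation
#' loops where speed matters. Agrees with dedicated ROC packages on tied and
#' untied scores.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param y binary labels (0/1).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class is empty")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal operating point
#'
#' Scans every distinct score as a candidate threshold (predict positive when
#' score >= threshold) and returns the point maximizing Youden's J
#' (sensitivity + specificity - 1). Ties on J resolve to the highest
#' threshold.
#'
#' @param scores numeric predictions.
#' @param y binary labels (0/1).
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, y) {
  y <- as.numeric(y)
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  best <- list(threshold = ths[1], sensitivity = 0, specificity = 1, j = -Inf)
  for (t in ths) {
    pos <- scores >= t
    sens <- sum(pos & y == 1) / n1
    spec <- sum(!pos & y == 0) / n0
    j <- sens + spec - 1
    if (j > best$j) best <- list(threshold = t, sensitivity = sens,
                                 specificity = spec, j = j)
  }
  best[c("threshold", "sensitivity", "specificity")]
}

# stratified k-fold assignment; both classes appear in every fold whenever
# each class has >= k members. Redraws (up to max_tries) if a fold ends up
# single-class; errors after that.
stratified_folds <- function(y, k, max_tries = 20L) {
  n <- length(y)
  for (try in seq_len(max_tries)) {
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(sample.int(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) length(unique(y[fold == f])) == 2L,
                     logical(1)))
    if (ok) return(fold)
    message(sprintf("fold draw %d produced a single-class fold; redrawing", try))
  }
  stop(sprintf("could not draw %d stratified folds with both classes after %d attempts",
               k, max_tries))
}

#' Default ridge penalty grid
#'
#' 30 log-spaced values in [1e-3, 1e3], on the standardized-feature scale.
#' @param n_lambda number of grid points.
#' @export
default_lambda_grid <- function(n_lambda = 30L) {
  exp(seq(log(1e-3), log(1e3), length.out = n_lambda))
}

#' Nested cross-validation evaluation of a ridge outcome model
#'
#' Estimates out-of-sample AUC, sensitivity and specificity for the injury or
#' recovery model with a 5x5 nested cross-validation, repeated over
#' resampled fold splits. In each iteration the data are split into
#' `outer_folds` stratified folds; for each outer training set an inner
#' `inner_folds`-fold cross-validation selects the ridge penalty maximizing
#' mean validation AUC; the model is refit on the outer training set at the
#' selected penalty and scored on the held-out outer fold. The outer-test
#' scores of one iteration are pooled into a single AUC, and sensitivity/
#' specificity at the Youden-optimal threshold on those pooled scores.
#' Means and standard deviations are taken over iterations. Standardization
#' happens inside each fit on its own training rows only, so no test-fold
#' information leaks into scaling, penalty selection, or fitting.
#'
#' The final reported model is refit on the full model population at the
#' modal selected penalty, and its dose coefficients are rescaled to the
#' [-100, 100] importance range.
#'
#' @param table a `feature_table`.
#' @param outcome `"injury"` (all patients) or `"recovery"` (injured only).
#' @param outer_folds,inner_folds fold counts, default 5 and 5.
#' @param lambda_grid ridge penalty grid, default [default_lambda_grid()].
#' @param n_iterations number of resampled nested-CV repetitions, default 50.
#' @param seed master seed; per-iteration fold seeds are derived from it.
#' @return An object of class `eval_metrics`: per-metric mean and sd,
#'   per-iteration values, the selected-penalty table, the final
#'   `ridge_logistic` model, and the normalized importance vector.
#' @export
nested_cv_evaluate <- function(table, outcome = c("injury", "recovery"),
                               outer_folds = 5L, inner_folds = 5L,
                               lambda_grid = default_lambda_grid(),
                               n_iterations = 50L, seed = 1L) {
  outcome <- match.arg(outcome)
  if (length(lambda_grid) == 0L) stop("lambda_grid must be nonempty")
  pop <- model_population(table, outcome)
  X <- pop$X; y <- pop$y
  lam_desc <- sort(lambda_grid, decreasing = TRUE)  # warm-start path, strongest first

  res <- with_local_seed(seed, {
    it_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
    auc_it <- sens_it <- spec_it <- numeric(n_iterations)
    lam_sel <- list()
    for (it in seq_len(n_iterations)) {
      set.seed(it_seeds[it])
      fold <- stratified_folds(y, outer_folds)
      scores <- numeric(length(y))
      for (f in seq_len(outer_folds)) {
        tr <- fold != f
        lam_best <- select_lambda_inner(X[tr, , drop = FALSE], y[tr],
                                        inner_folds, lam_desc)
        fit <- fit_ridge_logistic(X[tr, , drop = FALSE], y[tr], lam_best)
        scores[!tr] <- predict(fit, X[!tr, , drop = FALSE])
        lam_sel[[length(lam_sel) + 1L]] <- lam_best
      }
      auc_it[it] <- auc_score(scores, y)
      yd <- youden_threshold(scores, y)
      sens_it[it] <- yd$sensitivity
      spec_it[it] <- yd$specificity
    }
    list(auc_it = auc_it, sens_it = sens_it, spec_it = spec_it,
         lam_sel = unlist(lam_sel))
  })

  lam_tab <- sort(table(res$lam_sel), decreasing = TRUE)
  lam_modal <- as.numeric(names(lam_tab)[1])
  final <- fit_ridge_logistic(X, y, lam_modal)
  imp <- normalized_importance(final)

  structure(list(
    outcome = outcome,
    auc_mean = mean(res$auc_it), auc_sd = stats::sd(res$auc_it),
    sensitivity_mean = mean(res$sens_it), sensitivity_sd = stats::sd(res$sens_it),
    specificity_mean = mean(res$spec_it), specificity_sd = stats::sd(res$spec_it),
    n_iterations = n_iterations,
    per_iteration = data.frame(iteration = seq_len(n_iterations),
                               auc = res$auc_it, sensitivity = res$sens_it,
                               specificity = res$spec_it),
    lambda_selected = res$lam_sel, lambda_modal = lam_modal,
    final_model = final, importance = imp, seed = seed
  ), class = "eval_metrics")
}

# inner CV: mean validation AUC per lambda, warm-started along the
# descending-penalty path; ties resolve to the stronger penalty.
select_lambda_inner <- function(X, y, k, lam_desc) {
  fold <- stratified_folds(y, k)
  aucs <- matrix(NA_real_, nrow = k, ncol = length(lam_desc))
  for (f in seq_len(k)) {
    tr <- fold != f
    warm <- NULL
    for (j in seq_along(lam_desc)) {
      fit <- fit_ridge_logistic(X[tr, , drop = FALSE], y[tr], lam_desc[j],
                                init = warm)
      warm <- list(intercept = fit$intercept, beta = unname(fit$beta))
      aucs[f, j] <- auc_score(predict(fit, X[!tr, , drop = FALSE]), y[!tr])
    }
  }
  mean_auc <- colMeans(aucs)
  lam_desc[which.max(mean_auc)]  # which.max takes the first (strongest) on ties
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("%s model, nested CV over %d iterations:\n", x$outcome, x$n_iterations))
  cat(sprintf("  AUC         %.3f +/- %.4f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  sensitivity %.3f +/- %.4f\n", x$sensitivity_mean, x$sensitivity_sd))
  cat(sprintf("  specificity %.3f +/- %.4f\n", x$specificity_mean, x$specificity_sd))
  cat(sprintf("  modal lambda %.4g\n", x$lambda_modal))
  invisible(x)
}
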