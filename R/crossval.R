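#' Sample-size adjusted chance level for a two-class decoder
#'
#' The smallest accuracy that is statistically above 50% for a given trial
#' count: with \eqn{X \sim \mathrm{Binomial}(n, 0.5)}, the threshold is
#' \eqn{100\, k^*/n} percent where \eqn{k^*} is the smallest correct-trial
#' count with \eqn{P(X \ge k^*) \le \alpha} (the inverse binomial test).
#' For small samples the threshold lies well above 50% and decreases towards
#' 50% as `n_trials` grows.
#'
#' @param n_trials number of classified trials.
#' @param alpha significance level of the one-sided binomial test.
#' @return chance-level threshold in percent.
#' @export
#' @examples
#' chance_level(100)   # ~ 59%
#' chance_level(10000) # close to 50%
chance_level <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1)
  # smallest k with P(X >= k) <= alpha  <=>  k - 1 = qbinom(1 - alpha, n, 1/2)
  k <- stats::qbinom(1 - alpha, n_trials, 0.5) + 1
  100 * k / n_trials
}

#' Repeated stratified-by-chance cross-validation of the rLDA decoder
#'
#' The within-session validation scheme for single-trial anticipation
#' decoding: trials are randomly split into `n_folds` folds; each fold in
#' turn is held out for testing while the remaining folds form the
#' calibration set, which is class-balanced by [balance_classes()] before
#' fitting (the test fold stays untouched and imbalanced). The whole
#' procedure is repeated `n_repeats` times with fresh splits. Per-class
#' correct-classification rates are reported as TNR (class 1, the
#' "continue" condition) and TPR (class 2, the "takeover" condition)
#' together with the overall accuracy, each averaged over the
#' `n_repeats * n_folds` fits and expressed in percent.
#'
#' @param x a `feature_matrix`, matrix or data.frame of trials x features.
#' @param y two-class label vector; class 1 / class 2 as in [fit_rlda()].
#' @param lambda covariance shrinkage passed to [fit_rlda()].
#' @param n_repeats,n_folds repetitions and folds of the scheme.
#' @param bias_convention passed to [fit_rlda()].
#' @param alpha significance level for the reported [chance_level()].
#'
#' @return An object of class `cv_result`: list with `tnr`, `tpr`, `acc`
#'   (percent), `per_fold` (data.frame with one row per repeat x fold),
#'   `n_class1`, `n_class2`, `chance_level` and `classes`.
#' @export
cross_validate <- function(x, y, lambda = 0.9, n_repeats = 10, n_folds = 10,
                           bias_convention = "midpoint", alpha = 0.05) {
  x <- as_feature_values(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("cross_validate needs exactly two classes")
  n <- length(y)
  if (min(table(y)) < n_folds) {
    stop("need at least n_folds = ", n_folds, " trials in each class")
  }

  per_fold <- data.frame(rep = integer(0), fold = integer(0),
                         tnr = numeric(0), tpr = numeric(0), acc = numeric(0))
  for (r in seq_len(n_repeats)) {
    # random permutation, contiguous split, remainder spread one per fold
    repeat {
      perm <- sample.int(n)
      sizes <- rep(n %/% n_folds, n_folds)
      if (n %% n_folds > 0) sizes[seq_len(n %% n_folds)] <- sizes[seq_len(n %% n_folds)] + 1
      fold_of <- integer(n)
      fold_of[perm] <- rep(seq_len(n_folds), sizes)
      ok <- all(vapply(seq_len(n_folds), function(f) {
        length(unique(y[fold_of != f])) == 2
      }, logical(1)))
      if (ok) break
    }
    for (f in seq_len(n_folds)) {
      test <- fold_of == f
      bal <- balance_classes(x[!test, , drop = FALSE], y[!test])
      model <- fit_rlda(bal$x, bal$y, lambda = lambda,
                        bias_convention = bias_convention)
      pred <- predict(model, x[test, , drop = FALSE])
      truth <- y[test]
      tnr <- if (any(truth == classes[1])) {
        100 * mean(pred[truth == classes[1]] == classes[1])
      } else NA_real_
      tpr <- if (any(truth == classes[2])) {
        100 * mean(pred[truth == classes[2]] == classes[2])
      } else NA_real_
      per_fold <- rbind(per_fold, data.frame(
        rep = r, fold = f, tnr = tnr, tpr = tpr, acc = 100 * mean(pred == truth)))
    }
  }
  structure(
    list(tnr = mean(per_fold$tnr, na.rm = TRUE),
         tpr = mean(per_fold$tpr, na.rm = TRUE),
         acc = mean(per_fold$acc),
         per_fold = per_fold,
         n_class1 = sum(y == classes[1]),
         n_class2 = sum(y == classes[2]),
         chance_level = chance_level(n, alpha),
         classes = classes),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d x %d-fold CV, %d + %d trials (%s vs %s)\n",
              max(x$per_fold$rep), max(x$per_fold$fold),
              x$n_class1, x$n_class2, x$classes[1], x$classes[2]))
  cat(sprintf("  TNR = %.1f%%  TPR = %.1f%%  ACC = %.1f%%  (chance %.1f%%)\n",
              x$tnr, x$tpr, x$acc, x$chance_level))
  invisible(x)
}
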