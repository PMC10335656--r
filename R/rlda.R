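# Coerce feature_matrix / matrix / data.frame to a plain numeric matrix.
as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values
  else if (is.data.frame(x)) as.matrix(x)
  else x
}

#' Fit a shrinkage-regularized linear discriminant (rLDA)
#'
#' Two-class LDA with class-wise covariance shrinkage towards the identity,
#' \eqn{\tilde\Sigma_j = (1-\lambda)\Sigma_j + \lambda I}, the standard
#' regularization for high-dimensional single-trial EEG features where the
#' sample covariance is poorly conditioned. The weight vector solves
#' \eqn{(\tilde\Sigma_1 + \tilde\Sigma_2)\, w = \hat\mu_1 - \hat\mu_2}.
#'
#' Class 1 is the first factor level (or the alphabetically first label) of
#' `y`; the decision value \eqn{d(x) = w^\top x + b} is positive on class 1's
#' side of the boundary and a trial exactly on the boundary (\eqn{d = 0}) is
#' assigned to class 1. Class-wise covariances use the unbiased
#' \eqn{1/(N_j - 1)} normalization before shrinkage.
#'
#' @param x a `feature_matrix`, matrix or data.frame of trials x features.
#' @param y class labels, exactly two distinct values with at least two
#'   trials each.
#' @param lambda shrinkage in `[0, 1]`; the package-wide default 0.9 is a
#'   robust choice for ERP features and is used unoptimized across all
#'   decoders.
#' @param bias_convention `"midpoint"` places the boundary at the class-mean
#'   midpoint, \eqn{b = -w^\top(\hat\mu_1+\hat\mu_2)/2} (default);
#'   `"sum"` uses \eqn{b = -w^\top(\hat\mu_1+\hat\mu_2)}, a variant that
#'   doubles the offset and is provided for strict comparability only.
#'
#' @return An object of class `rlda_model`: list with `w`, `b`, `lambda`,
#'   `classes` (class 1, class 2), `bias_convention`.
#' @seealso [predict.rlda_model()], [cross_validate()]
#' @export
fit_rlda <- function(x, y, lambda = 0.9,
                     bias_convention = c("midpoint", "sum")) {
  bias_convention <- match.arg(bias_convention)
  x <- as_feature_values(x)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  classes <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(as.character(y)))
  if (length(classes) != 2) {
    stop("fit_rlda needs exactly two classes, got: ", paste(classes, collapse = ", "))
  }
  y <- as.character(y)
  i1 <- y == classes[1]
  i2 <- y == classes[2]
  if (sum(i1) < 2 || sum(i2) < 2) stop("each class needs at least 2 trials")

  mu1 <- colMeans(x[i1, , drop = FALSE])
  mu2 <- colMeans(x[i2, , drop = FALSE])
  p <- ncol(x)
  shrink <- function(idx) {
    s <- stats::cov(x[idx, , drop = FALSE])
    (1 - lambda) * s + lambda * diag(p)
  }
  pooled <- shrink(i1) + shrink(i2)
  w <- tryCatch(
    drop(solve(pooled, mu1 - mu2)),
    error = function(e) {
      stop("pooled regularized covariance is singular at lambda = ", lambda,
           "; increase the shrinkage", call. = FALSE)
    })
  b <- switch(bias_convention,
              midpoint = -sum(w * (mu1 + mu2)) / 2,
              sum      = -sum(w * (mu1 + mu2)))
  structure(
    list(w = w, b = b, lambda = lambda, classes = classes,
         bias_convention = bias_convention),
    class = "rlda_model")
}

#' Decision values and class predictions from an rLDA model
#'
#' @param object an [fit_rlda()] model.
#' @param newdata a `feature_matrix`, matrix or data.frame with the model's
#'   feature count.
#' @param type `"class"` for labels, `"decision"` for the raw decision values
#'   \eqn{w^\top x + b}.
#' @param ... unused.
#' @return character vector of class labels, or numeric decision values.
#' @export
predict.rlda_model <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- as_feature_values(newdata)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$w)) {
    stop("newdata has ", ncol(x), " features; model expects ", length(object$w))
  }
  d <- drop(x %*% object$w) + object$b
  if (type == "decision") return(d)
  # d = 0 ties resolve to class 1
  ifelse(d >= 0, object$classes[1], object$classes[2])
}

#' @export
print.rlda_model <- function(x, ...) {
  cat(sprintf("<rlda_model> %d features, lambda = %g, bias = %s\n",
              length(x$w), x$lambda, x$bias_convention))
  cat(sprintf("  class 1 (d >= 0): %s | class 2 (d < 0): %s\n",
              x$classes[1], x$classes[2]))
  invisible(x)
}

#' Balance two classes by resampling the minority class
#'
#' Random pick-and-replace balancing for imbalanced calibration data: the
#' minority class is oversampled with replacement up to the majority count,
#' majority-class trials are left unchanged, so no trial is discarded.
#'
#' @param x trials x features matrix (or `feature_matrix`).
#' @param y two-class label vector.
#' @return list with balanced `x`, `y` and the row `index` into the input.
#' @export
balance_classes <- function(x, y) {
  x <- as_feature_values(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("balance_classes needs exactly two classes")
  n <- table(factor(y, classes))
  if (any(n == 0)) stop("empty class")
  if (n[1] == n[2]) {
    idx <- seq_along(y)
  } else {
    minority <- classes[which.min(n)]
    extra <- sample(which(y == minority), max(n) - min(n), replace = TRUE)
    idx <- c(seq_along(y), extra)
  }
  list(x = x[idx, , drop = FALSE], y = y[idx], index = idx)
}
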