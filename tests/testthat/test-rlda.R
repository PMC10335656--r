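test_that("full shrinkage on the symmetric case gives the textbook boundary", {
  model <- symmetric_rlda_fit()
  expect_equal(model$w, c(1, 0), tolerance = 1e-12)
  expect_equal(model$b, 0, tolerance = 1e-12)
  expect_equal(predict(model, rbind(c(5, 0))), "a")
  expect_equal(predict(model, rbind(c(-5, 0))), "b")
  # exactly on the boundary: tie resolves to class 1
  expect_equal(predict(model, rbind(c(0, 3))), "a")
})

test_that("lambda = 0 matches an independent linear-algebra oracle", {
  set.seed(71)
  g <- make_gaussian_classes(60, 45, mu1 = c(1, 0.5, 0), mu2 = c(-0.5, 0, 0.2))
  model <- fit_rlda(g$x, g$y, lambda = 0)
  # oracle: covariances and solve computed from first principles
  center <- function(m) sweep(m, 2, colMeans(m))
  x1 <- g$x[g$y == "a", ]; x2 <- g$x[g$y == "b", ]
  s1 <- crossprod(center(x1)) / (nrow(x1) - 1)
  s2 <- crossprod(center(x2)) / (nrow(x2) - 1)
  w_oracle <- solve(s1 + s2) %*% (colMeans(x1) - colMeans(x2))
  expect_equal(model$w, drop(w_oracle), tolerance = 1e-10)
  expect_equal(model$b, -sum(model$w * (colMeans(x1) + colMeans(x2))) / 2,
               tolerance = 1e-10)
})

test_that("lambda = 0 with equal class sizes matches the MASS::lda boundary", {
  set.seed(72)
  g <- make_gaussian_classes(80, 80, mu1 = c(0.8, 0), mu2 = c(0, 0.8))
  model <- fit_rlda(g$x, g$y, lambda = 0)
  probe <- matrix(stats::rnorm(400), 200, 2)
  ref <- MASS::lda(g$x, grouping = g$y, prior = c(0.5, 0.5))
  expect_equal(predict(model, probe),
               as.character(predict(ref, probe)$class))
})

test_that("lambda = 1 predictions equal the nearest-class-mean rule", {
  set.seed(73)
  g <- make_gaussian_classes(40, 40, mu1 = c(1, 2, -1), mu2 = c(-1, 0, 1), sd = 2)
  model <- fit_rlda(g$x, g$y, lambda = 1)
  probe <- matrix(stats::rnorm(300, sd = 3), 100, 3)
  mu1 <- colMeans(g$x[g$y == "a", ]); mu2 <- colMeans(g$x[g$y == "b", ])
  d1 <- rowSums(sweep(probe, 2, mu1)^2)
  d2 <- rowSums(sweep(probe, 2, mu2)^2)
  nearest <- ifelse(d1 <= d2, "a", "b")
  expect_equal(predict(model, probe), nearest)
})

test_that("linearly separable calibration data is re-predicted perfectly", {
  set.seed(74)
  g <- make_gaussian_classes(30, 30, mu1 = c(10, 0), mu2 = c(-10, 0), sd = 1)
  model <- fit_rlda(g$x, g$y)
  expect_equal(mean(predict(model, g$x) == g$y), 1)
})

test_that("shrinkage defaults to 0.9 and inputs are validated", {
  expect_equal(formals(fit_rlda)$lambda, 0.9)
  set.seed(75)
  g <- make_gaussian_classes(10, 10, mu1 = 1, mu2 = -1)
  expect_error(fit_rlda(g$x[g$y == "a", , drop = FALSE], g$y[g$y == "a"]),
               "two classes")
  model <- fit_rlda(g$x, g$y)
  expect_error(predict(model, matrix(0, 2, 5)), "features")
  # lambda = 0 on degenerate (rank-deficient) data names the shrinkage
  xdeg <- cbind(rep(c(0, 1), 10), rep(c(0, 1), 10))
  expect_error(fit_rlda(xdeg, rep(c("a", "b"), each = 10), lambda = 0),
               "lambda = 0")
})

test_that("balancing oversamples the minority class up to the majority count", {
  x <- matrix(seq_len(742), ncol = 1)
  y <- rep(c("RR", "RH"), c(530, 212))
  set.seed(76)
  bal <- balance_classes(x, y)
  expect_equal(as.vector(table(bal$y)[c("RR", "RH")]), c(530, 530))
  # majority rows pass through unchanged, extras are copies of minority rows
  expect_identical(bal$x[seq_len(742), , drop = FALSE], x)
  expect_true(all(bal$index[-seq_len(742)] %in% which(y == "RH")))
})

test_that("already balanced input is returned unchanged", {
  x <- matrix(1:10, ncol = 1)
  y <- rep(c("a", "b"), each = 5)
  bal <- balance_classes(x, y)
  expect_identical(bal$x, x)
  expect_identical(bal$y, y)
})

test_that("balancing is reproducible under a fixed seed", {
  x <- matrix(1:30, ncol = 1)
  y <- rep(c("a", "b"), c(20, 10))
  set.seed(77); b1 <- balance_classes(x, y)
  set.seed(77); b2 <- balance_classes(x, y)
  expect_identical(b1$index, b2$index)
  expect_error(balance_classes(x[1:20, , drop = FALSE], y[1:20]), "two classes")
})
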