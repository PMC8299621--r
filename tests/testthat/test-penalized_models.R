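# Oracle tests for the penalized solvers. The implementation's objective is
# (1/(2n)) RSS + lambda * P(beta) on the standardized design; the ridge
# closed form under this scaling is (Z'Z + n*lambda*I)^{-1} Z'y on the
# centered standardized design (lambda' = n * lambda).

ridge_oracle <- function(fm, lambda) {
  X <- fm$X
  Z <- scale(X)                       # same standardization contract
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  yc <- fm$sites$y - mean(fm$sites$y)
  n <- nrow(X)
  as.numeric(solve(crossprod(Zc) + n * lambda * diag(ncol(Z)),
                   crossprod(Zc, yc)))
}

random_toy <- function(n = 50, p = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta + rnorm(n))
  toy_feature_matrix(X, y)
}

test_that("ridge matches the normal-equations closed form", {
  for (seed in 1:5) {
    fm <- random_toy(seed = seed)
    for (lam in c(1e-4, 0.05, 2)) {
      m <- fit_penalized(fm, model_config("l2", transform = "raw"), lam)
      expect_equal(unname(m$beta), ridge_oracle(fm, lam),
                   tolerance = 1e-6)
    }
  }
})

test_that("lambda = 0 reduces to ordinary least squares for both penalties", {
  fm <- random_toy(n = 100, p = 5, seed = 2)
  Z <- scale(fm$X)
  ols <- coef(lm(fm$sites$y ~ Z))
  for (pen in c("l1", "l2")) {
    m <- fit_penalized(fm, model_config(pen, transform = "raw"), 0)
    expect_equal(unname(m$beta), unname(ols[-1]), tolerance = 1e-6,
                 info = pen)
    expect_equal(m$intercept, unname(ols[1]), tolerance = 1e-6)
  }
})

test_that("one-dimensional lasso equals the soft-threshold formula", {
  set.seed(3)
  n <- 80
  x <- rnorm(n)
  y <- 0.7 * x + rnorm(n, sd = 0.4)
  fm <- toy_feature_matrix(cbind(f1 = x), y)
  z <- as.numeric(scale(x))
  for (lam in c(0, 0.05, 0.2, 1)) {
    rho <- sum(z * (y - mean(y))) / n
    expected <- sign(rho) * max(abs(rho) - lam, 0) / (sum(z^2) / n)
    m <- fit_penalized(fm, model_config("l1", transform = "raw"), lam)
    expect_equal(unname(m$beta), expected, tolerance = 1e-6,
                 info = paste("lambda", lam))
  }
})

test_that("large lambda drives every lasso coefficient to zero", {
  fm <- random_toy(n = 60, p = 8, seed = 4)
  m <- fit_penalized(fm, model_config("l1", transform = "raw"), 1e3)
  expect_true(all(m$beta == 0))
  expect_equal(m$intercept, mean(fm$sites$y))
})

test_that("non-finite inputs are rejected", {
  fm <- random_toy(seed = 5)
  fm$X[1, 1] <- NaN
  expect_error(fit_penalized(fm, model_config("l1", transform = "raw"),
                             0.1), "non-finite")
})

test_that("cross-validation is deterministic, gene-grouped, with a monotone L1 path", {
  set.seed(6)
  n <- 240
  genes <- rep(sprintf("g%02d", 1:24), each = 10)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.numeric(X[, 1:3] %*% c(1, -0.5, 0.5) + rnorm(n, sd = 0.8))
  fm <- toy_feature_matrix(X, y, gene = genes)
  cfg <- model_config("l1", transform = "raw", seed = 7,
                      lambda_grid = 10^seq(-4, 0.5, by = 0.5))
  cv1 <- cv_lambda(fm, cfg)
  cv2 <- cv_lambda(fm, cfg)
  expect_equal(cv1, cv2)
  # all sites of a gene share a fold
  expect_length(attr(cv1, "fold_of_gene"), 24)
  # nonzero count non-increasing in lambda on this fixture
  expect_true(all(diff(cv1$nonzero) <= 0))
  # largest lambda kills the weak-signal fit entirely
  expect_equal(cv1$nonzero[nrow(cv1)], 0)
})

test_that("select_lambda implements the sparsity-leaning rule", {
  cv <- data.frame(lambda = c(1e-3, 1e-2, 1e-1),
                   mse = c(1.00, 1.02, 1.50), nonzero = c(5, 3, 0))
  expect_equal(select_lambda(cv, 0.05), 1e-2)
  expect_equal(select_lambda(cv, 0), 1e-3)
  # ties at the minimum: largest qualifying lambda wins
  cv2 <- data.frame(lambda = c(1e-3, 1e-2), mse = c(1, 1),
                    nonzero = c(2, 2))
  expect_equal(select_lambda(cv2, 0), 1e-2)
  expect_equal(select_lambda(cv, 0.05, override = 0.01), 0.01)
})

test_that("evaluation handles perfect and constant predictions", {
  fm <- random_toy(n = 100, p = 3, seed = 8)
  fm$sites$split <- rep(c("train", "test"), each = 50)
  # y is an exact linear function -> near-perfect test prediction
  fm$sites$y <- as.numeric(fm$X %*% c(1, 2, -1))
  m <- fit_penalized(fm, model_config("l2", transform = "raw"), 1e-10)
  ev <- predict_and_evaluate(m, fm, "test")
  expect_equal(ev$r, 1, tolerance = 1e-6)
  expect_lt(ev$mse, 1e-8)
  expect_equal(ev$n, 50)

  # all-zero model predicts a constant: r reported as 0 with a flag
  m0 <- fit_penalized(fm, model_config("l1", transform = "raw"), 1e3)
  ev0 <- predict_and_evaluate(m0, fm, "test")
  expect_equal(ev0$r, 0)
  expect_true(ev0$constant_prediction)
})

test_that("predictions are invariant to affine rescaling of a column", {
  fm <- random_toy(n = 120, p = 4, seed = 9)
  m1 <- fit_penalized(fm, model_config("l2", transform = "raw"), 0.05)
  fm2 <- fm
  fm2$X[, 2] <- 10 * fm2$X[, 2] + 3
  m2 <- fit_penalized(fm2, model_config("l2", transform = "raw"), 0.05)
  expect_equal(predict(m1, fm), predict(m2, fm2), tolerance = 1e-8)
})

test_that("predict errors on mismatched feature columns", {
  fm <- random_toy(seed = 10)
  m <- fit_penalized(fm, model_config("l2", transform = "raw"), 0.1)
  fm2 <- subset_features(fm, 1:3)
  expect_error(predict(m, fm2), "do not match")
})

test_that("coefficient report groups by sign with proportions of the group total", {
  fm <- random_toy(n = 40, p = 4, seed = 11)
  m <- fit_penalized(fm, model_config("l2", transform = "raw"), 0.01)
  # craft a model with known coefficients: 0.78 around-site, 0.53 whole-RNA
  m$beta[] <- c(0.78, 0.53, -0.2, 0)
  specs <- fm$specs
  specs$scope <- c("around_site", "whole_rna", "around_site", "whole_rna")
  rep <- coefficient_report(m, specs)
  pos <- rep$positive$by_scope
  expect_equal(pos$sum[pos$level == "around_site"], 0.78)
  expect_equal(pos$proportion[pos$level == "around_site"], 0.78 / 1.31,
               tolerance = 1e-12)            # 59.5% of the positive group
  expect_equal(sum(pos$proportion), 1)
  expect_equal(rep$negative$by_scope$proportion, 1)  # single negative

  m$beta[] <- 0
  rep0 <- coefficient_report(m, specs)
  expect_equal(rep0$positive$total, 0)
  expect_equal(nrow(rep0$positive$top), 0)

  m$beta[] <- c(0.4, 0, 0, 0)
  rep1 <- coefficient_report(m, specs)
  expect_equal(rep1$positive$by_category$proportion, 1)
})
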