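test_that("autoscaling centres, scales and inverts exactly", {
  expect_equal(autoscale(matrix(c(0, 2), 2, 1))$X[, 1],
               c(-0.7071068, 0.7071068), tolerance = 1e-6)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("D", 1:4)))
  y <- rnorm(10)
  sc <- autoscale(X, y)
  expect_equal(colMeans(sc$X), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(sc$X, 2, sd), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(invert_scaling(sc$params, sc$X), X, ignore_attr = TRUE,
               tolerance = 1e-12)
  Xc <- X; Xc[, 2] <- 7
  expect_error(autoscale(Xc), "D2")
})

test_that("SIMPLS matches least squares at full rank", {
  set.seed(1)
  # univariate: identical to simple regression
  x <- matrix(rnorm(12), ncol = 1)
  y <- 2 + 3 * x[, 1] + rnorm(12, 0, 0.2)
  m1 <- simpls_fit(x, y, 1)
  ols1 <- lm(y ~ x)
  expect_equal(unname(m1$fitted), unname(fitted(ols1)), tolerance = 1e-10)

  # multivariate at n_lv = rank
  X <- matrix(rnorm(75), 15, 5)
  y2 <- rnorm(15)
  m <- simpls_fit(X, y2, 5)
  expect_equal(unname(m$fitted), unname(fitted(lm(y2 ~ X))), tolerance = 1e-8)
  expect_error(simpls_fit(X, y2, 6), "rank")
})

test_that("SIMPLS scores are orthogonal and explained variance behaves", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  y <- drop(X %*% c(1, -1, 0.5, 0, 0)) + rnorm(20, 0, 0.3)
  m <- simpls_fit(X, y, 4)
  G <- crossprod(m$scores)
  expect_equal(G, diag(4), ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(m$explained_x >= 0 & m$explained_x <= 100))
  expect_true(all(m$explained_y >= 0 & m$explained_y <= 100))
  expect_lte(sum(m$explained_x), 100 + 1e-8)
  expect_true(all(diff(cumsum(m$explained_y)) >= -1e-10))
})

test_that("a response orthogonal to X gives near-zero coefficients", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  v <- rnorm(20)
  y <- resid(lm(v ~ X)) # orthogonal to the X columns by construction
  m <- simpls_fit(X, y, 3)
  expect_lt(max(abs(m$coef_scaled)), 1e-10)
})

test_that("prediction applies stored scaling and is row-equivariant", {
  set.seed(4)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  m <- simpls_fit(X, y, 2)
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-12)
  expect_length(predict(m, X[1, , drop = FALSE]), 1)
  perm <- c(3, 1, 2, 5, 4)
  expect_equal(predict(m, X[perm, ]), predict(m, X)[perm])
  expect_equal(predict(m, X, scale = "minutes"), exp(predict(m, X)))
  expect_error(predict(m, X[, 1:3]), "columns")
})

test_that("LOO-CV matches a per-fold OLS oracle at full rank and never leaks", {
  set.seed(5)
  X <- matrix(rnorm(48), 12, 4)
  y <- drop(X %*% c(1, -0.5, 0, 0.3)) + rnorm(12, 0, 0.1)
  cv <- loo_cv_curve(X, y)
  oracle <- loo_ols_oracle(X, y)
  expect_equal(unname(cv$predictions[, 4]), unname(oracle), tolerance = 1e-8)
  expect_equal(cv$rmsecv[4], sqrt(mean((oracle - y)^2)), tolerance = 1e-8)
  expect_equal(cv$rmsecv_minutes[4], sqrt(mean((exp(oracle) - exp(y))^2)),
               tolerance = 1e-6)

  # leakage: perturbing a held-out response must not change its prediction
  y2 <- y; y2[3] <- y2[3] + 10
  cv2 <- loo_cv_curve(X, y2)
  expect_equal(cv2$predictions[3, ], cv$predictions[3, ], tolerance = 1e-10)

  # minimal size: m = 3 runs with a single candidate
  cv3 <- loo_cv_curve(X[1:3, 1:2], y[1:3])
  expect_equal(cv3$n_lv, 1)
})

test_that("noiseless single-descriptor signal is recovered exactly by 1 LV", {
  set.seed(6)
  x <- matrix(rnorm(20), 20, 1)
  y <- 1 + 2 * x[, 1]
  cv <- loo_cv_curve(x, y)
  expect_lt(cv$rmsecv[1], 1e-8)
})

test_that("latent-variable selection policies", {
  expect_equal(select_n_lvs(c(5, 5, 5)), 1) # flat curve
  expect_equal(select_n_lvs(c(10, 3, 2.9, 2.89), tol = 0.02), 2)
  expect_equal(select_n_lvs(c(5, 2, 3), policy = "min"), 2)
  expect_equal(select_n_lvs(c(3, 2, 2), policy = "min"), 2) # tie -> smaller
  expect_error(select_n_lvs(numeric(0)), "empty")
})

test_that("rmse and the train/validation average", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(3, -4), c(0, 0)), sqrt(12.5))
  expect_equal(average_rmse(2, 4), 3)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})
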