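test_that("ln transform and its inverse", {
  expect_equal(ln_transform(1), 0)
  expect_equal(ln_transform(exp(1)), 1)
  expect_error(ln_transform(0), "> 0")
  expect_error(ln_transform(-2), "> 0")
  t_R <- c(0.5, 3.7, 28)
  expect_equal(inv_ln_transform(ln_transform(t_R)), t_R, tolerance = 1e-12)
})

test_that("Pearson correlation matches the closed-form t-test oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  out <- pearson_with_test(x, y)
  # direct formula oracle
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(abs(t_hand), df = 2, lower.tail = FALSE)
  expect_equal(out$R, r_hand, tolerance = 1e-10)
  expect_equal(out$p_value, p_hand, tolerance = 1e-10)
  expect_equal(out$n, 4)

  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    got <- pearson_with_test(a, b)
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    tt <- r * sqrt(18 / (1 - r^2))
    expect_equal(got$R, r, tolerance = 1e-10)
    expect_equal(got$p_value, 2 * pt(abs(tt), 18, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  expect_equal(pearson_with_test(1:5, 1:5)$R, 1)
  expect_equal(pearson_with_test(1:5, -(1:5))$R, -1)
  expect_error(pearson_with_test(rep(1, 5), 1:5), "variance")
  expect_error(pearson_with_test(1:4, 1:5), "equal length")
})

test_that("cross-column retention correlations are computed pairwise on ln scale", {
  set.seed(21)
  base <- runif(25, 2, 30)
  ret <- rbind(
    data.frame(analyte_id = paste0("a", 1:25), column_name = "C18",
               t_R_min = base),
    data.frame(analyte_id = paste0("a", 1:25), column_name = "F5",
               t_R_min = base * exp(rnorm(25, 0, 0.15))),
    data.frame(analyte_id = paste0("a", 1:25), column_name = "IAM",
               t_R_min = base * exp(rnorm(25, 0, 0.6))))
  corr <- retention_correlations(ret)
  expect_equal(nrow(corr), 3)
  pair <- corr[corr$column_1 == "C18" & corr$column_2 == "F5", ]
  lnb <- log(base)
  lnf <- log(ret$t_R_min[ret$column_name == "F5"])
  expect_equal(pair$R, cor(lnb, lnf), tolerance = 1e-12)
  # tightly coupled columns correlate more strongly than loosely coupled ones
  loose <- corr[corr$column_1 == "C18" & corr$column_2 == "IAM", ]
  expect_gt(pair$R, loose$R)
})

test_that("Kennard-Stone picks the extreme pair first and is deterministic", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  sp <- kennard_stone_split(X, 2 / 3)
  expect_equal(sp$train, c(1, 3)) # brute force: (0, 10) is the farthest pair
  expect_equal(sp$validation, 2)

  set.seed(31)
  Xr <- matrix(rnorm(60), 20, 3)
  s1 <- kennard_stone_split(Xr, 0.7)
  s2 <- kennard_stone_split(Xr, 0.7)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 14) # round(0.7 * 20)
  expect_equal(sort(c(s1$train, s1$validation)), 1:20)

  X30 <- matrix(rnorm(90), 30, 3)
  expect_equal(length(kennard_stone_split(X30, 0.7)$train), 21)

  # duplicated rows: ties broken to the lowest row index
  Xd <- matrix(c(0, 0, 5, 5, 9), ncol = 1)
  sd_ <- kennard_stone_split(Xd, 0.6)
  expect_true(1 %in% sd_$train)
  expect_false(2 %in% sd_$train[1:2])

  expect_error(kennard_stone_split(Xr, 1.2), "train_fraction")
  expect_error(kennard_stone_split(Xr[1:2, , drop = FALSE], 0.5), "at least 3")
})

test_that("qsrr_dataset validates and drops incomplete rows", {
  X <- matrix(rnorm(20), 5, 4)
  y <- rnorm(5)
  ds <- qsrr_dataset(X, y, analyte_ids = letters[1:5])
  expect_s3_class(ds, "qsrr_dataset")
  expect_equal(nrow(ds$X), 5)
  X[2, 3] <- NA
  expect_message(ds2 <- qsrr_dataset(X, y, analyte_ids = letters[1:5]),
                 "dropping")
  expect_equal(ds2$analyte_ids, c("a", "c", "d", "e"))
  expect_error(qsrr_dataset(X, y[1:4]), "equal")
  expect_error(qsrr_dataset(X, y, split = rep("train", 4)), "one label")
})
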