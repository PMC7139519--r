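test_that("ANOVA tables are internally consistent by construction", {
  tab <- anova_table(19.36, 18.81, 20, 8)
  expect_equal(tab$table$MS[2], 18.81 / 8) # 2.35 at printed precision
  expect_equal(tab$table$SS[3], 0.55, tolerance = 1e-12)
  expect_equal(tab$table$df[3], 12)
  expect_equal(tab$F, (18.81 / 8) / (0.55 / 12))
  expect_silent(validate_anova_table(tab))
  expect_error(anova_table(10, 12, 20, 8), "exceeds")
  expect_error(anova_table(10, 5, 8, 8), "positive")
})

test_that("cv_anova partitions variation around the mean", {
  set.seed(40)
  y <- rnorm(21, 2, 1)
  # perfect cross-validated predictions: all variation explained
  perfect <- cv_anova(y, y, n_lv = 3)
  expect_equal(perfect$table$SS[3], 0)
  expect_true(is.infinite(perfect$F))
  expect_equal(perfect$p_value, 0)
  expect_equal(perfect$table$df, c(20, 6, 14))

  # anti-predictions (reflection about the mean) are worse than the mean:
  # SS_Fit is floored at 0 with a warning
  expect_warning(null_tab <- cv_anova(y, 2 * mean(y) - y, n_lv = 3), "floored")
  expect_equal(null_tab$table$SS[2], 0)
  expect_equal(null_tab$F, 0)

  # df policies
  byp <- cv_anova(y, y + rnorm(21, 0, 0.1), df_policy = "n_descriptors",
                  n_descriptors = 4)
  expect_equal(byp$table$df[2], 4)
  expect_error(cv_anova(y, y, n_lv = 10), "smaller")
})

test_that("leverages match the explicit hat-matrix computation", {
  X <- matrix(c(1, 0, -1, 0.5, 2, -0.5), nrow = 3) # 3 x 2 toy
  h <- leverages(X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(h, diag(H), tolerance = 1e-12, ignore_attr = TRUE)
  # trace identity on any full-column-rank matrix
  set.seed(41)
  Xa <- scale(matrix(rnorm(60), 15, 4))
  expect_equal(sum(leverages(Xa)), 4, tolerance = 1e-8)
  # a query at the centroid of autoscaled space has zero leverage
  expect_equal(unname(leverages(Xa, matrix(0, 1, 4))), 0)
  expect_error(leverages(Xa, matrix(0, 1, 3)), "mismatch")
  # rank-deficient training matrix: pseudo-inverse with a warning
  Xd <- cbind(Xa[, 1], Xa[, 1])
  expect_warning(leverages(Xd), "pseudo-inverse")
})

test_that("critical leverage follows 3(n+1)/m and its monotonicities", {
  expect_equal(round(critical_leverage(4, 21), 3), 0.714)
  expect_equal(round(critical_leverage(6, 21), 3), 1.000)
  expect_equal(round(critical_leverage(7, 19), 3), 1.263)
  expect_true(critical_leverage(4, 30) < critical_leverage(4, 21))
  expect_true(critical_leverage(7, 21) > critical_leverage(4, 21))
  expect_error(critical_leverage(0, 10), ">= 1")
})

test_that("external validation reports per-set and averaged RMSE", {
  d <- toy_dataset(m = 20, p = 5, seed = 42)
  cm <- fit_consensus(d$X[1:14, ], d$y[1:14], c(1, 1, 0, 0, 0))
  same <- external_validate(cm, d$X[1:14, ], d$y[1:14])
  expect_equal(same$rmse_validation, same$rmse_train)
  out <- external_validate(cm, d$X[15:20, ], d$y[15:20])
  expect_equal(out$rmse_average,
               (out$rmse_train + out$rmse_validation) / 2)
  pred_min <- predict(cm, d$X[15:20, ], scale = "minutes")
  expect_equal(out$rmse_validation_minutes,
               rmse(pred_min, exp(d$y[15:20])))
  expect_error(external_validate(cm, d$X[0, ], numeric(0)), "empty")
})

test_that("applicability domain flags extremes and covers all analytes", {
  spec <- synthetic_spec(m_analytes = 40, preset = "kc18", seed = 43,
                         noise_sd = 0.15)
  sim <- generate_dataset(spec)
  X <- sim$dataset$X; y <- sim$dataset$y
  mask <- as.integer(descriptor_names() %in% sim$truth$support)
  cm <- fit_consensus(X[1:28, ], y[1:28], mask)
  ad <- applicability_domain(cm, X[29:40, ], y[29:40])
  expect_equal(nrow(ad$table), 40)
  expect_setequal(unique(ad$table$set), c("train", "validation"))
  # matched-noise in-hull data: the large majority sits inside the domain
  expect_gte(mean(ad$table$in_domain), 0.9)
  # training analytes' leverages obey the trace identity
  htr <- ad$table$leverage[ad$table$set == "train"]
  expect_equal(sum(htr), length(cm$selected), tolerance = 1e-8)

  # a constructed point far outside the training cloud is flagged
  far <- X[29, , drop = FALSE]
  far[, sim$truth$support] <- far[, sim$truth$support] +
    10 * apply(X[1:28, sim$truth$support], 2, sd)
  ad_far <- applicability_domain(cm, far, y[29])
  row <- ad_far$table[ad_far$table$set == "validation", ]
  expect_true(row$high_leverage)
  expect_gt(row$leverage, ad_far$h_star)
})
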