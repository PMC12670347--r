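# logistic allocation DGP with one binary category indicator
alloc_sim <- function(n, log_or, seed, p_cat = 0.5, b0 = -0.3) {
  withr::with_seed(seed, {
    z <- rbinom(n, 1, p_cat)
    A <- rbinom(n, 1, plogis(b0 + log_or * z))
    list(X = cbind(cat = z), A = A, z = z)
  })
}

test_that("boosted propensity separates only when there is signal", {
  withr::with_seed(3, {
    X <- cbind(x1 = rnorm(5000), x2 = rnorm(5000))
    A_null <- rbinom(5000, 1, 0.45)
    A_det <- as.integer(X[, "x1"] > 0)
  })
  tr <- 1:4000; ho <- 4001:5000
  auroc <- function(score, lab) {
    r <- rank(score)
    (sum(r[lab == 1]) - sum(lab == 1) * (sum(lab == 1) + 1) / 2) /
      (sum(lab == 1) * sum(lab == 0))
  }
  m0 <- fit_boosted_propensity(X[tr, ], A_null[tr], seed = 1)
  s0 <- predict(m0$booster, xgboost::xgb.DMatrix(X[ho, ]))
  expect_lt(abs(auroc(s0, A_null[ho]) - 0.5), 0.05)

  m1 <- fit_boosted_propensity(X[tr, ], A_det[tr], seed = 1)
  s1 <- predict(m1$booster, xgboost::xgb.DMatrix(X[ho, ]))
  expect_gt(auroc(s1, A_det[ho]), 0.95)

  expect_error(fit_boosted_propensity(X, rep(1L, 5000)), "degenerate")
})

test_that("model fits and resampled ORs are reproducible under a fixed seed", {
  d <- alloc_sim(1200, log(1.5), seed = 5)
  m1 <- fit_boosted_propensity(d$X, d$A, seed = 9)
  m2 <- fit_boosted_propensity(d$X, d$A, seed = 9)
  expect_identical(predict(m1$booster, xgboost::xgb.DMatrix(d$X)),
                   predict(m2$booster, xgboost::xgb.DMatrix(d$X)))
  r1 <- resampled_or(d$X, d$A, "cat", n_iter = 5, seed = 11, nrounds = 30)
  r2 <- resampled_or(d$X, d$A, "cat", n_iter = 5, seed = 11, nrounds = 30)
  expect_identical(r1[c("or_point", "ci95")], r2[c("or_point", "ci95")])
})

test_that("an indicator the trees never use has odds ratio exactly one", {
  d <- alloc_sim(800, log(2), seed = 7)
  # a second indicator, constant in training, so no tree can split on it
  Xtr <- cbind(d$X, unused = 0)
  m <- fit_boosted_propensity(Xtr, d$A, seed = 2)
  Xev <- cbind(d$X, unused = rbinom(nrow(d$X), 1, 0.5))
  expect_equal(shap_or(m, Xev, "unused"), 1)
  # empty category on the evaluation side is undefined, reported as NA
  expect_true(is.na(shap_or(m, cbind(cat = rep(1, 10), unused = 0), "cat")))
})

test_that("shapley odds ratios track the logistic-regression oracle", {
  d <- alloc_sim(10000, log(2.0), seed = 13)
  m <- fit_boosted_propensity(d$X, d$A, seed = 3)
  or_shap <- shap_or(m, d$X, "cat")
  or_logit <- exp(coef(glm(d$A ~ d$z, family = binomial()))[["d$z"]])
  expect_lt(abs(log(or_shap) - log(or_logit)), log(1.15))

  # doubling the log-odds gap roughly doubles the attribution gap
  d2 <- alloc_sim(10000, 2 * log(2.0), seed = 13)
  m2 <- fit_boosted_propensity(d2$X, d2$A, seed = 3)
  ratio <- log(shap_or(m2, d2$X, "cat")) / log(or_shap)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("recoding the indicator inverts the odds ratio", {
  d <- alloc_sim(4000, log(1.8), seed = 17)
  m <- fit_boosted_propensity(d$X, d$A, seed = 4)
  or_fwd <- shap_or(m, d$X, "cat")
  Xr <- cbind(cat = 1 - d$z)
  mr <- fit_boosted_propensity(Xr, d$A, seed = 4)
  or_rev <- shap_or(mr, Xr, "cat")
  expect_equal(log(or_fwd), -log(or_rev), tolerance = 1e-3)
})

test_that("one iteration with one fold degenerates to a single evaluation", {
  d <- alloc_sim(1500, log(1.6), seed = 19)
  r <- resampled_or(d$X, d$A, "cat", n_iter = 1, k = 1, seed = 23,
                    nrounds = 50)
  expect_equal(r$n_iterations, 1L)
  expect_true(r$or_point > 0)
  expect_true(r$ci95[1] <= r$or_point && r$or_point <= r$ci95[2])
})

test_that("cohort-level disparity table covers every treatment and category", {
  co <- quick_cohort(1500, seed = 29)
  tab <- disparity_ors(co, n_iter = 3, nrounds = 20, seed = 31)
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(tab$or > 0))
  expect_true(all(tab$ci_lo <= tab$or & tab$or <= tab$ci_hi))
})
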