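sim_xy <- function(n, seed, binary = TRUE) {
  withr::with_seed(seed, {
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
    lp <- -0.3 + 0.9 * X[, "x1"] - 0.6 * X[, "x2"] + 0.5 * X[, "x3"]
    y <- if (binary) rbinom(n, 1, plogis(lp)) else lp + rnorm(n)
    list(X = X, y = y)
  })
}

test_that("a singleton constant-mean library predicts the sample mean with weight one", {
  d <- sim_xy(300, 1)
  fit <- fit_stack(d$X, d$y, "binomial", seed = 2, learners = "mean")
  expect_equal(unname(fit$weights), 1)
  expect_equal(unique(predict(fit, d$X)), mean(d$y), tolerance = 1e-12)
})

test_that("the GLM learner dominates under a well-specified logistic model", {
  d <- sim_xy(3000, 7)
  fit <- fit_stack(d$X, d$y, "binomial", seed = 3,
                   learners = c("mean", "glm", "ranger"))
  w <- fit$weights
  expect_gte(w[["glm"]], w[["mean"]])
  expect_gte(w[["glm"]], w[["ranger"]])
})

test_that("duplicating a learner leaves ensemble predictions unchanged", {
  d <- sim_xy(400, 5)
  f1 <- fit_stack(d$X, d$y, "binomial", seed = 9, learners = "mean")
  f2 <- fit_stack(d$X, d$y, "binomial", seed = 9,
                  learners = c("mean", "mean"))
  expect_equal(sum(f2$weights), 1, tolerance = 1e-10)
  expect_equal(predict(f2, d$X), predict(f1, d$X), tolerance = 1e-8)
})

test_that("ensemble CV risk never exceeds the best single learner's", {
  for (s in 1:3) {
    d <- sim_xy(500, s)
    fb <- fit_stack(d$X, d$y, "binomial", seed = s,
                    learners = c("mean", "glm", "glmnet"))
    expect_lte(fb$ensemble_cv_risk, min(fb$cv_risks, na.rm = TRUE) + 1e-8)
    expect_equal(sum(fb$weights), 1, tolerance = 1e-10)
    expect_true(all(fb$weights >= 0))

    dg <- sim_xy(500, s + 10, binary = FALSE)
    fg <- fit_stack(dg$X, dg$y, "gaussian", seed = s,
                    learners = c("mean", "glm", "glmnet"))
    expect_lte(fg$ensemble_cv_risk, min(fg$cv_risks, na.rm = TRUE) + 1e-8)
    expect_equal(sum(fg$weights), 1, tolerance = 1e-10)
  }
})

test_that("folds are outcome-stratified and balanced within one", {
  d <- sim_xy(513, 21)
  fit <- fit_stack(d$X, d$y, "binomial", seed = 4, learners = "mean", k = 5)
  sizes <- table(fit$fold_map)
  expect_lte(max(sizes) - min(sizes), 1)
  ones <- table(fit$fold_map[d$y == 1])
  expect_lte(max(ones) - min(ones), 1)
})

test_that("row permutation with a matched fold map leaves weights unchanged", {
  d <- sim_xy(600, 8)
  folds <- rep_len(1:5, 600)
  f1 <- fit_stack(d$X, d$y, "binomial", seed = 1,
                  learners = c("mean", "glm"), folds = folds)
  perm <- withr::with_seed(99, sample.int(600))
  f2 <- fit_stack(d$X[perm, ], d$y[perm], "binomial", seed = 1,
                  learners = c("mean", "glm"), folds = folds[perm])
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
})

test_that("a learner that cannot fit is dropped with weight zero, not fatal", {
  # a non-finite covariate breaks the GLM; the constant-mean learner survives
  withr::with_seed(2, {
    X <- cbind(x1 = rnorm(60), x2 = rnorm(60))
    X[5, "x2"] <- Inf
    y <- rbinom(60, 1, 0.5)
  })
  expect_warning(
    fit <- fit_stack(X, y, "binomial", seed = 3, k = 3,
                     learners = c("mean", "glm")),
    "dropped"
  )
  expect_equal(unname(fit$weights[["glm"]]), 0)
  expect_equal(unname(fit$weights[["mean"]]), 1)
  expect_length(predict(fit, X), 60)
})

test_that("predictions are convex combinations, clipped for binomial loss", {
  d <- sim_xy(400, 12)
  fit <- fit_stack(d$X, d$y, "binomial", seed = 6,
                   learners = c("mean", "glm"))
  p <- predict(fit, d$X)
  expect_true(all(p > 0 & p < 1))
  # force a unit-vector weight: ensemble equals that learner exactly
  fit$weights[] <- c(0, 1)
  p_glm <- predict(fit, d$X)
  glm_only <- fit_stack(d$X, d$y, "binomial", seed = 6, learners = "glm")
  expect_equal(p_glm, predict(glm_only, d$X), tolerance = 1e-8)
  expect_error(predict(fit, d$X[, 1:2]), "x3")
})
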