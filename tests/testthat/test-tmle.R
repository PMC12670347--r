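test_that("bounded-outcome scaling round-trips and reports in days", {
  y <- c(0, 7, 28)
  s <- scale_bounded(y)
  expect_equal(as.numeric(s), c(0, 0.25, 1))
  expect_equal(unscale_effect(0.1), 2.8)
  expect_equal(unscale_effect(as.numeric(s)) , y, tolerance = 1e-12)
  expect_error(scale_bounded(c(1, 29)), "2")
})

test_that("with known propensity and saturated outcome model TMLE equals the g-formula", {
  cfg <- binary_confounder_cfg(n = 2000, seed = 41, g0 = 0, gz = 0)
  rec <- generate_cohort(cfg)
  A <- assign_treatment(rec, "trt")
  Y <- derive_outcomes(rec)$Y_mortality
  z <- rec$z
  # saturated initial fit: empirical cell means over the 2x2 (A, z) table
  cell <- function(a, zz) mean(Y[A == a & z == zz])
  Q0 <- ifelse(z == 1, cell(0, 1), cell(0, 0))
  Q1 <- ifelse(z == 1, cell(1, 1), cell(1, 0))
  fit <- estimate_ate(cbind(z = z), A, Y, g_hat = 0.5,
                      Q_init = cbind(Q0, Q1))
  # exhaustive enumeration over the empirical 2x2x2 table
  gform <- mean(z) * (cell(1, 1) - cell(0, 1)) +
    (1 - mean(z)) * (cell(1, 0) - cell(0, 0))
  expect_lt(abs(fit$estimate - gform), 1e-6)
  expect_lt(abs(fit$score_residual), 1e-6)
})

test_that("a null treatment effect is recovered within sampling error", {
  cfg <- binary_confounder_cfg(n = 20000, seed = 43, bA = 0)
  rec <- generate_cohort(cfg)
  A <- assign_treatment(rec, "trt")
  Y <- derive_outcomes(rec)$Y_mortality
  fit <- estimate_ate(cbind(z = rec$z), A, Y, seed = 2,
                      learners = c("mean", "glm"))
  expect_lt(abs(fit$estimate), 3 * fit$se)

  cm <- counterfactual_mean(cbind(z = rec$z), A, Y, a_target = 0, seed = 3,
                            learners = c("mean", "glm"))
  expect_true(cm$estimate >= 0 && cm$estimate <= 1)
  expect_lt(abs(cm$estimate - mean(Y)), 3 * cm$se)
})

test_that("the counterfactual untreated mean matches the oracle baseline", {
  # single-treatment design so E[Y(0)] is exactly the oracle's baseline mean
  oc <- default_outcome_coefficients()
  oc$treatment <- oc$treatment["imv"]
  oc$treatment_severity <- oc$treatment_severity["imv"]
  cfg <- small_cfg(20000, seed = 47,
                   propensity_coefficients = default_propensity_coefficients()["imv"],
                   outcome_coefficients = oc)
  tr <- compute_truth(cfg, n_mc = 1e5, seed = 5)
  base_truth <- tr$baseline$truth[tr$baseline$stratum == "overall"]
  co <- quick_cohort(cfg = cfg)
  X <- cohort_design(co)
  cm <- counterfactual_mean(X, co$A_imv, co$Y_mortality, a_target = 0,
                            seed = 7, learners = c("mean", "glm"))
  expect_lt(abs(cm$estimate - base_truth), 3 * cm$se)
  expect_true(cm$estimate > 0 && cm$estimate < 1)
})

test_that("the score equation is solved after fluctuation on every fit", {
  for (s in 1:4) {
    cfg <- small_cfg(1500, seed = 50 + s)
    co <- quick_cohort(cfg = cfg)
    X <- cohort_design(co)
    fit <- estimate_ate(X, co$A_imv, co$Y_mortality, seed = s,
                        learners = c("mean", "glm"))
    expect_lt(abs(fit$score_residual), 1e-6)
    yh <- scale_bounded(co$Y_hfd, 0, 28)
    fh <- estimate_ate(X, co$A_vasopressor, as.numeric(yh), "gaussian",
                       seed = s, learners = c("mean", "glm"))
    expect_lt(abs(fh$score_residual), 1e-6)
  }
})

test_that("double robustness: misspecified outcome model, correct propensity", {
  b0 <- -1.0; bA <- 0.8; bz <- 1.2; pz <- 0.4; g0 <- 0.1; gz <- 1.1
  cfg <- binary_confounder_cfg(n = 20000, seed = 61, b0 = b0, bA = bA,
                               bz = bz, pz = pz, g0 = g0, gz = gz)
  rec <- generate_cohort(cfg)
  A <- assign_treatment(rec, "trt")
  Y <- derive_outcomes(rec)$Y_mortality
  truth <- gformula_truth(b0, bA, bz, pz)
  g_true <- plogis(g0 + gz * rec$z)
  Q_bad <- cbind(rep(mean(Y), length(Y)), rep(mean(Y), length(Y)))
  fit <- estimate_ate(cbind(z = rec$z), A, Y, g_hat = g_true, Q_init = Q_bad)
  expect_lt(abs(fit$estimate - truth), 3 * fit$se)
})

test_that("widening the truncation bounds never truncates more propensities", {
  cfg <- small_cfg(4000, seed = 71)
  co <- quick_cohort(cfg = cfg)
  X <- cohort_design(co)
  n_at_bounds <- function(b) {
    f <- estimate_ate(X, co$A_imv, co$Y_mortality, g_bounds = b, seed = 5,
                      learners = c("mean", "glm"))
    sum(f$g <= b[1] | f$g >= b[2])
  }
  expect_lte(n_at_bounds(c(0.01, 0.99)), n_at_bounds(c(0.025, 0.975)))
  expect_lte(n_at_bounds(c(0.001, 0.999)), n_at_bounds(c(0.01, 0.99)))
})

test_that("invalid estimation inputs raise explicit errors", {
  X <- cbind(z = rnorm(100))
  expect_error(estimate_ate(X, rep(2, 100), rbinom(100, 1, 0.5)), "binary")
  expect_error(estimate_ate(X, rbinom(100, 1, 0.5), rnorm(100) * 10),
               "\\[0, 1\\]")
  expect_error(estimate_ate(X, rep(1, 100), rbinom(100, 1, 0.5)),
               "positivity")
  expect_error(estimate_ate(X[1:20, , drop = FALSE], rbinom(20, 1, 0.5),
                            rbinom(20, 1, 0.5)), "at least")
})

test_that("stratified estimation covers every stratum or reports a skip", {
  co <- quick_cohort(3000, seed = 81)
  tab <- suppressWarnings(
    stratified_ates(co, treatments = "imv", outcome = "mortality",
                    seed = 2, learners = c("mean", "glm")))
  grid <- septrial:::strata_grid(co)
  expect_equal(nrow(tab), nrow(grid))          # nothing silently absent
  small <- tab$n < 50
  expect_true(all(!is.na(tab$skipped_reason[small])))
  done <- !is.na(tab$estimate)
  expect_true(all(is.na(tab$skipped_reason[done])))
  expect_true(all(abs(tab$estimate[done]) <= 1))
  expect_equal(tab$ci_lo[done], tab$estimate[done] - 1.96 * tab$se[done],
               tolerance = 1e-9)

  # a stratum with no treated rows is flagged as a positivity skip
  co2 <- co
  co2$A_imv[co2$cancer_category == "solid"] <- 0L
  tab2 <- suppressWarnings(
    stratified_ates(co2, treatments = "imv", outcome = "mortality",
                    seed = 2, learners = c("mean", "glm")))
  solid_full <- tab2[tab2$cancer_category == "solid" &
                       tab2$stratum == "0%-100%", ]
  expect_match(solid_full$skipped_reason, "positivity")
})

test_that("the designed treatment-severity interaction shows up across PMP strata", {
  cfg <- small_cfg(40000, seed = 91)
  co <- quick_cohort(cfg = cfg)
  X <- cohort_design(co)
  est_in <- function(str) {
    idx <- co$severity_stratum == str
    estimate_ate(X[idx, ], co$A_imv[idx], co$Y_mortality[idx], seed = 3,
                 learners = c("mean", "glm"))$estimate
  }
  tr <- compute_truth(cfg, n_mc = 1e5, seed = 6)
  t_low <- true_ate(tr, "imv", stratum = "low", stratum_type = "severity")$truth
  t_high <- true_ate(tr, "imv", stratum = "high", stratum_type = "severity")$truth
  expect_gt(t_high, t_low)                     # oracle confirms the design
  expect_gt(est_in("high") - est_in("low"), 0) # estimator recovers the sign
})
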