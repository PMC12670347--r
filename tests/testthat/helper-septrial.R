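# Shared fixtures, built in code.

# Default-structure synthetic config at a chosen size.
small_cfg <- function(n = 2000, seed = 1L, ...) {
  dgp_config(n_stays = n, seed = seed, ...)
}

# Minimal DGP with a single Bernoulli confounder z, one treatment "trt"
# always started inside the 24 h window, no cancer and no contamination.
# Closed-form g-formula quantities are available for this design.
binary_confounder_cfg <- function(n = 2000, seed = 1L,
                                  b0 = -1.0, bA = 0.8, bz = 1.2,
                                  pz = 0.4, g0 = 0.0, gz = 1.0) {
  dgp_config(
    n_stays = n, seed = seed,
    cancer_prevalences = c(solid = 0, hematological = 0, metastasized = 0),
    covariate_spec = list(
      list(name = "z", dist = "bernoulli", params = c(prob = pz),
           tag = "static", center = 0, scale = 1)
    ),
    propensity_coefficients = list(
      trt = list(intercept = g0, covariates = c(z = gz), cancer = NULL)
    ),
    treatment_start_distribution = list(family = "uniform", min = 0, max = 20),
    outcome_coefficients = list(intercept = b0, covariates = c(z = bz),
                                cancer = NULL, treatment = c(trt = bA),
                                treatment_severity = NULL),
    missing_discharge_rate = 0, under18_rate = 0, repeat_stay_rate = 0,
    short_stay_rate = 0, nonsepsis_rate = 0
  )
}

# closed-form standardized risk difference for binary_confounder_cfg
gformula_truth <- function(b0, bA, bz, pz) {
  sum(vapply(c(0, 1), function(z) {
    p <- ifelse(z == 1, pz, 1 - pz)
    p * (plogis(b0 + bA + bz * z) - plogis(b0 + bz * z))
  }, numeric(1)))
}

# build a trial cohort from the default synthetic structure
quick_cohort <- function(n = 2000, seed = 1L, cfg = small_cfg(n, seed)) {
  build_cohort(generate_cohort(cfg), calibration = default_calibration(cfg))
}

# hand-built tiny trial_cohort for summary-table arithmetic
make_toy_cohort <- function(n_cancer = 10, n_none = 10,
                            deaths_cancer = 2, deaths_none = 1) {
  n <- n_cancer + n_none
  y <- c(rep(1, deaths_cancer), rep(0, n_cancer - deaths_cancer),
         rep(1, deaths_none), rep(0, n_none - deaths_none))
  co <- data.frame(
    stay_id = sprintf("s%02d", seq_len(n)),
    severity_score = rep(30, n),
    A_imv = rep(c(1, 0), length.out = n),
    Y_mortality = y,
    Y_hfd = ifelse(y == 1, 0L, 20L),
    Y_parity = rep(c(0, 1), length.out = n),
    cancer_category = factor(rep(c("solid", "none"), c(n_cancer, n_none)),
                             levels = c("none", "solid", "hematological",
                                        "metastasized")),
    pmp = rep(0.2, n),
    severity_stratum = factor(rep("low", n),
                              levels = c("low", "moderate", "high")),
    los_days = rep(5, n),
    sex = rep(c("F", "M"), length.out = n)
  )
  attr(co, "covariates") <- "severity_score"
  attr(co, "treatments") <- "imv"
  class(co) <- c("trial_cohort", "data.frame")
  co
}
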