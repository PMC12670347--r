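#' Configuration of the synthetic septic-cohort generator
#'
#' Describes the full data-generating process for a stay-level septic ICU
#' cohort: covariate distributions, cancer-category prevalences, per-treatment
#' logistic propensity models, a treatment initiation-hour distribution with
#' mass both inside and outside the 24 h eligibility window, a logistic
#' in-hospital mortality model (death or discharge to hospice) with a
#' treatment-by-severity interaction, a length-of-stay model, and
#' contamination fractions that exercise the cohort inclusion filters.
#'
#' The default parameter values are invented: no public ICU database
#' documents its covariate joint distribution, so the defaults were chosen
#' once to emulate the broad margins of a pooled US septic ICU cohort
#' (roughly 10% cancer prevalence, 16% in-hospital mortality overall and
#' about twice that among cancer patients, about 45--50% of stays treated
#' with mechanical ventilation or vasopressors, median length of stay about
#' 5 days), with the severity score deliberately driving both treatment
#' uptake and mortality so that naive treated-vs-control contrasts are
#' confounded by design.
#'
#' Structural coefficients act on internally standardised covariates:
#' `z = (x - center) / scale` (on the log scale for log-normal variables),
#' with centres and scales fixed in `covariate_spec`, so coefficients are
#' interpretable as log-odds per SD.
#'
#' Mortality depends on treatment *received within the first 24 h*
#' (initiation after the window has no structural effect), so the target-trial
#' contrast downstream coincides with the structural treatment effect.
#'
#' @param n_stays number of ICU stays to generate.
#' @param seed integer seed; the same `(config, seed)` pair reproduces the
#'   cohort byte for byte.
#' @param cancer_prevalences named probabilities for `solid`,
#'   `hematological`, `metastasized`; the remainder is cancer-free.
#' @param covariate_spec list of covariate definitions
#'   `list(name, dist, params, tag, center, scale)`; `dist` one of
#'   `"normal"`, `"truncnorm"`, `"truncnorm_int"`, `"lognormal"`,
#'   `"uniform"`, `"gamma"`, `"bernoulli"`; `tag` is the first-24h
#'   aggregation tag (`max`, `min`, `mean`, `static`).
#' @param propensity_coefficients named list, one element per treatment,
#'   each `list(intercept, covariates = named vector, cancer = named vector)`
#'   on the log-odds scale for the latent "ever treated" state.
#' @param treatment_start_distribution initiation hour given ever treated;
#'   `list(family = "gamma", shape, scale)` (hours from ICU admission).
#' @param outcome_coefficients `list(intercept, covariates, cancer,
#'   treatment = named vector, treatment_severity = named vector)` for the
#'   logistic model of death-or-hospice.
#' @param los_model length-of-stay (days): truncated log-normal parameters
#'   per survival status plus the lower truncation bound `min_days`.
#' @param hospice_fraction among composite-mortality events, the fraction
#'   discharged to hospice rather than dying in hospital.
#' @param missing_discharge_rate,under18_rate,repeat_stay_rate,short_stay_rate,nonsepsis_rate
#'   independent contamination fractions that create records failing,
#'   respectively, the missing-discharge, adult-age, first-stay,
#'   one-day-stay and sepsis inclusion criteria.
#' @return an object of class `dgp_config`.
#' @seealso [generate_cohort()], [compute_truth()]
#' @export
dgp_config <- function(n_stays = 10000L,
                       seed = 1L,
                       cancer_prevalences = c(solid = 0.040,
                                              hematological = 0.024,
                                              metastasized = 0.040),
                       covariate_spec = default_covariate_spec(),
                       propensity_coefficients = default_propensity_coefficients(),
                       treatment_start_distribution = list(family = "gamma",
                                                           shape = 1.5,
                                                           scale = 8),
                       outcome_coefficients = default_outcome_coefficients(),
                       los_model = list(died = list(meanlog = log(4.8), sdlog = 0.85),
                                        survived = list(meanlog = log(5.3), sdlog = 0.80),
                                        min_days = 1),
                       hospice_fraction = 0.15,
                       missing_discharge_rate = 0.01,
                       under18_rate = 0.02,
                       repeat_stay_rate = 0.05,
                       short_stay_rate = 0.03,
                       nonsepsis_rate = 0.02) {
  cfg <- list(
    n_stays = as.integer(n_stays),
    seed = as.integer(seed),
    cancer_prevalences = cancer_prevalences,
    covariate_spec = covariate_spec,
    propensity_coefficients = propensity_coefficients,
    treatment_start_distribution = treatment_start_distribution,
    outcome_coefficients = outcome_coefficients,
    los_model = los_model,
    hospice_fraction = hospice_fraction,
    missing_discharge_rate = missing_discharge_rate,
    under18_rate = under18_rate,
    repeat_stay_rate = repeat_stay_rate,
    short_stay_rate = short_stay_rate,
    nonsepsis_rate = nonsepsis_rate
  )
  class(cfg) <- "dgp_config"
  validate_dgp_config(cfg)
  cfg
}

#' Default covariate specification for the synthetic cohort
#'
#' Seven first-24h covariate aggregates typical of a septic ICU cohort.
#' `severity_score` is an integer acute-severity score standing in for
#' OASIS/APACHE-type scores and is the variable the predicted mortality
#' probability (PMP) calibration acts on.
#'
#' @return list of covariate definitions (see [dgp_config()]).
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "severity_score", dist = "truncnorm_int",
         params = c(mean = 32, sd = 12, min = 0, max = 80),
         tag = "max", center = 32, scale = 12),
    list(name = "age", dist = "truncnorm",
         params = c(mean = 66, sd = 15, min = 18.01, max = 99),
         tag = "static", center = 66, scale = 15),
    list(name = "lactate_max", dist = "lognormal",
         params = c(meanlog = log(2.2), sdlog = 0.5),
         tag = "max", center = log(2.2), scale = 0.5, log_z = TRUE),
    list(name = "creatinine_max", dist = "lognormal",
         params = c(meanlog = log(1.2), sdlog = 0.6),
         tag = "max", center = log(1.2), scale = 0.6, log_z = TRUE),
    list(name = "heart_rate_mean", dist = "normal",
         params = c(mean = 95, sd = 15), tag = "mean",
         center = 95, scale = 15),
    list(name = "map_min", dist = "normal",
         params = c(mean = 62, sd = 10), tag = "min",
         center = 62, scale = 10),
    list(name = "wbc_max", dist = "lognormal",
         params = c(meanlog = log(12), sdlog = 0.4),
         tag = "max", center = log(12), scale = 0.4, log_z = TRUE)
  )
}

#' @rdname default_covariate_spec
#' @export
default_propensity_coefficients <- function() {
  list(
    imv = list(intercept = -0.15,
               covariates = c(severity_score = 0.9, age = 0.05,
                              lactate_max = 0.3, map_min = -0.3),
               cancer = c(solid = -0.05, hematological = -0.35,
                          metastasized = -0.15)),
    vasopressor = list(intercept = -0.35,
                       covariates = c(severity_score = 1.0,
                                      lactate_max = 0.5, map_min = -0.5),
                       cancer = c(solid = 0.0, hematological = -0.20,
                                  metastasized = 0.0))
  )
}

#' @rdname default_covariate_spec
#' @export
default_outcome_coefficients <- function() {
  list(intercept = -2.35,
       covariates = c(severity_score = 1.0, age = 0.25, lactate_max = 0.4),
       cancer = c(solid = 0.5, hematological = 0.9, metastasized = 1.0),
       treatment = c(imv = 0.25, vasopressor = 0.35),
       treatment_severity = c(imv = 0.15, vasopressor = 0.15))
}

validate_dgp_config <- function(cfg) {
  stopifnot(inherits(cfg, "dgp_config"))
  if (cfg$n_stays < 1L) stop("n_stays must be >= 1", call. = FALSE)
  prev <- cfg$cancer_prevalences
  if (any(prev < 0) || any(prev > 1) || sum(prev) > 1) {
    stop("cancer_prevalences must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  rates <- c(cfg$missing_discharge_rate, cfg$under18_rate,
             cfg$repeat_stay_rate, cfg$short_stay_rate, cfg$nonsepsis_rate,
             cfg$hospice_fraction)
  if (any(rates < 0) || any(rates > 1)) {
    stop("contamination fractions must lie in [0,1]", call. = FALSE)
  }
  all_coefs <- unlist(c(lapply(cfg$propensity_coefficients, unlist),
                        unlist(cfg$outcome_coefficients)))
  if (!all(is.finite(all_coefs))) {
    stop("configuration error: non-finite structural coefficients",
         call. = FALSE)
  }
  trts <- names(cfg$propensity_coefficients)
  if (is.null(trts) || any(trts == "")) {
    stop("propensity_coefficients must be a named list (one per treatment)",
         call. = FALSE)
  }
  miss <- setdiff(trts, names(cfg$outcome_coefficients$treatment))
  if (length(miss)) {
    stop("outcome_coefficients$treatment missing treatments: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

dgp_treatments <- function(cfg) names(cfg$propensity_coefficients)

# sample one covariate column
sample_covariate <- function(n, cv) {
  p <- cv$params
  switch(cv$dist,
    normal = stats::rnorm(n, p[["mean"]], p[["sd"]]),
    truncnorm = truncnorm_draw(n, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]]),
    truncnorm_int = round(truncnorm_draw(n, p[["mean"]], p[["sd"]],
                                         p[["min"]], p[["max"]])),
    lognormal = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    uniform = stats::runif(n, p[["min"]], p[["max"]]),
    gamma = stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    bernoulli = stats::rbinom(n, 1L, p[["prob"]]),
    stop("unknown covariate distribution: ", cv$dist, call. = FALSE)
  )
}

truncnorm_draw <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_covariates <- function(cfg, n) {
  cols <- lapply(cfg$covariate_spec, function(cv) sample_covariate(n, cv))
  names(cols) <- vapply(cfg$covariate_spec, `[[`, "", "name")
  as.data.frame(cols)
}

# standardised design used by all structural equations
standardize_covariates <- function(cfg, covars) {
  z <- lapply(cfg$covariate_spec, function(cv) {
    x <- covars[[cv$name]]
    if (isTRUE(cv$log_z)) x <- log(x)
    (x - (cv$center %||% 0)) / (cv$scale %||% 1)
  })
  names(z) <- vapply(cfg$covariate_spec, `[[`, "", "name")
  do.call(cbind, z)
}

cancer_indicator_matrix <- function(cancer_category) {
  lv <- c("solid", "hematological", "metastasized")
  m <- sapply(lv, function(l) as.numeric(cancer_category == l))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, lv))
  m
}

linear_predictor <- function(coefs, Z, C) {
  lp <- rep(coefs$intercept, nrow(Z))
  bc <- coefs$covariates
  if (length(bc)) {
    missing_cov <- setdiff(names(bc), colnames(Z))
    if (length(missing_cov)) {
      stop("coefficients reference unknown covariates: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    lp <- lp + as.vector(Z[, names(bc), drop = FALSE] %*% bc)
  }
  bk <- coefs$cancer
  if (length(bk)) lp <- lp + as.vector(C[, names(bk), drop = FALSE] %*% bk)
  lp
}

outcome_linear_predictor <- function(cfg, Z, C, D) {
  oc <- cfg$outcome_coefficients
  lp <- linear_predictor(oc, Z, C)
  zsev <- if ("severity_score" %in% colnames(Z)) Z[, "severity_score"] else 0
  for (t in colnames(D)) {
    bt <- oc$treatment[[t]] %||% 0
    gt <- oc$treatment_severity[[t]] %||% 0
    lp <- lp + D[, t] * (bt + gt * zsev)
  }
  lp
}

draw_start_hour <- function(cfg, n) {
  d <- cfg$treatment_start_distribution
  switch(d$family,
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    uniform = stats::runif(n, d$min, d$max),
    stop("unknown treatment_start_distribution family: ", d$family,
         call. = FALSE)
  )
}

# P(start hour <= w) under the configured initiation-time law
start_within_prob <- function(cfg, w = 24) {
  d <- cfg$treatment_start_distribution
  switch(d$family,
    gamma = stats::pgamma(w, shape = d$shape, scale = d$scale),
    uniform = stats::punif(w, d$min, d$max))
}

trunc_lnorm_draw <- function(u, meanlog, sdlog, lo) {
  # inverse-CDF draw from a log-normal truncated below at `lo`
  plo <- stats::plnorm(lo, meanlog, sdlog)
  stats::qlnorm(plo + u * (1 - plo), meanlog, sdlog)
}

draw_cancer <- function(cfg, n) {
  prev <- cfg$cancer_prevalences
  probs <- c(none = 1 - sum(prev), prev[c("solid", "hematological", "metastasized")])
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# diagnosis-code lists consistent with the latent cancer label, using the
# packaged toy code map plus unmapped comorbidity noise codes
draw_diagnosis_codes <- function(cancer_category) {
  solid <- c("C18", "C34", "C50", "C61")
  heme <- c("C81", "C91", "C92")
  met <- c("C77", "C78", "C79")
  noise <- c("I10", "J44", "N17", "E11", "A41", "J96")
  vapply(cancer_category, function(cc) {
    codes <- sample(noise, sample(2:4, 1))
    if (cc == "solid") {
      codes <- c(codes, sample(solid, 1))
    } else if (cc == "hematological") {
      codes <- c(codes, sample(heme, 1),
                 if (stats::runif(1) < 0.4) sample(solid, 1))
    } else if (cc == "metastasized") {
      codes <- c(codes, sample(met, 1),
                 if (stats::runif(1) < 0.7) sample(solid, 1),
                 if (stats::runif(1) < 0.15) sample(heme, 1))
    }
    paste(sample(codes), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic stay-level septic ICU cohort
#'
#' Draws `config$n_stays` ICU stay records from the structural model in
#' `config`: covariates, a latent cancer category with consistent
#' diagnosis-code lists, per-treatment initiation hours from a confounded
#' logistic propensity, composite in-hospital mortality (death or hospice
#' discharge) from a logistic outcome model in which only treatment begun
#' within 24 h acts, a length of stay, an event hour of day drawn
#' independently of everything (the negative-control outcome), and
#' contamination records that fail the inclusion filters.
#'
#' @param config a [dgp_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a `data.frame` of class `stay_records`, one row per stay. The
#'   column `cancer_category_latent` is generator ground truth (not
#'   available in real data) kept for validation; `<treatment>_start_hour`
#'   columns are `NA` for never-treated stays.
#' @export
#' @examples
#' cfg <- dgp_config(n_stays = 200, seed = 42)
#' rec <- generate_cohort(cfg)
#' table(rec$cancer_category_latent)
generate_cohort <- function(config, seed = NULL) {
  validate_dgp_config(config)
  with_seed(seed %||% config$seed, {
    n <- config$n_stays
    covars <- draw_covariates(config, n)
    cancer <- draw_cancer(config, n)
    Z <- standardize_covariates(config, covars)
    C <- cancer_indicator_matrix(cancer)

    trts <- dgp_treatments(config)
    start <- matrix(NA_real_, n, length(trts), dimnames = list(NULL, trts))
    D <- matrix(0, n, length(trts), dimnames = list(NULL, trts))
    for (t in trts) {
      p_ever <- expit(linear_predictor(config$propensity_coefficients[[t]], Z, C))
      ever <- stats::rbinom(n, 1L, p_ever) == 1L
      h <- draw_start_hour(config, n)
      start[ever, t] <- h[ever]
      D[, t] <- as.numeric(ever & h <= 24)
    }

    p_y <- expit(outcome_linear_predictor(config, Z, C, D))
    y <- stats::rbinom(n, 1L, p_y) == 1L
    hospice <- y & stats::runif(n) < config$hospice_fraction
    died <- y & !hospice

    u_los <- stats::runif(n)
    lm_ <- config$los_model
    los <- ifelse(y,
      trunc_lnorm_draw(u_los, lm_$died$meanlog, lm_$died$sdlog, lm_$min_days),
      trunc_lnorm_draw(u_los, lm_$survived$meanlog, lm_$survived$sdlog,
                       lm_$min_days))

    discharge <- ifelse(died, "DIED", ifelse(hospice, "HOSPICE",
      sample(c("HOME", "SNF", "REHAB"), n, replace = TRUE,
             prob = c(0.60, 0.25, 0.15))))

    rec <- data.frame(
      stay_id = sprintf("stay_%06d", seq_len(n)),
      subject_id = sprintf("subj_%06d", seq_len(n)),
      stay_index = 1L,
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.456, 0.544)),
      race = sample(c("White", "Black", "Other", "Hispanic", "Asian"), n,
                    replace = TRUE,
                    prob = c(0.736, 0.101, 0.102, 0.042, 0.019)),
      sepsis3 = TRUE,
      diagnosis_codes = draw_diagnosis_codes(cancer),
      stringsAsFactors = FALSE
    )
    rec <- cbind(rec, covars)
    for (t in trts) rec[[paste0(t, "_start_hour")]] <- start[, t]
    rec$los_days <- los
    rec$died_in_hospital <- died
    rec$discharged_to_hospice <- hospice
    rec$discharge_location <- discharge
    rec$event_hour_of_day <- sample(0:23, n, replace = TRUE)
    rec$code_status_admission <- stats::runif(n) < 0.92
    rec$code_status_discharge <- stats::runif(n) < 0.82
    rec$cancer_category_latent <- cancer

    # contamination: independent per-record flips exercising each filter
    flip <- function(rate) stats::runif(n) < rate
    i <- flip(config$under18_rate)
    if (!is.null(rec$age)) rec$age[i] <- stats::runif(sum(i), 1, 17.9)
    i <- flip(config$nonsepsis_rate)
    rec$sepsis3[i] <- FALSE
    i <- flip(config$repeat_stay_rate)
    rec$stay_index[i] <- sample(2:3, sum(i), replace = TRUE)
    i <- flip(config$missing_discharge_rate)
    rec$discharge_location[i] <- NA_character_
    i <- flip(config$short_stay_rate)
    rec$los_days[i] <- stats::runif(sum(i), 0.1, 0.99)

    attr(rec, "covariates") <- names(covars)
    attr(rec, "treatments") <- trts
    class(rec) <- c("stay_records", "data.frame")
    rec
  })
}

#' Monte-Carlo ground-truth causal effects for a synthetic configuration
#'
#' Brute-force oracle: simulates `n_mc` covariate draws from the structural
#' model and contrasts each stay's potential outcomes with the treatment of
#' interest forced on versus off within the 24 h window (other treatments
#' keep their natural, covariate-driven values). Mortality contrasts use the
#' conditional probability difference per draw (Rao-Blackwellised over the
#' Bernoulli outcome draw); hospital-free-day contrasts couple the death and
#' length-of-stay draws across arms. Also reports the counterfactual
#' mortality mean with every treatment withheld (the "baseline" mean).
#'
#' Truths are reported overall and within cancer-category and
#' severity-tertile strata (tertiles of the predicted mortality probability
#' implied by [default_calibration()]).
#'
#' @param config a [dgp_config()].
#' @param n_mc number of Monte-Carlo draws (at least 10,000).
#' @param seed integer seed for the oracle draws.
#' @param window_hours eligibility window defining "treated" (default 24).
#' @return object of class `truth_oracle` with elements `ate` (data.frame:
#'   treatment, outcome, stratum_type, stratum, truth, mc_se, n) and
#'   `baseline` (counterfactual untreated mortality mean per stratum).
#' @export
compute_truth <- function(config, n_mc = 1e5, seed = 1L, window_hours = 24) {
  validate_dgp_config(config)
  if (n_mc < 1e4) stop("n_mc must be at least 10,000", call. = FALSE)
  with_seed(seed, {
    n <- as.integer(n_mc)
    covars <- draw_covariates(config, n)
    cancer <- draw_cancer(config, n)
    Z <- standardize_covariates(config, covars)
    C <- cancer_indicator_matrix(cancer)
    trts <- dgp_treatments(config)

    # natural within-window treatment states
    Dnat <- matrix(0, n, length(trts), dimnames = list(NULL, trts))
    for (t in trts) {
      p_ever <- expit(linear_predictor(config$propensity_coefficients[[t]], Z, C))
      ever <- stats::rbinom(n, 1L, p_ever) == 1L
      h <- draw_start_hour(config, n)
      Dnat[, t] <- as.numeric(ever & h <= window_hours)
    }

    has_severity <- "severity_score" %in% names(covars)
    strata <- list(cancer = cancer)
    if (has_severity) {
      pmp <- default_calibration_pmp(config, covars$severity_score)
      strata$severity <- cut(pmp,
                             breaks = stats::quantile(pmp, c(0, 1/3, 2/3, 1)),
                             labels = c("low", "moderate", "high"),
                             include.lowest = TRUE)
    }

    lm_ <- config$los_model
    u_death <- stats::runif(n)
    u_los <- stats::runif(n)

    hfd_of <- function(death, los) ifelse(death, 0, pmax(0, 28 - ceiling(los)))

    rows <- list()
    for (t in trts) {
      D1 <- Dnat; D1[, t] <- 1
      D0 <- Dnat; D0[, t] <- 0
      p1 <- expit(outcome_linear_predictor(config, Z, C, D1))
      p0 <- expit(outcome_linear_predictor(config, Z, C, D0))
      diff_mort <- p1 - p0
      death1 <- u_death < p1
      death0 <- u_death < p0
      los1 <- ifelse(death1,
        trunc_lnorm_draw(u_los, lm_$died$meanlog, lm_$died$sdlog, lm_$min_days),
        trunc_lnorm_draw(u_los, lm_$survived$meanlog, lm_$survived$sdlog,
                         lm_$min_days))
      los0 <- ifelse(death0,
        trunc_lnorm_draw(u_los, lm_$died$meanlog, lm_$died$sdlog, lm_$min_days),
        trunc_lnorm_draw(u_los, lm_$survived$meanlog, lm_$survived$sdlog,
                         lm_$min_days))
      diff_hfd <- hfd_of(death1, los1) - hfd_of(death0, los0)

      add_row <- function(outcome, diffs, stratum_type, stratum, idx) {
        d <- diffs[idx]
        data.frame(treatment = t, outcome = outcome,
                   stratum_type = stratum_type, stratum = stratum,
                   truth = mean(d),
                   mc_se = stats::sd(d) / sqrt(length(d)),
                   n = length(d), stringsAsFactors = FALSE)
      }
      for (outc in c("mortality", "hfd")) {
        diffs <- if (outc == "mortality") diff_mort else diff_hfd
        rows[[length(rows) + 1L]] <-
          add_row(outc, diffs, "overall", "0%-100%", seq_len(n))
        for (cc in unique(strata$cancer)) {
          rows[[length(rows) + 1L]] <-
            add_row(outc, diffs, "cancer", cc, which(strata$cancer == cc))
        }
        any_ca <- which(strata$cancer != "none")
        if (length(any_ca)) {
          rows[[length(rows) + 1L]] <-
            add_row(outc, diffs, "cancer", "any", any_ca)
        }
        if (has_severity) {
          for (sv in levels(strata$severity)) {
            rows[[length(rows) + 1L]] <-
              add_row(outc, diffs, "severity", sv, which(strata$severity == sv))
          }
        }
      }
    }

    D00 <- matrix(0, n, length(trts), dimnames = list(NULL, trts))
    p_base <- expit(outcome_linear_predictor(config, Z, C, D00))
    base_rows <- lapply(c("overall", unique(cancer), "any"), function(s) {
      idx <- switch(s, overall = seq_len(n), any = which(cancer != "none"),
                    which(cancer == s))
      if (!length(idx)) return(NULL)
      data.frame(stratum = s, truth = mean(p_base[idx]),
                 mc_se = stats::sd(p_base[idx]) / sqrt(length(idx)),
                 n = length(idx), stringsAsFactors = FALSE)
    })

    out <- list(ate = do.call(rbind, rows),
                baseline = do.call(rbind, base_rows),
                n_mc = n, window_hours = window_hours)
    class(out) <- "truth_oracle"
    out
  })
}

#' Look up one oracle truth value
#'
#' @param truth a `truth_oracle` from [compute_truth()].
#' @param treatment treatment name.
#' @param outcome `"mortality"` or `"hfd"`.
#' @param stratum stratum label (default overall).
#' @param stratum_type `"overall"`, `"cancer"` or `"severity"`.
#' @return one-row data.frame with `truth` and `mc_se`.
#' @export
true_ate <- function(truth, treatment, outcome = "mortality",
                     stratum = "0%-100%", stratum_type = "overall") {
  a <- truth$ate
  r <- a[a$treatment == treatment & a$outcome == outcome &
           a$stratum_type == stratum_type & a$stratum == stratum, ]
  if (nrow(r) != 1L) stop("no unique oracle entry for that query", call. = FALSE)
  r
}

#' PMP calibration implied by the synthetic outcome model
#'
#' Maps the integer severity score to a predicted mortality probability with
#' the logistic link `expit(a + b * score)`, where `(a, b)` are derived from
#' the configuration's outcome coefficients so the calibration plays the
#' role the OASIS/APACHE prediction formulas play on real data.
#'
#' @param config a [dgp_config()].
#' @return numeric `c(intercept, slope)` on the log-odds scale.
#' @export
default_calibration <- function(config) {
  oc <- config$outcome_coefficients
  cv <- Filter(function(x) x$name == "severity_score", config$covariate_spec)
  if (!length(cv)) stop("config has no severity_score covariate", call. = FALSE)
  cv <- cv[[1L]]
  b <- (oc$covariates[["severity_score"]] %||% 0) / cv$scale
  a <- oc$intercept - b * cv$center
  c(intercept = a, slope = b)
}

default_calibration_pmp <- function(config, score) {
  cal <- default_calibration(config)
  expit(cal[["intercept"]] + cal[["slope"]] * score)
}

#' @export
print.stay_records <- function(x, ...) {
  cat(sprintf("<stay_records> %d ICU stays, %d covariates, treatments: %s\n",
              nrow(x), length(attr(x, "covariates")),
              paste(attr(x, "treatments"), collapse = ", ")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' @export
print.truth_oracle <- function(x, ...) {
  cat(sprintf("<truth_oracle> %d Monte-Carlo draws, %d truth entries\n",
              x$n_mc, nrow(x$ate)))
  ov <- x$ate[x$ate$stratum_type == "overall", ]
  print(ov, row.names = FALSE)
  invisible(x)
}

#' Write / read a stay-level cohort as delimited text
#'
#' Tab-separated, header row, hours and days as plain floats; missing values
#' written as empty fields. `read_cohort()` restores the `stay_records`
#' attributes (treatments are inferred from `*_start_hour` columns).
#'
#' @param records a `stay_records` data.frame.
#' @param path file path.
#' @param covariates covariate column names (for `read_cohort`; default: the
#'   columns of [default_covariate_spec()] present in the file).
#' @return `write_cohort`: `path`, invisibly. `read_cohort`: `stay_records`.
#' @export
write_cohort <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, covariates = NULL) {
  rec <- utils::read.delim(path, sep = "\t", na.strings = "",
                           stringsAsFactors = FALSE)
  trts <- sub("_start_hour$", "", grep("_start_hour$", names(rec), value = TRUE))
  if (is.null(covariates)) {
    covariates <- intersect(
      vapply(default_covariate_spec(), `[[`, "", "name"), names(rec))
  }
  attr(rec, "covariates") <- covariates
  attr(rec, "treatments") <- trts
  class(rec) <- c("stay_records", "data.frame")
  rec
}

#' @rdname write_cohort
#' @param truth a `truth_oracle`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(ate = truth$ate, baseline = truth$baseline,
                            n_mc = truth$n_mc,
                            window_hours = truth$window_hours),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
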