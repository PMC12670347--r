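clean_records <- function(n = 10) {
  data.frame(stay_id = sprintf("s%02d", seq_len(n)), age = 50, sepsis3 = TRUE,
              stay_index = 1L, discharge_location = "HOME", los_days = 5)
}

test_that("inclusion filters apply in fixed order and reconcile", {
  rec <- clean_records(10)
  out <- apply_inclusion(rec)
  expect_equal(nrow(out$records), 10)
  expect_true(all(out$log == 0))

  rec$los_days[3] <- 0.5               # excluded: stay under one day
  rec$age[4] <- 18                     # boundary: "older than 18" is strict
  rec$discharge_location[5] <- NA
  rec$stay_index[6] <- 2L
  rec$sepsis3[7] <- FALSE
  out <- apply_inclusion(rec)
  expect_equal(unname(out$log[["LOS < 1 day"]]), 1)
  expect_equal(unname(out$log[["under-18"]]), 1)
  expect_equal(unname(out$log[["missing discharge location"]]), 1)
  expect_equal(unname(out$log[["not first stay"]]), 1)
  expect_equal(unname(out$log[["no sepsis flag"]]), 1)
  expect_equal(attr(out$log, "n_input") - sum(out$log),
               attr(out$log, "n_output"))
  expect_false("s03" %in% out$records$stay_id)

  # idempotence
  again <- apply_inclusion(out$records)
  expect_equal(nrow(again$records), nrow(out$records))
  expect_true(all(again$log == 0))
})

test_that("missing required fields raise a per-record error with stay ids", {
  rec <- clean_records(3)
  rec$age[2] <- NA
  expect_error(apply_inclusion(rec), "s02")
  expect_error(apply_inclusion(rec[, setdiff(names(rec), "los_days")]),
               "los_days")
})

test_that("exclusion counts match contamination expectations under criterion order", {
  cfg <- small_cfg(10000, seed = 31, under18_rate = 0.05,
                   repeat_stay_rate = 0.03, missing_discharge_rate = 0.02,
                   short_stay_rate = 0, nonsepsis_rate = 0)
  out <- apply_inclusion(generate_cohort(cfg))
  n <- 10000
  # expected removals respect the filter order (earlier filters thin later ones)
  p <- c(`under-18` = 0.05, `no sepsis flag` = 0, `not first stay` = 0.03,
         `missing discharge location` = 0.02, `LOS < 1 day` = 0)
  surv <- 1
  for (crit in names(p)) {
    expected <- n * surv * p[[crit]]
    se <- sqrt(n * surv * p[[crit]] * (1 - surv * p[[crit]]))
    expect_lte(abs(out$log[[crit]] - expected), max(3 * se, 1e-9),
               label = crit)
    surv <- surv * (1 - p[[crit]])
  }
})

test_that("treatment assignment honours the 24h window and keeps every record", {
  rec <- clean_records(4)
  rec$imv_start_hour <- c(30, NA, 24, 2)
  A <- assign_treatment(rec, "imv")
  expect_equal(A, c(0L, 0L, 1L, 1L))   # late start stays in control, retained
  expect_length(A, nrow(rec))
  rec$imv_start_hour[1] <- -1
  expect_error(assign_treatment(rec, "imv"), "negative")
  expect_error(assign_treatment(clean_records(2), "imv"), "imv_start_hour")
})

test_that("cancer categorization follows the metastasized > hematological > solid hierarchy", {
  map <- load_code_map()
  expect_equal(as.character(categorize_cancer("C91;C78", map)), "metastasized")
  expect_equal(as.character(categorize_cancer("C18;C91", map)), "hematological")
  expect_equal(as.character(categorize_cancer("C18", map)), "solid")
  expect_equal(as.character(categorize_cancer("", map)), "none")
  out <- categorize_cancer(c("I10;E11", "C34;ZZZ"), map)
  expect_equal(as.character(out), c("none", "solid"))
  expect_equal(attr(out, "n_unmapped"), 3L)  # unmapped codes ignored, counted
})

test_that("covariate aggregation respects the 24h window and tags", {
  tv <- data.frame(variable = "lac", offset_hour = c(-2, 3, 10),
                   value = c(5, 7, 9))
  expect_equal(unname(aggregate_covariates(tv, c(lac = "max"))), 9)
  tv2 <- data.frame(variable = c("a", "a", "b", "c"),
                    offset_hour = c(1, 2, 5, 30), value = c(2, 4, 7, 99))
  agg <- aggregate_covariates(tv2, c(a = "mean", b = "min", c = "max"))
  expect_equal(unname(agg["a"]), 3)
  expect_equal(unname(agg["b"]), 7)
  expect_true(is.na(agg["c"]))         # only a post-window value
  one <- aggregate_covariates(data.frame(variable = "x", offset_hour = 4,
                                         value = 3.5),
                              c(x = "static"))
  expect_equal(unname(one), 3.5)
  expect_error(aggregate_covariates(tv, c(lac = "median")), "tag")
})

test_that("outcome derivation matches the composite and hospital-free-day rules", {
  rec <- data.frame(died_in_hospital = c(FALSE, FALSE, TRUE, FALSE),
                    discharged_to_hospice = c(FALSE, TRUE, FALSE, FALSE),
                    los_days = c(5.2, 3, 2, 40),
                    event_hour_of_day = c(14, 13, 2, 8))
  y <- derive_outcomes(rec)
  expect_equal(y$Y_mortality, c(0L, 1L, 1L, 0L))
  expect_equal(y$Y_hfd, c(22L, 0L, 0L, 0L))  # 28 - ceil(5.2); hfd floors at 0
  expect_equal(y$Y_parity, c(1L, 0L, 1L, 1L))
})

test_that("PMP is a calibrated logistic of the severity score", {
  expect_equal(compute_pmp(40, c(-40 * 0.1, 0.1)), 0.5)
  expect_equal(compute_pmp(c(10, 70), c(0.3, 0)), rep(plogis(0.3), 2))
  expect_error(compute_pmp(40, NULL), "calibration")
  expect_error(compute_pmp(40), "calibration")
  p <- compute_pmp(seq(0, 80, 10), c(-5, 0.08))
  expect_true(all(diff(p) > 0) && all(p > 0 & p < 1))
})

test_that("PMP rank-correlates with realized mortality on synthetic data", {
  co <- quick_cohort(10000, seed = 17)
  expect_gt(cor(co$pmp, co$Y_mortality, method = "spearman"), 0.1)
})

test_that("severity strata split as tertiles or half-open bands", {
  expect_equal(as.character(assign_strata(c(0.1, 0.2, 0.3), "tertile")),
               c("low", "moderate", "high"))
  lab <- assign_strata(c(0.05, 0.10, 0.5), "bands",
                       band_edges = c(0, 0.10, 0.20, 1))
  expect_equal(as.character(lab), c("0%-10%", "10%-20%", "20%-100%"))
  expect_warning(s <- assign_strata(rep(0.2, 5), "tertile"), "identical")
  expect_equal(length(unique(s)), 1L)
  expect_error(assign_strata(c(0.1), "bands", band_edges = c(0.5, 0.1)),
               "increasing")
})

test_that("built cohort satisfies its structural invariants", {
  cfg <- small_cfg(4000, seed = 23)
  co <- build_cohort(generate_cohort(cfg),
                     calibration = default_calibration(cfg))
  # outcome coupling
  expect_true(all(co$Y_hfd[co$Y_mortality == 1] == 0))
  expect_true(all(co$Y_hfd >= 0 & co$Y_hfd <= 28))
  expect_true(all(co$pmp > 0 & co$pmp < 1))
  # strata partition the cohort
  expect_equal(sum(table(co$severity_stratum)), nrow(co))
  # treatment assignment drops no record
  expect_equal(nrow(co), attr(attr(co, "exclusion_log"), "n_output"))
  # code-based categorizer recovers the generator's latent label exactly
  expect_equal(as.character(co$cancer_category), co$cancer_category_latent)
  expect_false(anyNA(co$A_imv) || anyNA(co$Y_mortality))
})
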