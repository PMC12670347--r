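#' Baseline cohort summary table
#'
#' Per group (cancer, non-cancer, overall): stay count, count (percentage)
#' for binary variables and median (Q1, Q3) for continuous ones, with
#' length of stay split by composite-mortality status. Percentages are
#' printed to one decimal; quantiles use the linear-interpolation (type-7)
#' convention. Groups with no qualifying rows print an em dash.
#'
#' @param cohort a `trial_cohort`.
#' @return data.frame of class `cohort_summary`: one row per variable, one
#'   character column per group.
#' @export
summarize_cohort <- function(cohort) {
  groups <- list(
    Cancer = cohort$cancer_category != "none",
    `Non-Cancer` = cohort$cancer_category == "none",
    Overall = rep(TRUE, nrow(cohort))
  )
  med_iqr <- function(x) {
    if (!length(x)) return("—")
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3])
  }
  one_group <- function(idx) {
    d <- cohort[idx, , drop = FALSE]
    vals <- c(
      `N` = format(nrow(d), big.mark = ","),
      `In-hospital mortality` = format_count(sum(d$Y_mortality), nrow(d)),
      `Length of stay if died (days)` = med_iqr(d$los_days[d$Y_mortality == 1]),
      `Length of stay if survived (days)` = med_iqr(d$los_days[d$Y_mortality == 0])
    )
    for (t in attr(cohort, "treatments")) {
      vals[paste("Treated:", t)] <- format_count(sum(d[[paste0("A_", t)]]),
                                                 nrow(d))
    }
    if ("age" %in% names(d)) {
      vals[["Age (years)"]] <- med_iqr(d$age)
    }
    if ("sex" %in% names(d)) {
      vals[["Sex (female)"]] <- format_count(sum(d$sex == "F"), nrow(d))
    }
    vals
  }
  cols <- lapply(groups, one_group)
  out <- data.frame(variable = names(cols[[1]]), cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects every setting of an end-to-end run: input mode, seeds, the PMP
#' calibration, treatment-assignment window, stratification mode,
#' propensity truncation bounds, nuisance stacking settings and disparity
#' resampling settings.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read stay-level delimited text from `input_path`).
#' @param dgp a [dgp_config()] (simulate mode).
#' @param input_path stay-level cohort file (ingest mode).
#' @param calibration PMP calibration `c(intercept, slope)`; defaults to the
#'   calibration implied by the synthetic outcome model in simulate mode,
#'   and must be given explicitly in ingest mode.
#' @param treatments treatment names; default: inferred from the records.
#' @param window_hours treatment eligibility window.
#' @param strata_mode,band_edges see [assign_strata()].
#' @param g_bounds propensity truncation bounds.
#' @param stacking list: `k` folds and `learners` for nuisance stacks.
#' @param disparity list: `n_iter`, `k`, `train_frac`, `nrounds` for
#'   [resampled_or()].
#' @param outcomes outcomes to estimate ATEs for.
#' @param oracle if `TRUE` (simulate mode), also compute and write the
#'   Monte-Carlo ground truth.
#' @param seed master seed for the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       dgp = dgp_config(),
                       input_path = NULL,
                       calibration = NULL,
                       treatments = NULL,
                       window_hours = 24,
                       strata_mode = "tertile", band_edges = NULL,
                       g_bounds = c(0.025, 0.975),
                       stacking = list(k = 5, learners = c("mean", "glm", "glmnet")),
                       disparity = list(n_iter = 100, k = 5, train_frac = 0.2,
                                        nrounds = 100),
                       outcomes = c("mortality", "hfd"),
                       oracle = FALSE,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ingest") {
    if (is.null(input_path) || !file.exists(input_path)) {
      stop("ingest mode requires an existing input_path", call. = FALSE)
    }
    if (is.null(calibration)) {
      stop("ingest mode requires an explicit PMP calibration", call. = FALSE)
    }
  }
  if (mode == "simulate" && is.null(calibration)) {
    calibration <- default_calibration(dgp)
  }
  cfg <- list(mode = mode, dgp = dgp, input_path = input_path,
              calibration = calibration, treatments = treatments,
              window_hours = window_hours, strata_mode = strata_mode,
              band_edges = band_edges, g_bounds = g_bounds,
              stacking = stacking, disparity = disparity,
              outcomes = outcomes, oracle = oracle, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a stay-level cohort, build the target-trial cohort,
#' tabulate positivity, estimate disparity odds ratios, estimate stratified
#' treatment effects and the negative control, and write every artifact as
#' delimited text to `out_dir` along with a manifest (configuration, seeds
#' and package versions) sufficient to reproduce the run byte for byte.
#' A stage failure aborts with the stage name; artifacts written before the
#' failure are left in place.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with every in-memory result plus `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("septrial_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seeds <- spawn_seeds(config$seed, 6L)

  records <- stage("input", {
    if (config$mode == "simulate") {
      rec <- generate_cohort(config$dgp, seed = seeds[1])
      write_cohort(rec, file.path(out_dir, "cohort_stays.tsv"))
      if (isTRUE(config$oracle)) {
        truth <- compute_truth(config$dgp, seed = seeds[2])
        write_truth(truth, file.path(out_dir, "truth_oracle.json"))
      }
      rec
    } else {
      read_cohort(config$input_path)
    }
  })

  cohort <- stage("build-cohort", {
    co <- build_cohort(records, calibration = config$calibration,
                       treatments = config$treatments %||%
                         attr(records, "treatments"),
                       window_hours = config$window_hours,
                       strata_mode = config$strata_mode,
                       band_edges = config$band_edges)
    log <- attr(co, "exclusion_log")
    write_tsv(data.frame(criterion = names(log), removed = as.integer(log)),
              file.path(out_dir, "exclusion_log.tsv"))
    write_tsv(summarize_cohort(co), file.path(out_dir, "cohort_summary.tsv"))
    co
  })

  positivity <- stage("diagnose", {
    pt <- positivity_table(cohort)
    write_tsv(pt, file.path(out_dir, "positivity_table.tsv"))
    pt
  })

  disparity <- stage("disparity", {
    d <- config$disparity
    tab <- disparity_ors(cohort, seed = seeds[3],
                         n_iter = d$n_iter %||% 100, k = d$k %||% 5,
                         train_frac = d$train_frac %||% 0.2,
                         nrounds = d$nrounds %||% 100)
    write_tsv(tab, file.path(out_dir, "disparity_or.tsv"))
    tab
  })

  ates <- stage("ate", {
    st <- config$stacking
    tabs <- lapply(config$outcomes, function(oc) {
      stratified_ates(cohort, outcome = oc, seed = seeds[4],
                      k = st$k %||% 5,
                      learners = st$learners %||% c("mean", "glm", "glmnet"),
                      g_bounds = config$g_bounds)
    })
    tab <- do.call(rbind, tabs)
    write_tsv(tab, file.path(out_dir, "tmle_ate.tsv"))
    tab
  })

  negctrl <- stage("negative-control", {
    st <- config$stacking
    rows <- lapply(attr(cohort, "treatments"), function(t) {
      r <- negative_control(cohort, t, seed = seeds[5], k = st$k %||% 5,
                            learners = st$learners %||% c("mean", "glm", "glmnet"),
                            g_bounds = config$g_bounds)
      data.frame(treatment = t, estimate = r$estimate, se = r$se,
                 ci_lo = r$ci95[["lo"]], ci_hi = r$ci95[["hi"]],
                 covers_zero = r$covers_zero, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    write_tsv(tab, file.path(out_dir, "negative_control.tsv"))
    tab
  })

  stage("manifest", {
    manifest <- list(
      mode = config$mode,
      seed = config$seed,
      derived_seeds = seeds,
      window_hours = config$window_hours,
      calibration = as.numeric(config$calibration),
      strata_mode = config$strata_mode,
      g_bounds = config$g_bounds,
      stacking = config$stacking,
      disparity = config$disparity,
      outcomes = config$outcomes,
      n_stays = if (config$mode == "simulate") config$dgp$n_stays else nrow(records),
      package_version = as.character(utils::packageVersion("septrial")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(out_dir = out_dir, records = records, cohort = cohort,
                 positivity = positivity, disparity = disparity,
                 ates = ates, negative_control = negctrl))
}
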