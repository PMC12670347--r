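#' Load a diagnosis-code to cancer-category mapping table
#'
#' Two-column delimited text (`code`, `category`) mapping diagnosis codes to
#' `solid`, `hematological` or `metastasized`. A small packaged toy mapping
#' (ICD-10-like oncology chapter codes) is used when no path is given; on
#' real data the user supplies their own table.
#'
#' @param path optional path to a delimited mapping file.
#' @return data.frame with columns `code`, `category`.
#' @export
load_code_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cancer_code_map.tsv", package = "septrial")
  }
  map <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("code", "category") %in% names(map))) {
    stop("code map must have columns `code` and `category`", call. = FALSE)
  }
  bad <- setdiff(unique(map$category),
                 c("solid", "hematological", "metastasized"))
  if (length(bad)) {
    stop("unknown cancer categories in code map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  map
}

# precedence: metastasized > hematological > solid > none
CANCER_PRECEDENCE <- c("metastasized", "hematological", "solid", "none")

#' Hierarchical cancer categorization from diagnosis codes
#'
#' A stay with several cancer diagnoses is categorised by the highest level
#' of the hierarchy present: any metastatic code makes it `metastasized`;
#' otherwise any hematologic code makes it `hematological`; otherwise any
#' solid-tumour code makes it `solid`; otherwise `none`. Codes absent from
#' the mapping are ignored (their count is attached as the
#' `"n_unmapped"` attribute), never fatal.
#'
#' @param diagnosis_codes character vector of `";"`-separated code strings
#'   (one element per stay), or a list of character vectors.
#' @param code_map mapping table from [load_code_map()].
#' @return factor with levels none/solid/hematological/metastasized and an
#'   `n_unmapped` attribute.
#' @export
#' @examples
#' categorize_cancer(c("C91;C78", "C18", "I10"), load_code_map())
categorize_cancer <- function(diagnosis_codes, code_map = load_code_map()) {
  if (!is.list(diagnosis_codes)) {
    diagnosis_codes <- strsplit(as.character(diagnosis_codes), ";", fixed = TRUE)
  }
  lut <- stats::setNames(code_map$category, code_map$code)
  n_unmapped <- 0L
  out <- vapply(diagnosis_codes, function(codes) {
    codes <- trimws(codes[nzchar(trimws(codes))])
    cats <- lut[codes]
    n_unmapped <<- n_unmapped + sum(is.na(cats))
    cats <- cats[!is.na(cats)]
    for (lev in CANCER_PRECEDENCE[1:3]) if (lev %in% cats) return(lev)
    "none"
  }, character(1))
  out <- factor(out, levels = rev(CANCER_PRECEDENCE))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Apply the target-trial inclusion and exclusion criteria
#'
#' Filters stay records to the analysis population, in a fixed order so the
#' exclusion log is deterministic: (1) age over 18; (2) sepsis flag present;
#' (3) first ICU stay; (4) discharge location documented; (5) length of
#' stay at least one day. The age criterion is strict (`age > 18`).
#'
#' @param records `stay_records` (or any data.frame with columns `age`,
#'   `sepsis3`, `stay_index`, `discharge_location`, `los_days`).
#' @return list with `records` (retained rows) and `log`, an
#'   `exclusion_log`: ordered counts removed per criterion.
#' @export
apply_inclusion <- function(records) {
  required <- c("age", "sepsis3", "stay_index", "discharge_location",
                "los_days")
  miss_col <- setdiff(required, names(records))
  if (length(miss_col)) {
    stop("records lack required field(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  }
  # discharge_location may legitimately be missing (it is a criterion);
  # the other fields must be present per record
  hard <- c("age", "sepsis3", "stay_index", "los_days")
  bad <- rowSums(is.na(records[hard])) > 0
  if (any(bad)) {
    ids <- if ("stay_id" %in% names(records)) {
      records$stay_id[bad]
    } else {
      which(bad)
    }
    stop("missing required field values for stay(s): ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }

  n_in <- nrow(records)
  criteria <- list(
    `under-18` = function(r) r$age > 18,
    `no sepsis flag` = function(r) r$sepsis3,
    `not first stay` = function(r) r$stay_index == 1L,
    `missing discharge location` = function(r) !is.na(r$discharge_location),
    `LOS < 1 day` = function(r) r$los_days >= 1
  )
  removed <- integer(length(criteria))
  names(removed) <- names(criteria)
  for (k in seq_along(criteria)) {
    keep <- criteria[[k]](records)
    removed[k] <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  log <- structure(removed, n_input = n_in, n_output = nrow(records),
                   class = "exclusion_log")
  list(records = records, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("<exclusion_log> %d stays in, %d retained\n",
              attr(x, "n_input"), attr(x, "n_output")))
  for (k in seq_along(x)) cat(sprintf("  removed %-28s %d\n", names(x)[k], x[k]))
  invisible(x)
}

#' Assign treatment within the eligibility window
#'
#' A stay is in the treated arm iff the treatment was started within the
#' first `window_hours` of ICU admission (boundary inclusive). Stays with
#' later initiation, or never treated, are retained in the control arm —
#' no record is ever dropped here, which is what guards against immortal
#' time bias.
#'
#' @param records stay records with a `<treatment_name>_start_hour` column.
#' @param treatment_name treatment whose start hours to use.
#' @param window_hours eligibility window in hours (default 24).
#' @return integer 0/1 vector, one element per record.
#' @export
assign_treatment <- function(records, treatment_name, window_hours = 24) {
  col <- paste0(treatment_name, "_start_hour")
  if (!col %in% names(records)) {
    stop("records lack column `", col, "`", call. = FALSE)
  }
  h <- records[[col]]
  neg <- !is.na(h) & h < 0
  if (any(neg)) {
    ids <- if ("stay_id" %in% names(records)) records$stay_id[neg] else which(neg)
    stop("negative treatment start hour for stay(s): ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  as.integer(!is.na(h) & h <= window_hours)
}

#' Aggregate time-stamped covariate values over the first 24 hours
#'
#' Values recorded before ICU admission (negative offsets) or after the
#' 24 h window are discarded; the remainder are reduced per variable with
#' the schema's aggregation tag (`max`, `min`, `mean`, or `static` = first
#' in-window value). Variables with no in-window value come back `NA`
#' (imputation happens at cohort assembly).
#'
#' @param timed_values data.frame with columns `variable`, `offset_hour`,
#'   `value`.
#' @param schema named character vector mapping variable name to tag.
#' @param window_hours upper edge of the aggregation window.
#' @return named numeric vector, one element per schema variable.
#' @export
#' @examples
#' tv <- data.frame(variable = "lactate_max",
#'                  offset_hour = c(-2, 3, 10), value = c(5, 7, 9))
#' aggregate_covariates(tv, c(lactate_max = "max"))
aggregate_covariates <- function(timed_values, schema, window_hours = 24) {
  bad <- setdiff(unique(schema), c("max", "min", "mean", "static"))
  if (length(bad)) {
    stop("unknown aggregation tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  inwin <- timed_values$offset_hour >= 0 & timed_values$offset_hour <= window_hours
  tv <- timed_values[inwin, , drop = FALSE]
  out <- vapply(names(schema), function(v) {
    rows <- tv[tv$variable == v, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    switch(schema[[v]],
      max = max(rows$value),
      min = min(rows$value),
      mean = mean(rows$value),
      static = rows$value[order(rows$offset_hour)][1])
  }, numeric(1))
  out
}

#' Derive the trial outcomes from raw disposition fields
#'
#' Composite in-hospital mortality is death in hospital *or* discharge to
#' hospice. Hospital-free days are 0 for composite-mortality stays and
#' `max(0, cap_days - ceiling(los_days))` otherwise. The negative-control
#' outcome is 1 when the death/discharge event falls on an even hour.
#'
#' @param records data.frame with `died_in_hospital`,
#'   `discharged_to_hospice`, `los_days`, `event_hour_of_day`.
#' @param cap_days hospital-free-day horizon (default 28).
#' @return data.frame with columns `Y_mortality`, `Y_hfd`, `Y_parity`.
#' @export
derive_outcomes <- function(records, cap_days = 28) {
  y <- as.integer(records$died_in_hospital | records$discharged_to_hospice)
  hfd <- ifelse(y == 1L, 0L,
                pmax(0L, cap_days - as.integer(ceiling(records$los_days))))
  parity <- as.integer(records$event_hour_of_day %% 2 == 0)
  data.frame(Y_mortality = y, Y_hfd = as.integer(hfd), Y_parity = parity)
}

#' Predicted mortality probability from a severity score
#'
#' Logistic calibration `expit(intercept + slope * score)`, the common
#' ground truth replacing database-specific severity-score prediction
#' formulas (OASIS, APACHE). The calibration must be supplied explicitly —
#' there is no defensible universal default.
#'
#' @param severity_score integer severity points.
#' @param calibration numeric `c(intercept, slope)` on the log-odds scale.
#' @return probabilities strictly inside (0, 1).
#' @export
compute_pmp <- function(severity_score, calibration) {
  if (missing(calibration) || is.null(calibration) || length(calibration) != 2L ||
      any(!is.finite(calibration))) {
    stop("configuration error: PMP calibration (intercept, slope) must be supplied",
         call. = FALSE)
  }
  expit(calibration[[1]] + calibration[[2]] * severity_score)
}

#' Assign severity strata from predicted mortality probabilities
#'
#' Tertile mode splits at the empirical 1/3 and 2/3 quantiles into
#' low/moderate/high severity; bands mode uses half-open intervals
#' `[e_i, e_{i+1})` labelled as percentage ranges. Estimation downstream
#' always adds a full-range `"0%-100%"` stratum on top of these labels.
#'
#' @param pmp probabilities in (0, 1).
#' @param mode `"tertile"` or `"bands"`.
#' @param band_edges increasing numeric edges for bands mode, e.g.
#'   `c(0, 0.10, 0.20, 1)`.
#' @return factor of stratum labels, same length as `pmp`.
#' @export
assign_strata <- function(pmp, mode = c("tertile", "bands"), band_edges = NULL) {
  mode <- match.arg(mode)
  if (mode == "tertile") {
    q <- stats::quantile(pmp, c(1/3, 2/3), names = FALSE)
    if (q[1] >= q[2] || q[1] <= min(pmp) || q[2] >= max(pmp)) {
      if (length(unique(pmp)) == 1L) {
        warning("all PMP values identical; single severity stratum",
                call. = FALSE)
        return(factor(rep("low", length(pmp)),
                      levels = c("low", "moderate", "high")))
      }
    }
    cut(pmp, breaks = c(-Inf, q, Inf),
        labels = c("low", "moderate", "high"), right = FALSE)
  } else {
    if (is.null(band_edges) || is.unsorted(band_edges, strictly = TRUE)) {
      stop("configuration error: band_edges must be strictly increasing",
           call. = FALSE)
    }
    labels <- paste0(formatC(100 * utils::head(band_edges, -1), format = "fg"),
                     "%-", formatC(100 * utils::tail(band_edges, -1),
                                   format = "fg"), "%")
    idx <- findInterval(pmp, band_edges, rightmost.closed = TRUE,
                        left.open = FALSE)
    if (any(idx < 1L | idx > length(labels))) {
      stop("PMP values outside the band edges", call. = FALSE)
    }
    factor(labels[idx], levels = labels)
  }
}

#' Assemble the analysis-ready trial cohort
#'
#' Runs the full target-trial construction on stay records: inclusion
#' filters, per-treatment 24 h window assignment, hierarchical cancer
#' categorization from diagnosis codes, outcome derivation, PMP computation
#' and severity stratification, plus covariate assembly with median
#' imputation and per-variable missingness indicators (so no row is lost to
#' missing covariates and the learners can exploit missingness).
#'
#' @param records `stay_records` (simulated or read from file).
#' @param calibration PMP calibration, numeric `c(intercept, slope)`.
#' @param treatments treatment names; default: the records' treatment
#'   attribute.
#' @param covariates covariate column names; default: the records'
#'   covariate attribute.
#' @param window_hours treatment-assignment window (default 24).
#' @param code_map cancer code mapping (default: packaged toy map).
#' @param strata_mode,band_edges see [assign_strata()].
#' @param cap_days hospital-free-day horizon.
#' @return a `trial_cohort` data.frame with the covariate matrix columns,
#'   one `A_<treatment>` indicator per treatment, outcomes `Y_mortality`,
#'   `Y_hfd`, `Y_parity`, `cancer_category`, `pmp` and `severity_stratum`;
#'   the exclusion log is attached as attribute `exclusion_log`.
#' @export
build_cohort <- function(records, calibration,
                         treatments = attr(records, "treatments"),
                         covariates = attr(records, "covariates"),
                         window_hours = 24,
                         code_map = load_code_map(),
                         strata_mode = "tertile", band_edges = NULL,
                         cap_days = 28) {
  if (is.null(treatments) || is.null(covariates)) {
    stop("treatments and covariates must be supplied (or carried as attributes)",
         call. = FALSE)
  }
  inc <- apply_inclusion(records)
  rec <- inc$records

  X <- as.data.frame(rec[, covariates, drop = FALSE])
  for (v in covariates) {
    if (anyNA(X[[v]])) {
      X[[paste0(v, "_missing")]] <- as.integer(is.na(X[[v]]))
      X[[v]][is.na(X[[v]])] <- stats::median(X[[v]], na.rm = TRUE)
    }
  }

  out <- data.frame(stay_id = rec$stay_id, X, check.names = FALSE)
  for (t in treatments) {
    out[[paste0("A_", t)]] <- assign_treatment(rec, t, window_hours)
  }
  out <- cbind(out, derive_outcomes(rec, cap_days = cap_days))
  out$cancer_category <- categorize_cancer(rec$diagnosis_codes, code_map)
  out$pmp <- compute_pmp(rec$severity_score, calibration)
  out$severity_stratum <- assign_strata(out$pmp, mode = strata_mode,
                                        band_edges = band_edges)
  if ("cancer_category_latent" %in% names(rec)) {
    out$cancer_category_latent <- rec$cancer_category_latent
  }
  # raw fields kept for the cohort summary table
  out$los_days <- rec$los_days
  if ("sex" %in% names(rec)) out$sex <- rec$sex

  attr(out, "covariates") <- setdiff(names(X), NULL)
  attr(out, "treatments") <- treatments
  attr(out, "exclusion_log") <- inc$log
  attr(out, "window_hours") <- window_hours
  attr(out, "calibration") <- calibration
  class(out) <- c("trial_cohort", "data.frame")
  out
}

#' @export
print.trial_cohort <- function(x, ...) {
  trts <- attr(x, "treatments")
  cat(sprintf("<trial_cohort> %d stays | treatments: %s | mortality %.1f%%\n",
              nrow(x), paste(trts, collapse = ", "),
              100 * mean(x$Y_mortality)))
  for (t in trts) {
    cat(sprintf("  %-14s treated %.1f%%\n", t,
                100 * mean(x[[paste0("A_", t)]])))
  }
  print(table(cancer = x$cancer_category, stratum = x$severity_stratum))
  invisible(x)
}

#' Numeric design matrix for nuisance estimation
#'
#' The cohort's covariate columns (including any missingness indicators)
#' plus, optionally, the cancer-category one-hot indicators.
#'
#' @param cohort a `trial_cohort`.
#' @param include_cancer include the cancer indicators (default `TRUE`).
#' @return numeric matrix, one row per stay.
#' @export
cohort_design <- function(cohort, include_cancer = TRUE) {
  X <- as.matrix(cohort[, attr(cohort, "covariates"), drop = FALSE])
  if (include_cancer) {
    X <- cbind(X, cancer_indicator_matrix(as.character(cohort$cancer_category)))
  }
  X
}
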