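#' @name tmle
#' @title Targeted maximum likelihood estimation of treatment effects
#'
#' @description
#' The ATE of a binary point exposure is estimated in the standard targeted
#' learning sequence: (1) an initial outcome regression fit by stacking;
#' (2) a stacked propensity score, truncated away from 0 and 1; (3) a
#' one-dimensional logistic fluctuation of the outcome fit along the
#' "clever covariate" (treatment indicator over propensity), which solves
#' the efficient-influence-curve score equation; (4) a plug-in contrast of
#' the targeted predictions; (5) Wald confidence intervals from the sample
#' variance of the efficient influence curve. Bounded continuous outcomes
#' (hospital-free days) are first mapped linearly to `[0, 1]` so the same
#' logistic fluctuation applies, then estimates are mapped back to days.
NULL

new_tmle_result <- function(estimand, estimate, se, stratum, n, g_range,
                            epsilon, score_residual, extra = list()) {
  res <- c(list(estimand = estimand, estimate = estimate, se = se,
                ci95 = c(lo = estimate - 1.96 * se,
                         hi = estimate + 1.96 * se),
                stratum = stratum, n = n, g_range = g_range,
                epsilon = epsilon, score_residual = score_residual),
           extra)
  class(res) <- "tmle_result"
  res
}

#' @export
print.tmle_result <- function(x, ...) {
  cat(sprintf("<tmle_result> %s = %.4f (se %.4f, 95%% CI %.4f to %.4f), n = %d\n",
              x$estimand, x$estimate, x$se, x$ci95[["lo"]], x$ci95[["hi"]],
              x$n))
  cat(sprintf("  propensity range after truncation: [%.3f, %.3f]; epsilon %.4g; score residual %.2g\n",
              x$g_range[1], x$g_range[2], x$epsilon, x$score_residual))
  invisible(x)
}

validate_tmle_inputs <- function(X, A, Y, min_n = 50L) {
  if (!all(A %in% c(0, 1))) stop("A must be binary 0/1", call. = FALSE)
  if (any(Y < -1e-12 | Y > 1 + 1e-12)) {
    stop("Y must lie in [0, 1]; rescale bounded outcomes with scale_bounded()",
         call. = FALSE)
  }
  n <- length(A)
  if (n < min_n) stop("need at least ", min_n, " observations", call. = FALSE)
  if (all(A == 1) || all(A == 0)) {
    stop("positivity violation: all observations in one treatment arm",
         call. = FALSE)
  }
  invisible(n)
}

# nuisance fits: initial outcome regression (on [A, X]) and propensity
fit_nuisances <- function(X, A, Y, loss_family, k, seed, learners,
                          g_hat = NULL, Q_init = NULL, g_bounds) {
  X <- as.matrix(X)
  seeds <- spawn_seeds(seed, 2L)
  if (is.null(Q_init)) {
    XA <- cbind(A = A, X)
    qfit <- fit_stack(XA, Y, loss_family = loss_family, k = k,
                      seed = seeds[1], learners = learners)
    Q0 <- predict(qfit, cbind(A = 0, X))
    Q1 <- predict(qfit, cbind(A = 1, X))
    QA <- ifelse(A == 1, Q1, Q0)
  } else {
    Q0 <- Q_init[, 1]
    Q1 <- Q_init[, 2]
    QA <- ifelse(A == 1, Q1, Q0)
    qfit <- NULL
  }
  if (is.null(g_hat)) {
    gfit <- fit_stack(X, A, loss_family = "binomial", k = k,
                      seed = seeds[2], learners = learners)
    g <- predict(gfit, X)
  } else {
    g <- rep_len(g_hat, length(A))
    gfit <- NULL
  }
  g <- pmin(pmax(g, g_bounds[1]), g_bounds[2])
  list(Q0 = clip_prob(Q0), Q1 = clip_prob(Q1), QA = clip_prob(QA), g = g,
       qfit = qfit, gfit = gfit)
}

fluctuate <- function(Y, H, offset_logit) {
  fit <- suppressWarnings(
    stats::glm(Y ~ -1 + H + offset(offset_logit),
               family = stats::quasibinomial())
  )
  eps <- unname(stats::coef(fit)[["H"]])
  if (!is.finite(eps)) eps <- 0
  eps
}

#' Estimate the average treatment effect by TMLE
#'
#' @param X covariate matrix (confounders only; not the treatment).
#' @param A binary treatment indicator.
#' @param Y outcome: binary, or continuous already scaled to `[0, 1]`
#'   (see [scale_bounded()]).
#' @param loss_family loss for the initial outcome regression:
#'   `"binomial"` for binary, `"gaussian"` admissible for scaled continuous
#'   outcomes.
#' @param g_bounds propensity truncation bounds (default `c(0.025, 0.975)`).
#' @param k cross-validation folds for the nuisance stacks.
#' @param seed integer seed controlling all nuisance randomness.
#' @param learners stacking library (see [fit_stack()]).
#' @param g_hat optional known/fixed propensity (scalar or vector); bypasses
#'   the propensity stack (useful for randomized designs and benchmarking).
#' @param Q_init optional n-by-2 matrix of initial outcome predictions
#'   `(Qbar(0,X), Qbar(1,X))`; bypasses the outcome stack.
#' @param stratum label attached to the result.
#' @return a `tmle_result` with the risk-difference estimate,
#'   influence-curve SE, 95% Wald CI, truncated propensity range, the
#'   fluctuation coefficient and the post-fluctuation score residual.
#' @export
estimate_ate <- function(X, A, Y, loss_family = c("binomial", "gaussian"),
                         g_bounds = c(0.025, 0.975), k = 5, seed = 1L,
                         learners = c("mean", "glm", "glmnet", "ranger", "gam"),
                         g_hat = NULL, Q_init = NULL, stratum = "0%-100%") {
  loss_family <- match.arg(loss_family)
  n <- validate_tmle_inputs(X, A, Y)
  nu <- fit_nuisances(X, A, Y, loss_family, k, seed, learners,
                      g_hat = g_hat, Q_init = Q_init, g_bounds = g_bounds)
  g <- nu$g
  H1 <- A / g
  H0 <- -(1 - A) / (1 - g)
  H <- H1 + H0
  eps <- fluctuate(Y, H, logit(nu$QA))
  Qs1 <- expit(logit(nu$Q1) + eps * (1 / g))
  Qs0 <- expit(logit(nu$Q0) + eps * (-1 / (1 - g)))
  QsA <- ifelse(A == 1, Qs1, Qs0)
  est <- mean(Qs1 - Qs0)
  ic <- H * (Y - QsA) + (Qs1 - Qs0) - est
  se <- stats::sd(ic) / sqrt(n)
  new_tmle_result("ATE", est, se, stratum, n, range(g), eps,
                  mean(H * (Y - QsA)),
                  extra = list(Qbar = cbind(Q0 = Qs0, Q1 = Qs1),
                               g = g, influence_curve = ic))
}

#' Counterfactual mean outcome under a fixed treatment level
#'
#' Targets `E[Y(a_target)]` (for `a_target = 0`, the "baseline" mean under
#' no treatment) with a single clever covariate
#' `1{A = a_target} / P(A = a_target | X)`.
#'
#' @inheritParams estimate_ate
#' @param a_target treatment level whose counterfactual mean is targeted.
#' @return a `tmle_result` with estimand `"counterfactual-mean"`.
#' @export
counterfactual_mean <- function(X, A, Y, a_target = 0,
                                loss_family = c("binomial", "gaussian"),
                                g_bounds = c(0.025, 0.975), k = 5, seed = 1L,
                                learners = c("mean", "glm", "glmnet", "ranger", "gam"),
                                g_hat = NULL, Q_init = NULL,
                                stratum = "0%-100%") {
  loss_family <- match.arg(loss_family)
  stopifnot(a_target %in% c(0, 1))
  n <- validate_tmle_inputs(X, A, Y)
  nu <- fit_nuisances(X, A, Y, loss_family, k, seed, learners,
                      g_hat = g_hat, Q_init = Q_init, g_bounds = g_bounds)
  g_a <- if (a_target == 1) nu$g else 1 - nu$g
  Qa <- if (a_target == 1) nu$Q1 else nu$Q0
  H <- as.numeric(A == a_target) / g_a
  eps <- fluctuate(Y, H, logit(nu$QA))
  Qsa <- expit(logit(Qa) + eps / g_a)
  QsA <- ifelse(A == a_target, Qsa,
                expit(logit(ifelse(a_target == 1, nu$Q0, nu$Q1))))
  est <- mean(Qsa)
  ic <- H * (Y - ifelse(A == a_target, Qsa, QsA)) + Qsa - est
  se <- stats::sd(ic) / sqrt(n)
  new_tmle_result("counterfactual-mean", est, se, stratum, n, range(nu$g),
                  eps, mean(H * (Y - ifelse(A == a_target, Qsa, QsA))),
                  extra = list(a_target = a_target))
}

#' Map a bounded outcome to the unit interval and back
#'
#' `scale_bounded()` applies `(y - lo) / (hi - lo)` (required before TMLE on
#' a bounded continuous outcome such as 28-day hospital-free days);
#' `unscale_effect()` maps an effect estimated on the unit scale back to the
#' outcome's natural units by multiplying with `hi - lo`.
#'
#' @param y numeric outcome values within `[lo, hi]`.
#' @param lo,hi outcome bounds (`lo < hi`).
#' @return `scale_bounded()`: values in `[0, 1]` with a `bounds` attribute;
#'   `unscale_effect()`: the rescaled effect.
#' @export
#' @examples
#' scale_bounded(c(0, 14, 28))
#' unscale_effect(0.1)  # 2.8 days
scale_bounded <- function(y, lo = 0, hi = 28) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  out_of_range <- which(y < lo | y > hi)
  if (length(out_of_range)) {
    stop("values outside [", lo, ", ", hi, "] at rows: ",
         paste(utils::head(out_of_range, 10), collapse = ", "),
         call. = FALSE)
  }
  structure((y - lo) / (hi - lo), bounds = c(lo = lo, hi = hi))
}

#' @rdname scale_bounded
#' @param effect effect estimate on the unit scale (difference scale, so the
#'   offset `lo` cancels).
#' @export
unscale_effect <- function(effect, lo = 0, hi = 28) effect * (hi - lo)

# every cancer-group x PMP-stratum cell requested from stratified_ates
strata_grid <- function(cohort) {
  cancer_groups <- c("all", "none", "solid", "hematological", "metastasized",
                     "any")
  present <- unique(as.character(cohort$cancer_category))
  cancer_groups <- cancer_groups[cancer_groups %in% c("all", "any", present)]
  pmp_strata <- c(levels(cohort$severity_stratum), "0%-100%")
  expand.grid(cancer_group = cancer_groups, pmp_stratum = pmp_strata,
              stringsAsFactors = FALSE)
}

cancer_group_rows <- function(cohort, group) {
  cc <- as.character(cohort$cancer_category)
  switch(group,
         all = rep(TRUE, nrow(cohort)),
         any = cc != "none",
         cc == group)
}

#' Stratified average treatment effects across the cohort
#'
#' One TMLE per treatment, cancer group and PMP stratum (including the
#' pooled "all"/"any" cancer groups and the full-range PMP stratum).
#' Strata failing the positivity check (an empty treatment arm) or too
#' small to estimate are reported as skip records with the reason — never
#' silently dropped. Hospital-free days are estimated on the unit scale
#' and reported back in days.
#'
#' @param cohort a `trial_cohort` from [build_cohort()].
#' @param treatments treatment names (default: cohort attribute).
#' @param outcome `"mortality"`, `"hfd"` or `"parity"`.
#' @param min_n smallest stratum size estimated (default 50).
#' @param ... passed to [estimate_ate()] (`learners`, `k`, `g_bounds`, ...).
#' @param seed integer seed.
#' @return data.frame of class `ate_table` with columns treatment,
#'   cancer_category, stratum, n, estimate, se, ci_lo, ci_hi, estimand,
#'   skipped_reason.
#' @export
stratified_ates <- function(cohort, treatments = attr(cohort, "treatments"),
                            outcome = c("mortality", "hfd", "parity"),
                            min_n = 50L, seed = 1L, ...) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, mortality = "Y_mortality", hfd = "Y_hfd",
                 parity = "Y_parity")
  Xall <- cohort_design(cohort)
  grid <- strata_grid(cohort)
  seeds <- spawn_seeds(seed, length(treatments) * nrow(grid))
  rows <- list()
  si <- 0L
  for (t in treatments) {
    Acol <- paste0("A_", t)
    for (gidx in seq_len(nrow(grid))) {
      si <- si + 1L
      cg <- grid$cancer_group[gidx]
      ps <- grid$pmp_stratum[gidx]
      idx <- cancer_group_rows(cohort, cg) &
        (ps == "0%-100%" | as.character(cohort$severity_stratum) == ps)
      n_str <- sum(idx)
      A <- cohort[[Acol]][idx]
      row <- data.frame(treatment = t, cancer_category = cg, stratum = ps,
                        n = n_str, estimate = NA_real_, se = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        estimand = paste0("ATE_", outcome),
                        skipped_reason = NA_character_,
                        stringsAsFactors = FALSE)
      if (n_str < min_n) {
        row$skipped_reason <- sprintf("stratum too small (n = %d)", n_str)
      } else if (sum(A == 1) == 0 || sum(A == 0) == 0) {
        row$skipped_reason <- "positivity: one treatment arm empty"
      } else {
        Y <- cohort[[ycol]][idx]
        if (outcome == "hfd") Y <- scale_bounded(Y, 0, 28)
        # squared-error nuisance loss for the bounded continuous outcome
        lf <- if (outcome == "hfd") "gaussian" else "binomial"
        fit <- try(estimate_ate(Xall[idx, , drop = FALSE], A, as.numeric(Y),
                                loss_family = lf, seed = seeds[si],
                                stratum = ps, ...),
                   silent = TRUE)
        if (inherits(fit, "try-error")) {
          row$skipped_reason <- paste("estimation error:",
                                      trimws(attr(fit, "condition")$message %||%
                                               as.character(fit)))
        } else {
          mult <- if (outcome == "hfd") 28 else 1
          row$estimate <- fit$estimate * mult
          row$se <- fit$se * mult
          row$ci_lo <- fit$ci95[["lo"]] * mult
          row$ci_hi <- fit$ci95[["hi"]] * mult
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ate_table", "data.frame")
  out
}
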