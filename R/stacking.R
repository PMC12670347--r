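#' @name stacking
#' @title Cross-validated stacking (super learner)
#'
#' @description
#' All nuisance models (outcome regressions and propensity scores) are fit
#' with a cross-validated stacking meta-estimator over a small library of
#' heterogeneous learners: a constant-mean predictor, a generalized linear
#' model, an elastic-net-penalized GLM, a random forest, and an adaptive
#' regression-splines learner. Out-of-fold predictions from each learner are
#' combined with convex (simplex) weights chosen to minimise cross-validated
#' risk, so the ensemble's CV risk can never exceed the best single
#' learner's.
NULL

# risk under the two supported loss families
stack_risk <- function(pred, y, loss_family) {
  if (loss_family == "binomial") {
    p <- clip_prob(pred)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((y - pred)^2)
  }
}

# learner registry: each entry is fit(X, y, loss_family) -> model and
# predict(model, X) -> numeric vector
learner_registry <- function() {
  glm_family <- function(loss_family) {
    if (loss_family == "binomial") stats::quasibinomial() else stats::gaussian()
  }
  list(
    mean = list(
      fit = function(X, y, loss_family) list(mu = mean(y)),
      predict = function(model, X) rep(model$mu, nrow(X))
    ),
    glm = list(
      fit = function(X, y, loss_family) {
        df <- data.frame(.y = y, X, check.names = TRUE)
        stats::glm(.y ~ ., data = df, family = glm_family(loss_family))
      },
      predict = function(model, X) {
        df <- data.frame(X, check.names = TRUE)
        as.numeric(stats::predict(model, newdata = df, type = "response"))
      }
    ),
    glmnet = list(
      fit = function(X, y, loss_family) {
        Xm <- as.matrix(X)
        if (ncol(Xm) < 2L) Xm <- cbind(Xm, `..dup` = Xm[, 1])
        fam <- if (loss_family == "binomial") "binomial" else "gaussian"
        fit <- glmnet::cv.glmnet(Xm, y, family = fam, alpha = 1, nfolds = 5)
        list(fit = fit, dup = ncol(as.matrix(X)) < 2L)
      },
      predict = function(model, X) {
        Xm <- as.matrix(X)
        if (model$dup) Xm <- cbind(Xm, `..dup` = Xm[, 1])
        as.numeric(stats::predict(model$fit, newx = Xm, s = "lambda.min",
                                  type = "response"))
      }
    ),
    ranger = list(
      fit = function(X, y, loss_family) {
        df <- data.frame(X, check.names = TRUE)
        if (loss_family == "binomial") {
          df$.y <- factor(y, levels = c(0, 1))
          ranger::ranger(.y ~ ., data = df, num.trees = 500,
                         probability = TRUE, num.threads = 1,
                         seed = sample.int(1e8, 1))
        } else {
          df$.y <- y
          ranger::ranger(.y ~ ., data = df, num.trees = 500,
                         num.threads = 1, seed = sample.int(1e8, 1))
        }
      },
      predict = function(model, X) {
        df <- data.frame(X, check.names = TRUE)
        p <- stats::predict(model, data = df, num.threads = 1)$predictions
        if (is.matrix(p)) as.numeric(p[, "1"]) else as.numeric(p)
      }
    ),
    gam = list(
      fit = function(X, y, loss_family) {
        df <- data.frame(.y = y, X, check.names = TRUE)
        terms <- vapply(setdiff(names(df), ".y"), function(v) {
          nu <- length(unique(df[[v]]))
          if (nu >= 10) {
            sprintf("s(%s, k = %d)", v, min(10L, nu - 1L))
          } else {
            v
          }
        }, character(1))
        f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
        fam <- if (loss_family == "binomial") stats::quasibinomial() else stats::gaussian()
        mgcv::gam(f, data = df, family = fam, method = "REML")
      },
      predict = function(model, X) {
        df <- data.frame(X, check.names = TRUE)
        as.numeric(stats::predict(model, newdata = df, type = "response"))
      }
    )
  )
}

# outcome-stratified folds (binomial) with global size balance <= 1
make_folds <- function(y, k, loss_family) {
  n <- length(y)
  ord <- if (loss_family == "binomial") {
    c(sample(which(y == 1)), sample(which(y == 0)))
  } else {
    sample.int(n)
  }
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

# convex minimisation of CV risk over the weight simplex; the candidate set
# always contains every vertex, so the minimiser is never worse than the
# best single learner
solve_simplex_weights <- function(Z, y, loss_family) {
  L <- ncol(Z)
  if (L == 1L) return(1)
  risk_of <- function(w) stack_risk(as.numeric(Z %*% w), y, loss_family)
  obj <- function(alpha) {
    s <- sum(alpha)
    if (s <= 0) return(stack_risk(rowMeans(Z), y, loss_family) + 1e6)
    risk_of(alpha / s)
  }
  vertices <- lapply(seq_len(L), function(j) replace(numeric(L), j, 1))
  vrisk <- vapply(vertices, risk_of, numeric(1))
  starts <- list(rep(1 / L, L), vertices[[which.min(vrisk)]] + 1e-4)
  cands <- vertices
  for (s0 in starts) {
    opt <- try(stats::optim(s0, obj, method = "L-BFGS-B",
                            lower = rep(0, L), upper = rep(10, L),
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(opt, "try-error") && sum(opt$par) > 0) {
      cands[[length(cands) + 1L]] <- opt$par / sum(opt$par)
    }
  }
  crisk <- vapply(cands, risk_of, numeric(1))
  w <- cands[[which.min(crisk)]]
  w / sum(w)
}

#' Fit a cross-validated stacking ensemble
#'
#' Builds the out-of-fold prediction matrix by training every learner on
#' k-1 folds and predicting the held-out fold, finds convex weights
#' minimising the cross-validated risk of the weighted ensemble, and refits
#' every learner on the full data for prediction. Folds are stratified by
#' outcome under binomial loss. A learner that fails to fit on any fold is
#' dropped with weight 0 and a warning; the stack never aborts because of a
#' single learner.
#'
#' @param X covariate matrix or data.frame (numeric columns).
#' @param y response; 0/1 when `loss_family = "binomial"`.
#' @param loss_family `"binomial"` (log-likelihood loss) or `"gaussian"`
#'   (squared error).
#' @param k number of cross-validation folds (default 5).
#' @param seed integer seed; the fit is deterministic given it.
#' @param learners character subset of
#'   `c("mean", "glm", "glmnet", "ranger", "gam")`.
#' @param folds optional integer vector in `1..k` fixing the fold map
#'   (overrides the seed-derived stratified assignment).
#' @return object of class `stack_fit`: weights, per-learner and ensemble
#'   CV risks, fold map, and the refit learners.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
#' y <- rbinom(200, 1, plogis(X[, 1]))
#' fit <- fit_stack(X, y, "binomial", seed = 7, learners = c("mean", "glm"))
#' fit$weights
fit_stack <- function(X, y, loss_family = c("binomial", "gaussian"), k = 5,
                      seed = 1L,
                      learners = c("mean", "glm", "glmnet", "ranger", "gam"),
                      folds = NULL) {
  loss_family <- match.arg(loss_family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (loss_family == "binomial" && !all(y %in% c(0, 1))) {
    stop("y must be 0/1 under binomial loss", call. = FALSE)
  }
  # constant columns carry no information and break several learners
  v <- apply(X, 2, stats::var)
  keep_cols <- !(is.finite(v) & v == 0)
  if (!any(keep_cols)) keep_cols[1] <- TRUE
  Xk <- X[, keep_cols, drop = FALSE]

  registry <- learner_registry()
  unknown <- setdiff(learners, names(registry))
  if (length(unknown)) {
    stop("unknown learner(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lnames <- make.unique(learners)

  with_seed(seed, {
    n <- nrow(Xk)
    if (is.null(folds)) {
      folds <- make_folds(y, k, loss_family)
    } else {
      stopifnot(length(folds) == n, all(folds %in% seq_len(k)))
    }
    Z <- matrix(NA_real_, n, length(lnames), dimnames = list(NULL, lnames))
    fitted <- vector("list", length(lnames))
    names(fitted) <- lnames
    failed <- logical(length(lnames))

    for (j in seq_along(lnames)) {
      lrn <- registry[[learners[j]]]
      ok <- TRUE
      for (f in seq_len(k)) {
        tr <- folds != f
        m <- try(lrn$fit(Xk[tr, , drop = FALSE], y[tr], loss_family),
                 silent = TRUE)
        p <- if (inherits(m, "try-error")) m else {
          try(lrn$predict(m, Xk[!tr, , drop = FALSE]), silent = TRUE)
        }
        if (inherits(p, "try-error") || anyNA(p) || !all(is.finite(p))) {
          ok <- FALSE
          break
        }
        Z[!tr, j] <- p
      }
      if (ok) {
        m <- try(lrn$fit(Xk, y, loss_family), silent = TRUE)
        if (inherits(m, "try-error")) ok <- FALSE else fitted[[j]] <- m
      }
      if (!ok) {
        failed[j] <- TRUE
        warning("learner `", lnames[j], "` failed to fit; dropped with weight 0",
                call. = FALSE)
      }
    }

    if (all(failed)) stop("every learner failed to fit", call. = FALSE)
    Zok <- Z[, !failed, drop = FALSE]
    if (loss_family == "binomial") Zok <- apply(Zok, 2, clip_prob)
    cv_risks <- rep(NA_real_, length(lnames))
    names(cv_risks) <- lnames
    cv_risks[!failed] <- apply(Zok, 2, stack_risk, y = y,
                               loss_family = loss_family)

    w_ok <- solve_simplex_weights(Zok, y, loss_family)
    weights <- numeric(length(lnames))
    names(weights) <- lnames
    weights[!failed] <- w_ok

    fit <- list(
      learner_names = lnames,
      base_learners = learners,
      weights = weights,
      cv_risks = cv_risks,
      ensemble_cv_risk = stack_risk(as.numeric(Zok %*% w_ok), y, loss_family),
      fold_map = folds,
      loss_family = loss_family,
      fitted_learners = fitted,
      failed = failed,
      feature_names = colnames(Xk),
      all_features = colnames(X),
      oof_matrix = Z,
      seed = seed
    )
    class(fit) <- "stack_fit"
    fit
  })
}

#' Predict from a fitted stacking ensemble
#'
#' Weighted combination of the refit learners' predictions; under binomial
#' loss, predictions are clipped to `(1e-6, 1 - 1e-6)`.
#'
#' @param object a `stack_fit`.
#' @param X_new matrix or data.frame containing (at least) the training
#'   feature columns.
#' @param ... unused.
#' @return numeric predictions, one per row of `X_new`.
#' @export
predict.stack_fit <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new))) colnames(X_new) <- object$all_features
  missing_cols <- setdiff(object$feature_names, colnames(X_new))
  if (length(missing_cols)) {
    stop("X_new lacks training feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  Xk <- X_new[, object$feature_names, drop = FALSE]
  storage.mode(Xk) <- "double"
  registry <- learner_registry()
  active <- which(!object$failed & object$weights > 0)
  if (!length(active)) active <- which(!object$failed)[1]
  Z <- sapply(active, function(j) {
    lrn <- registry[[object$base_learners[j]]]
    lrn$predict(object$fitted_learners[[j]], Xk)
  })
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = nrow(Xk))
  w <- object$weights[active]
  if (sum(w) == 0) w <- rep(1 / length(active), length(active))
  pred <- as.numeric(Z %*% (w / sum(w)))
  if (object$loss_family == "binomial") pred <- clip_prob(pred) else pred
}

#' @export
print.stack_fit <- function(x, ...) {
  cat(sprintf("<stack_fit> %s loss, %d folds\n", x$loss_family,
              max(x$fold_map)))
  tab <- data.frame(learner = x$learner_names,
                    weight = round(x$weights, 4),
                    cv_risk = round(x$cv_risks, 6),
                    dropped = x$failed)
  print(tab, row.names = FALSE)
  cat(sprintf("ensemble CV risk: %.6f\n", x$ensemble_cv_risk))
  invisible(x)
}
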