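#' @keywords internal
expit <- function(x) stats::plogis(x)

#' @keywords internal
logit <- function(p) stats::qlogis(p)

# clip probabilities away from {0,1} so logit() and log-likelihoods stay finite
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched. All exported stochastic functions route
# their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds from one master seed (keeps every seed < 2^31)
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Format a proportion as a percentage string with one decimal
#'
#' Counts printed in cohort summary tables are reported as `n (x.x%)`,
#' with the percentage rounded to one decimal place.
#'
#' @param x numerator count(s).
#' @param n denominator count(s).
#' @return character vector like `"1,864 (30.3%)"`.
#' @export
#' @examples
#' format_count(1864, 6145)
format_count <- function(x, n) {
  sprintf("%s (%s%%)", format(x, big.mark = ",", trim = TRUE),
          formatC(100 * x / n, format = "f", digits = 1))
}

#' Percentage of a count, rounded to one decimal
#'
#' @param x numerator count(s).
#' @param n denominator count(s).
#' @return numeric percentage(s) on the 0--100 scale, one decimal.
#' @export
#' @examples
#' percent_of(9520, 58988)  # 16.1
percent_of <- function(x, n) round(100 * x / n, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
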