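## Psychometric thresholding of the two-point discrimination (TPD) task: a
## binomial logistic regression of the "two points" response probability on
## pin distance; the 50% point of the fitted curve is the TPD threshold.
## "Uncertain" responses are pooled with "one point" by the task's button
## mapping, and single-pin (0 mm) trials enter as distance 0.

#' Fit the logistic psychometric function
#'
#' Maximum-likelihood binomial logistic regression of P(two points) on pin
#' distance. Perfect separation (all-or-nothing responses) cannot be fitted
#' at finite slope; such fits are flagged non-converged and the slope is
#' clamped at `clamp_slope`, refitting the intercept at the clamped slope.
#'
#' @param table behavioral data frame with columns `distance` (mm) and
#'   `response` (`"two_point"` / `"one_or_uncertain"`, or 0/1), one row per
#'   trial.
#' @param clamp_slope maximum admissible |slope| (1/mm).
#' @return object of class `psychometric_fit`: `intercept`, `slope`,
#'   `threshold` (mm), `converged`, `clamped`, `proportions` (per-distance
#'   observed rates), `deviance`, `null_deviance`.
#' @export
fit_psychometric <- function(table, clamp_slope = 25) {
  .assert(all(c("distance", "response") %in% names(table)),
          "table needs columns distance, response")
  y <- if (is.numeric(table$response)) as.integer(table$response > 0) else
    as.integer(table$response == "two_point")
  agg <- aggregate(y, by = list(distance = table$distance),
                   FUN = function(v) c(sum(v), length(v)))
  fit_psychometric_counts(agg$distance, agg$x[, 1], agg$x[, 2], clamp_slope)
}

#' Fit the psychometric function from per-distance counts
#'
#' @param distance distinct pin distances, mm.
#' @param n_two_point number (possibly fractional, for idealized proportions)
#'   of "two points" responses per distance.
#' @param n_trials trials per distance.
#' @param clamp_slope maximum admissible |slope|.
#' @return a `psychometric_fit`; see [fit_psychometric()].
#' @export
fit_psychometric_counts <- function(distance, n_two_point, n_trials,
                                    clamp_slope = 25) {
  .assert(length(unique(distance)) >= 2, "need at least 2 distinct distances")
  .assert(all(n_two_point >= 0 & n_two_point <= n_trials), "invalid counts")
  .assert(sum(n_two_point) > 0 || sum(n_trials - n_two_point) > 0,
          "empty data")
  resp <- cbind(n_two_point, n_trials - n_two_point)
  g <- suppressWarnings(glm(resp ~ distance, family = binomial()))
  b0 <- unname(coef(g)[1])
  b1 <- unname(coef(g)[2])
  separated <- sum(n_two_point) == 0 || sum(n_trials - n_two_point) == 0 ||
    !g$converged || !is.finite(b1) || abs(b1) > clamp_slope
  clamped <- FALSE
  if (separated) {
    ## refit the intercept at the clamped slope (sign from the data trend)
    s <- sign(suppressWarnings(cor(distance, n_two_point / n_trials)))
    if (!is.finite(s) || s == 0) s <- 1
    b1 <- s * clamp_slope
    g2 <- suppressWarnings(glm(resp ~ 1 + offset(b1 * distance),
                               family = binomial()))
    b0 <- unname(coef(g2)[1])
    clamped <- TRUE
  }
  fit <- structure(list(
    intercept = b0, slope = b1,
    threshold = if (b1 > 0) -b0 / b1 else NA_real_,
    converged = !separated, clamped = clamped,
    proportions = data.frame(distance = distance,
                             p_two_point = n_two_point / n_trials,
                             n = n_trials),
    deviance = g$deviance, null_deviance = g$null.deviance),
    class = "psychometric_fit")
  fit
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> threshold = %.3f mm, slope = %.3f /mm%s\n",
              x$threshold, x$slope,
              if (!x$converged) " (non-converged, clamped)" else ""))
  invisible(x)
}

#' 50% threshold of a psychometric fit
#'
#' The pin distance at which the fitted probability of "two points" is 0.5:
#' `-intercept / slope`. Undefined (flagged `NA`) for non-positive slopes.
#'
#' @param fit a `psychometric_fit`.
#' @return threshold in mm.
#' @export
threshold_50 <- function(fit) {
  .assert(inherits(fit, "psychometric_fit"), "need a psychometric_fit")
  if (!isTRUE(fit$slope > 0)) {
    warning("non-positive slope: 50% threshold undefined")
    return(NA_real_)
  }
  -fit$intercept / fit$slope
}
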