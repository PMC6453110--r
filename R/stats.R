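#' Bootstrap configuration
#'
#' @param n_samples Number of bootstrap resamples (default 20000). Values
#'   below 1000 trigger a warning: the BCa adjustment is unstable with few
#'   resamples.
#' @param confidence Confidence level (default 0.95).
#' @param seed Optional integer seed making interval endpoints reproducible
#'   bit-for-bit.
#' @param unit Resampling unit: `"observer"` (resample per-observer
#'   proportions; the reported means are across-observer means) or `"trial"`
#'   (resample pooled trials). The reporting unit is not fixed by the
#'   analysis description, so it is switchable; `"observer"` is the default.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_samples = 20000, confidence = 0.95,
                             seed = NULL, unit = c("observer", "trial")) {
  if (n_samples < 1000) {
    warning("n_samples = ", n_samples,
            " is below the stability floor of 1000 for BCa intervals")
  }
  stopifnot(confidence > 0, confidence < 1)
  structure(list(n_samples = as.integer(n_samples), confidence = confidence,
                 seed = seed, unit = match.arg(unit)),
            class = "bootstrap_config")
}

#' Logit transform with an extreme-proportion clamp
#'
#' Linearizes proportions as `log(y / (1 - y))`. Proportions of exactly 0 or
#' 1 cannot be transformed, so they are first moved inward by the constant
#' 1/48 — half of the maximum resolution achievable with 24 repetitions per
#' grouped condition (`0 -> 1/48`, `1 -> 1 - 1/48`). The clamp applies only
#' at exactly 0 and 1, never as a universal shrinkage.
#'
#' @param y Proportions in \[0, 1\].
#' @param clamp Clamp constant (default `1/48`).
#' @return Numeric vector of log-odds; `logit_transform(0.5)` is 0 and
#'   `logit_transform(1)` is `log(47)`.
#' @export
#' @examples
#' logit_transform(c(0, 0.5, 1))
logit_transform <- function(y, clamp = 1 / 48) {
  stopifnot(all(y >= 0 & y <= 1, na.rm = TRUE))
  y <- ifelse(y == 0, clamp, ifelse(y == 1, 1 - clamp, y))
  log(y / (1 - y))
}

#' BCa bootstrap confidence interval for a mean
#'
#' Bias-corrected and accelerated percentile interval for the mean of
#' `values` (typically per-observer proportions). Observations are resampled
#' with replacement `n_samples` times; the bias correction `z0` comes from
#' the fraction of bootstrap means below the observed mean and the
#' acceleration `a` from jackknife skewness. If the observed mean falls at an
#' extreme of the bootstrap distribution (degenerate `z0`), the interval
#' falls back to plain percentile bounds with a warning. All-identical input
#' returns a zero-width interval.
#'
#' @param values Numeric vector, length at least 2.
#' @param config A [bootstrap_config()].
#' @return Named numeric vector `c(ci_low, ci_high)` with attributes `z0`,
#'   `accel` and `method` (`"bca"`, `"percentile"` or `"degenerate"`).
#' @export
#' @examples
#' bca_ci(rbinom(22, 24, 0.7) / 24, bootstrap_config(seed = 1))
bca_ci <- function(values, config = bootstrap_config()) {
  stopifnot(length(values) >= 2, is.numeric(values), !anyNA(values))
  n <- length(values)
  obs <- mean(values)
  alpha <- (1 - config$confidence) / 2
  if (diff(range(values)) == 0) {
    out <- c(ci_low = obs, ci_high = obs)
    attr(out, "method") <- "degenerate"
    return(out)
  }
  draw <- function() {
    idx <- sample.int(n, n * config$n_samples, replace = TRUE)
    rowMeans(matrix(values[idx], config$n_samples, n))
  }
  boots <- if (is.null(config$seed)) draw() else
    withr::with_seed(config$seed, draw())

  prop_less <- mean(boots < obs)
  if (prop_less == 0 || prop_less == 1) {
    warning("observed mean at an extreme of the bootstrap distribution; ",
            "falling back to percentile bounds")
    q <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    out <- c(ci_low = q[1], ci_high = q[2])
    attr(out, "method") <- "percentile"
    return(out)
  }
  z0 <- qnorm(prop_less)
  jack <- (sum(values) - values) / (n - 1)  # leave-one-out means
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  q <- quantile(boots, adj, names = FALSE)
  out <- c(ci_low = q[1], ci_high = q[2])
  attr(out, "z0") <- z0
  attr(out, "accel") <- a
  attr(out, "method") <- "bca"
  out
}

#' Logit-additivity test of eccentricity biases
#'
#' Tests whether the bias in the 0|8 condition equals the sum of the 0|4 and
#' 4|8 biases on the log-odds scale. For each observer the logits of the 0|4
#' and 4|8 proportions are summed and compared to the logit of the 0|8
#' proportion; the group-level mean difference (predicted minus observed)
#' gets a BCa bootstrap CI. Under a logit-additive decision rule the CI
#' should cover 0.
#'
#' @param p_04,p_48,p_08 Per-observer proportions for the 0|4, 4|8 and 0|8
#'   grouped conditions, indexed by the same observers.
#' @param config A [bootstrap_config()].
#' @return A list of class `additivity_test`: per-observer `predicted_logit`,
#'   `observed_logit` and `difference`, the `mean_difference`, its `ci_low` /
#'   `ci_high`, and `covers_zero`.
#' @export
additivity_test <- function(p_04, p_48, p_08, config = bootstrap_config()) {
  stopifnot(length(p_04) == length(p_48), length(p_48) == length(p_08))
  predicted <- logit_transform(p_04) + logit_transform(p_48)
  observed <- logit_transform(p_08)
  difference <- predicted - observed
  ci <- bca_ci(difference, config)
  structure(
    list(predicted_logit = predicted, observed_logit = observed,
         difference = difference, mean_difference = mean(difference),
         ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         covers_zero = ci[1] <= 0 && 0 <= ci[2],
         n_observers = length(difference)),
    class = "additivity_test"
  )
}

#' @export
print.additivity_test <- function(x, ...) {
  cat("Logit-additivity test: (0|4) + (4|8) vs (0|8)\n")
  cat(sprintf("  mean difference %.4f logits, CI [%.4f, %.4f] (n = %d)\n",
              x$mean_difference, x$ci_low, x$ci_high, x$n_observers))
  cat("  additivity", if (x$covers_zero) "not rejected" else "rejected", "\n")
  invisible(x)
}

#' Linear trend over within-condition trial number
#'
#' Ordinary least-squares line through the across-observer mean proportion at
#' each within-condition trial number, to assess whether biases change over
#' the course of the experiment.
#'
#' @param series A data frame with the trial-number and mean-value columns
#'   (e.g. from [trial_series()]).
#' @param value,index Column names of the response and the trial number.
#' @return A list: `slope`, `intercept`, `slope_ci` (95%), and the `lm` fit.
#' @export
trend_regression <- function(series, value = "mean_value",
                             index = "trial_number") {
  stopifnot(all(c(value, index) %in% names(series)))
  df <- data.frame(y = series[[value]], x = series[[index]])
  fit <- lm(y ~ x, data = df)
  ci <- suppressWarnings(confint(fit))["x", ]
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       slope_ci = unname(ci),
       fit = fit)
}
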