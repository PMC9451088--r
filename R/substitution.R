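#' Define a time reallocation
#'
#' A reallocation is a set of signed per-part changes in minutes that must
#' net to zero, so the 24-hour total is preserved. Each part's change is
#' bounded by `cap` (60 min by default, configurable).
#'
#' @param deltas Named numeric vector of signed minutes; any subset of
#'   [activity_parts()] may be given, the rest default to 0.
#' @param cap Maximum absolute change allowed per part, minutes.
#' @return Object of class `reallocation` (named length-7 vector).
#' @export
reallocation <- function(deltas, cap = 60) {
  parts <- activity_parts()
  d <- stats::setNames(numeric(7L), parts)
  if (is.null(names(deltas))) {
    if (length(deltas) != 7L)
      stop("unnamed deltas must have length 7 in the canonical part order")
    d[] <- deltas
  } else {
    bad <- setdiff(names(deltas), parts)
    if (length(bad)) stop("unknown activity part(s): ", paste(bad, collapse = ", "))
    d[names(deltas)] <- deltas
  }
  if (abs(sum(d)) > 1e-9)
    stop("reallocation deltas must sum to zero (net change ",
         format(sum(d)), " min)")
  over <- abs(d) > cap
  if (any(over))
    stop("reallocation exceeds the ", cap, "-minute cap for: ",
         paste(parts[over], collapse = ", "))
  structure(d, cap = cap, class = c("reallocation", "numeric"))
}

#' Apply a reallocation to an initial composition
#'
#' @param initial A closed composition (sum 1440, or the model's total).
#' @param realloc A [reallocation()], or a named delta vector passed to it.
#' @param cap Cap forwarded to [reallocation()] when `realloc` is a plain
#'   vector.
#' @return The new closed [composition()].
#' @export
apply_reallocation <- function(initial, realloc, cap = 60) {
  init <- as_part_matrix(initial)[1L, ]
  total <- sum(init)
  if (!inherits(realloc, "reallocation")) realloc <- reallocation(realloc, cap = cap)
  new <- init + unclass(realloc)
  neg <- new < 0
  if (any(neg)) {
    part <- activity_parts()[which(neg)[1L]]
    stop("reallocation would result in a negative value for ", part,
         " (short by ", format(round(-new[part], 2)), " min); ",
         "change your selection")
  }
  composition(new, total = total)
}

#' Predict an outcome for a composition and covariate profile
#'
#' Computes ilr coordinates for the composition (after fixed-value zero
#' replacement), builds the polynomial design row and predicts from the
#' stored regression parameters: point estimate `x'beta`, standard error
#' `sqrt(x' V x)` and a t-based confidence interval on the model (link)
#' scale. For log-scale models the raw-scale estimate and limits are the
#' exponentials of the link-scale values.
#'
#' @param model A `fitted_model`.
#' @param comp Composition (zeros allowed; they are imputed at 3.25 min).
#' @param cov A [covariate_profile()].
#' @param alpha Two-sided error rate (default 0.05 for 95% intervals).
#' @return List of class `outcome_prediction`: `fit`, `se`, `df` on the
#'   link scale, plus raw-scale `estimate`, `ci_low`, `ci_high`.
#' @export
predict_outcome <- function(model, comp, cov, alpha = 0.05) {
  x <- prediction_row(model, comp, cov)
  fit <- drop(x %*% model$coef)
  se <- sqrt(max(0, drop(x %*% model$vcov %*% x)))
  tq <- stats::qt(1 - alpha / 2, df = model$residual_df)
  lo <- fit - tq * se
  hi <- fit + tq * se
  raw <- if (model$transform == "log") exp(c(fit, lo, hi)) else c(fit, lo, hi)
  structure(list(outcome_name = model$outcome_name, fit = fit, se = se,
                 df = model$residual_df, estimate = raw[1L],
                 ci_low = raw[2L], ci_high = raw[3L], alpha = alpha),
            class = "outcome_prediction")
}

prediction_row <- function(model, comp, cov) {
  if (length(model$coef) != N_DESIGN_COLS)
    stop("prediction requires a full polynomial model (35 coefficients)")
  comp <- replace_zeros_fixed(as_part_matrix(comp)[1L, ])
  z <- ilr(comp, sbp = model$sbp)
  build_design_row(z, cov)
}

#' Estimate the outcome difference between two compositions
#'
#' Dispatches to the linear-contrast construction
#' ([estimate_difference_linear()]) for identity-scale models and to the
#' MOVER lognormal construction ([estimate_difference_lognormal()]) for
#' log-scale models.
#'
#' @param model A `fitted_model`.
#' @param comp0 Initial composition.
#' @param comp1 New (reallocated) composition.
#' @param cov A [covariate_profile()].
#' @param alpha Two-sided error rate (default 0.05).
#' @return A `substitution_estimate`.
#' @export
estimate_difference <- function(model, comp0, comp1, cov, alpha = 0.05) {
  switch(model$transform,
         identity = estimate_difference_linear(model, comp0, comp1, cov, alpha),
         log = estimate_difference_lognormal(model, comp0, comp1, cov, alpha))
}

#' Linear-contrast difference for identity-scale outcomes
#'
#' The difference between the predictions at the new and initial
#' compositions is the linear combination `d = (x1 - x0)' beta` with
#' variance `(x1 - x0)' V (x1 - x0)`; the 95% CI is `d +/- t * sqrt(Var)`
#' with the model's residual degrees of freedom.
#'
#' @inheritParams estimate_difference
#' @return A `substitution_estimate`.
#' @export
estimate_difference_linear <- function(model, comp0, comp1, cov, alpha = 0.05) {
  if (model$transform != "identity")
    stop("model is log-scale; use estimate_difference_lognormal()")
  x0 <- prediction_row(model, comp0, cov)
  x1 <- prediction_row(model, comp1, cov)
  ct <- x1 - x0
  # computed as the difference of the two predictions so the linearity
  # identity holds to the last bit
  d <- drop(x1 %*% model$coef) - drop(x0 %*% model$coef)
  v <- max(0, drop(ct %*% model$vcov %*% ct))
  tq <- stats::qt(1 - alpha / 2, df = model$residual_df)
  p0 <- predict_outcome(model, comp0, cov, alpha)
  p1 <- predict_outcome(model, comp1, cov, alpha)
  new_substitution_estimate(model, p0, p1, d, d - tq * sqrt(v), d + tq * sqrt(v),
                            alpha)
}

#' MOVER confidence interval for a difference of two estimates
#'
#' Method-of-variance-estimates-recovery interval for `theta1 - theta2`
#' from the individual limits `(l1, u1)`, `(l2, u2)` and the correlation
#' `r` of the underlying estimators (Zou's construction):
#' `L = theta1 - theta2 - sqrt((theta1 - l1)^2 + (u2 - theta2)^2
#'      - 2 r (theta1 - l1)(u2 - theta2))` and symmetrically
#' `U = theta1 - theta2 + sqrt((u1 - theta1)^2 + (theta2 - l2)^2
#'      - 2 r (u1 - theta1)(theta2 - l2))`.
#'
#' @param theta1,l1,u1 Point estimate and confidence limits of the first
#'   quantity (here, the prediction at the new composition).
#' @param theta2,l2,u2 Same for the second quantity (initial composition).
#' @param r Correlation between the two estimators.
#' @return Numeric vector `c(low, high)`.
#' @export
mover_ci <- function(theta1, l1, u1, theta2, l2, u2, r = 0) {
  d <- theta1 - theta2
  low <- d - sqrt(max(0, (theta1 - l1)^2 + (u2 - theta2)^2 -
                        2 * r * (theta1 - l1) * (u2 - theta2)))
  high <- d + sqrt(max(0, (u1 - theta1)^2 + (theta2 - l2)^2 -
                         2 * r * (u1 - theta1) * (theta2 - l2)))
  c(low, high)
}

#' MOVER difference for log-scale outcomes
#'
#' For a log-transformed outcome the difference on the raw scale is
#' `exp(y1_hat) - exp(y0_hat)`; its 95% CI is built with [mover_ci()] from
#' the raw-scale limits of each prediction and the correlation of the two
#' link-scale predictions, `r = (x1' V x0) / (se1 se0)`, accounting for the
#' lognormal transformation and the covariance of the two estimates. When
#' the two compositions are identical the difference is exactly zero with a
#' zero-width interval.
#'
#' @inheritParams estimate_difference
#' @return A `substitution_estimate`.
#' @export
estimate_difference_lognormal <- function(model, comp0, comp1, cov, alpha = 0.05) {
  if (model$transform != "log")
    stop("model is identity-scale; use estimate_difference_linear()")
  x0 <- prediction_row(model, comp0, cov)
  x1 <- prediction_row(model, comp1, cov)
  p0 <- predict_outcome(model, comp0, cov, alpha)
  p1 <- predict_outcome(model, comp1, cov, alpha)
  if (max(abs(x1 - x0)) == 0)
    return(new_substitution_estimate(model, p0, p1, 0, 0, 0, alpha))
  r <- drop(x1 %*% model$vcov %*% x0) / (p1$se * p0$se)
  d <- p1$estimate - p0$estimate
  ci <- mover_ci(p1$estimate, p1$ci_low, p1$ci_high,
                 p0$estimate, p0$ci_low, p0$ci_high, r = r)
  new_substitution_estimate(model, p0, p1, d, ci[1L], ci[2L], alpha)
}

new_substitution_estimate <- function(model, p0, p1, d, lo, hi, alpha) {
  pct <- percent_of(d, p0$estimate)
  favourable <- if (d == 0) NA else
    (d < 0) == (model$direction == "lower")
  structure(list(
    outcome_name = model$outcome_name,
    transform = model$transform,
    estimate_initial = p0$estimate, ci_initial = c(p0$ci_low, p0$ci_high),
    estimate_new = p1$estimate, ci_new = c(p1$ci_low, p1$ci_high),
    difference = d, ci_low = lo, ci_high = hi,
    percent_difference = pct,
    favourable = favourable,
    alpha = alpha
  ), class = "substitution_estimate")
}

percent_of <- function(d, baseline) {
  if (!is.finite(baseline) || baseline == 0)
    stop("percent difference undefined: baseline estimate is zero")
  100 * d / baseline
}

#' Percentage difference of a substitution estimate
#'
#' 100 times the estimated difference divided by the raw-scale prediction
#' at the initial composition.
#'
#' @param est A `substitution_estimate`.
#' @return Percentage difference (signed).
#' @export
percent_difference <- function(est) {
  percent_of(est$difference, est$estimate_initial)
}

#' @export
print.substitution_estimate <- function(x, ...) {
  dir <- if (is.na(x$favourable)) "no change"
         else if (x$favourable) "favourable" else "unfavourable"
  cat(sprintf("%s: difference %+.3f [%.3f, %.3f] (%+.2f%%, %s)\n",
              x$outcome_name, x$difference, x$ci_low, x$ci_high,
              x$percent_difference, dir))
  invisible(x)
}
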