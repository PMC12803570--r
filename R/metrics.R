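#' Relative risk from arm-level counts
#'
#' Ratio of cumulative event proportions, active arm over placebo arm,
#' rounded half-up to \code{dp} decimals as in trial report tables.
#'
#' @param events_a,n_a active-arm event count and denominator.
#' @param events_b,n_b placebo-arm event count and denominator.
#' @param dp rounding digits (default 2); \code{NULL} for unrounded.
#' @return the relative risk, or \code{NA} (with a warning) when the placebo
#'   arm has no events.
#' @export
#' @examples
#' relative_risk(776, 7332, 778, 7339)   # 1.00
#' relative_risk(579, 7356, 593, 7396)   # 0.98
relative_risk <- function(events_a, n_a, events_b, n_b, dp = 2) {
  stopifnot(n_a > 0, n_b > 0, events_a <= n_a, events_b <= n_b,
            events_a >= 0, events_b >= 0)
  if (events_b == 0) {
    warning("placebo arm has zero events: relative risk undefined")
    return(NA_real_)
  }
  rr <- (events_a / n_a) / (events_b / n_b)
  if (is.null(dp)) rr else round_half_up(rr, dp)
}

#' Unadjusted Cox proportional-hazards ratio between arms
#'
#' Fits \code{survival::coxph} with Efron tie handling on the arm indicator
#' (active vs placebo) and returns the exponentiated coefficient with its
#' Wald 95\% confidence interval.
#'
#' @param observed data frame with columns \code{arm}
#'   (\code{active}/\code{placebo}), \code{time} (years) and \code{event}
#'   (0/1).
#' @return list: \code{hr}, \code{lower}, \code{upper}, \code{se_log_hr},
#'   \code{flagged} (TRUE when the fit is degenerate; the CI is then NA).
#' @export
cox_hr <- function(observed) {
  stopifnot(all(c("arm", "time", "event") %in% names(observed)))
  if (any(observed$time < 0)) .stopf("negative follow-up times")
  if (length(unique(observed$arm)) < 2)
    .stopf("both arms must be represented")
  if (sum(observed$event) < 1) .stopf("no events observed")
  active <- as.numeric(observed$arm == "active")
  fit <- survival::coxph(survival::Surv(observed$time, observed$event) ~ active,
                         ties = "efron")
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  flagged <- !is.finite(b) || !is.finite(se) || se > 100
  list(hr = exp(b),
       lower = if (flagged) NA_real_ else exp(b - 1.96 * se),
       upper = if (flagged) NA_real_ else exp(b + 1.96 * se),
       se_log_hr = se, flagged = flagged)
}

#' Kaplan-Meier cumulative incidence
#'
#' One minus the product-limit survival estimate: a right-continuous,
#' non-decreasing step function starting at 0.
#'
#' @param time follow-up times (years), non-negative.
#' @param event event indicators (0/1).
#' @return data frame with columns \code{time} and \code{incidence}
#'   (evaluated just after each distinct observed time), plus a
#'   \code{stepfun} attribute \code{fn} for interpolation.
#' @export
cumulative_incidence <- function(time, event) {
  if (!length(time)) .stopf("no observations")
  if (any(time < 0)) .stopf("negative follow-up times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  inc <- 1 - fit$surv
  out <- data.frame(time = fit$time, incidence = inc)
  attr(out, "fn") <- stats::stepfun(fit$time, c(0, inc), right = FALSE)
  out
}

#' Brier score
#'
#' Mean squared difference between predicted risk and binary outcome; 0 is
#' perfect accuracy, 1 perfect inaccuracy, and scores below 0.25 are
#' conventionally read as informative.
#'
#' @param pred predicted risks in [0, 1].
#' @param obs binary outcomes (0/1).
#' @return list: \code{score} and \code{informative}
#'   (\code{score < 0.25}).
#' @export
brier <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) > 0)
  s <- mean((pred - obs)^2)
  list(score = s, informative = s < 0.25)
}

#' Calibration intercept, slope and decile curve
#'
#' Ranks participants into \code{bins} groups of predicted risk and reports
#' mean predicted risk against observed proportion per group, together with
#' the two logistic recalibration parameters: the slope (coefficient of
#' logit(pred) in a logistic regression of the outcome on logit(pred)) and
#' the intercept (fitted with the slope fixed at 1, logit(pred) entering as
#' an offset).  Target values are slope 1 and intercept 0; a negative
#' intercept indicates overestimation, a positive one underestimation.
#' Predictions are clipped to [1e-6, 1 - 1e-6] before the logit.
#'
#' @param pred predicted risks in [0, 1].
#' @param obs binary outcomes (0/1).
#' @param bins number of risk groups (default 10).
#' @return object of class \code{calibration_result}: list with
#'   \code{deciles} (data frame \code{bin}, \code{mean_pred},
#'   \code{obs_prop}, \code{n}), \code{intercept}, \code{intercept_se},
#'   \code{slope}, \code{slope_se}, \code{flagged} (TRUE when the slope is
#'   unidentifiable, e.g. all predictions equal).
#' @export
calibration <- function(pred, obs, bins = 10) {
  stopifnot(length(pred) == length(obs), length(pred) > 0)
  p <- clamp(pred, 1e-6, 1 - 1e-6)
  lg <- stats::qlogis(p)
  grp <- cut(rank(p, ties.method = "first"),
             breaks = seq(0, length(p), length.out = bins + 1),
             labels = FALSE, include.lowest = TRUE)
  dec <- data.frame(
    bin = sort(unique(grp)),
    mean_pred = as.numeric(tapply(p, grp, mean)),
    obs_prop = as.numeric(tapply(obs, grp, mean)),
    n = as.numeric(table(grp)))
  flagged <- stats::var(lg) < 1e-12
  if (flagged) {
    slope <- NA_real_; slope_se <- NA_real_
  } else {
    fit_s <- stats::glm(obs ~ lg, family = stats::binomial())
    slope <- unname(stats::coef(fit_s)[2])
    slope_se <- sqrt(diag(stats::vcov(fit_s)))[2]
  }
  fit_i <- stats::glm(obs ~ 1 + offset(lg), family = stats::binomial())
  structure(list(deciles = dec,
                 intercept = unname(stats::coef(fit_i)[1]),
                 intercept_se = sqrt(stats::vcov(fit_i)[1, 1]),
                 slope = slope, slope_se = unname(slope_se),
                 flagged = flagged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: intercept %.3f (SE %.3f), slope %s\n",
              x$intercept, x$intercept_se,
              if (x$flagged) "undefined (constant predictions)"
              else sprintf("%.3f (SE %.3f)", x$slope, x$slope_se)))
  invisible(x)
}

#' Harrell's C-statistic under censoring
#'
#' Concordance over censoring-comparable pairs: a pair is comparable when
#' the shorter observed time belongs to a subject with the event (for tied
#' times, when exactly one of the two has the event).  A pair is concordant
#' when the event-first subject carries the higher risk estimate; risk ties
#' count 1/2.  1 is perfect discrimination, 0.5 coin-toss.
#'
#' @param risk per-subject risk estimates (higher = riskier).
#' @param time observed times.
#' @param event event indicators (0/1).
#' @return list: \code{c} (concordance), \code{pairs} (comparable pairs),
#'   \code{flagged} (TRUE and \code{c = NA} when no pair is comparable).
#' @export
harrell_c <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  conc <- 0
  npairs <- 0
  ev_idx <- which(event == 1)
  for (i in ev_idx) {
    later <- (time > time[i]) | (time == time[i] & event == 0)
    later[i] <- FALSE
    # avoid double counting tied-time event pairs: they are not comparable;
    # tied-time event/censored pairs counted once from the event side
    m <- sum(later)
    if (!m) next
    npairs <- npairs + m
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (npairs == 0)
    return(list(c = NA_real_, pairs = 0L, flagged = TRUE))
  list(c = conc / npairs, pairs = npairs, flagged = FALSE)
}

#' Fixed-horizon binary outcomes from censored follow-up
#'
#' Maps censored time-to-event records to the binary outcome "event by the
#' horizon": 1 when the event occurred at or before the horizon, 0 when
#' follow-up reached the horizon event-free.  Subjects censored early
#' without the event are excluded (\code{keep = FALSE}) since their horizon
#' status is unknown.
#'
#' @param time observed times.
#' @param event event indicators (0/1).
#' @param horizon horizon in years.
#' @return data frame: \code{obs} (0/1) and \code{keep} (logical mask).
#' @export
horizon_outcomes <- function(time, event, horizon) {
  had <- event == 1 & time <= horizon + 1e-9
  full <- time >= horizon - 1e-9
  keep <- had | full
  data.frame(obs = as.integer(had), keep = keep)
}
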