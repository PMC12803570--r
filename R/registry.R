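# Canonical field registry shared by the cohort, equation and engine layers.
# Covariate names in a coefficient file must resolve against these.

# Continuous annualized risk factors (units in the docs of read_cohort()).
.CONT_FACTORS <- c("weight", "hdl", "ldl", "sbp", "hba1c",
                   "heart_rate", "wbc", "haemoglobin", "egfr")

# Boolean annualized risk factors (0/1).
.BOOL_FACTORS <- c("smoker", "afib", "pad", "albuminuria")

# Time-invariant demographics. `age` and `diabetes_duration` advance by one
# year per simulated cycle; the others are fixed at baseline.
.DEMOGRAPHICS <- c("age", "male", "diabetes_duration", "height",
                   "race_afro", "race_indian", "race_other")

# Historical event categories known at baseline.
.PRIOR_EVENTS <- c("prior_ihd", "prior_hf", "prior_amputation",
                   "prior_blindness", "prior_kidney_failure",
                   "prior_mi", "prior_stroke", "prior_ulcer")

# Within-simulation first-event flags an equation may condition on.
.SIM_EVENT_FLAGS <- c("event_mi", "event_stroke", "event_ihd",
                      "event_hf", "event_ua")

.ALL_COVARIATES <- c(.CONT_FACTORS, .BOOL_FACTORS, .DEMOGRAPHICS,
                     .PRIOR_EVENTS, .SIM_EVENT_FLAGS)

#' Model-admissible ranges for the continuous risk factors
#'
#' Every continuous risk factor carries a prespecified admissible
#' \code{[min, max]} window plus a population-average fallback used when a
#' factor is missing for an entire study.  Observed values outside the window
#' are treated as missing and re-imputed rather than clamped; values produced
#' by progression equations are clamped into it.
#'
#' Defaults are conventional clinical plausibility windows (HbA1c 4--15\%,
#' systolic blood pressure 70--250 mmHg, eGFR 5--200 mL/min/1.73m2, ...);
#' each can be overridden via a JSON config with entries
#' \code{{"factor": {"min": ..., "max": ..., "population_mean": ...}}}.
#'
#' @param path optional JSON file overriding any subset of factors.
#' @return data.frame with columns \code{factor}, \code{min}, \code{max},
#'   \code{population_mean}, one row per continuous factor.
#' @export
default_factor_limits <- function(path = NULL) {
  lim <- data.frame(
    factor = .CONT_FACTORS,
    min = c(30,  0.3, 0.3,  70, 4,  30, 1,  5,   5),
    max = c(250, 4,   10, 250, 15, 200, 50, 25, 200),
    population_mean = c(85, 1.1, 2.5, 135, 7.5, 72, 7.5, 13.8, 75),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    ov <- jsonlite::read_json(path)
    for (f in names(ov)) {
      i <- match(f, lim$factor)
      if (is.na(i)) .stopf("unknown risk factor in limits config: '%s'", f)
      for (k in intersect(names(ov[[f]]), c("min", "max", "population_mean")))
        lim[[k]][i] <- as.numeric(ov[[f]][[k]])
    }
  }
  stopifnot(all(lim$min < lim$max))
  lim
}

.limits_row <- function(limits, factor) {
  i <- match(factor, limits$factor)
  if (is.na(i)) .stopf("risk factor '%s' absent from the limits table", factor)
  limits[i, ]
}

#' Default age bands for age- and sex-adjusted imputation strata
#'
#' Ten-year bands (<55, 55-64, 65-74, >=75).  The band edges are
#' configurable wherever they are consumed.
#' @return numeric vector of interior band edges.
#' @export
default_age_bands <- function() c(55, 65, 75)

.age_band <- function(age, edges = default_age_bands()) {
  findInterval(age, edges)  # 0..length(edges)
}
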