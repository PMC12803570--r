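#' Synthetic cardiovascular-outcome-trial cohort profile
#'
#' Bundles everything the generator needs: arm sizes, per-factor baseline
#' marginal distributions, a Gaussian-copula correlation among the
#' cardiometabolic factors, prior-event prevalences, per-factor missingness
#' rates (with optional missing-not-at-random dependence on the factor's own
#' value), and a follow-up length distribution for censoring.
#'
#' Two named profiles ship with the package, emulating the shape of the two
#' large sitagliptin and exenatide cardiovascular outcome trials:
#' \code{"tecos"} (14 671 participants, arms 7332/7339, every participant
#' with prior atherosclerotic cardiovascular disease, follow-up drawn
#' uniformly over 2.3--3.8 years so the median is near 3.0) and
#' \code{"exscel"} (14 752 participants, arms 7356/7396, 73.1\% with prior
#' ASCVD, follow-up uniform over 2.2--4.4 years, median near 3.2).  The
#' missing-not-at-random rates for HDL-cholesterol, LDL-cholesterol and
#' haemoglobin default to 19.8\%, 25.6\% and 39.7\%.  Baseline marginals are
#' illustrative plausible type 2 diabetes values; they are stand-ins, not
#' estimates of the real trial populations.
#'
#' @param name \code{"tecos"} or \code{"exscel"}.
#' @param n_active,n_placebo optional arm-size overrides.
#' @param missingness optional named vector overriding per-factor missing
#'   rates (in [0, 1]).
#' @param mnar_beta log-odds change in missingness per standard deviation of
#'   the factor's own value, for the MNAR factors (default -0.5: lower
#'   values more often missing); 0 gives missing completely at random.
#' @return object of class \code{cohort_profile}.
#' @export
cohort_profile <- function(name = c("tecos", "exscel"),
                           n_active = NULL, n_placebo = NULL,
                           missingness = NULL, mnar_beta = -0.5) {
  name <- match.arg(name)
  prof <- list(
    name = name,
    n_active = if (name == "tecos") 7332L else 7356L,
    n_placebo = if (name == "tecos") 7339L else 7396L,
    fu_range = if (name == "tecos") c(2.3, 3.8) else c(2.2, 4.4),
    median_fu = if (name == "tecos") 3.0 else 3.2,
    ascvd_prevalence = if (name == "tecos") 1.0 else 0.731,
    marginals = list(
      age = list(family = "normal", mean = if (name == "tecos") 65.5 else 62,
                 sd = 8),
      diabetes_duration = list(family = "gamma", shape = 4,
                               rate = if (name == "tecos") 0.34 else 0.33),
      height = list(family = "normal", mean = 168, sd = 10),
      weight = list(family = "normal", mean = 87, sd = 18),
      hdl = list(family = "lognormal", meanlog = log(1.1), sdlog = 0.22),
      ldl = list(family = "lognormal", meanlog = log(2.3), sdlog = 0.35),
      sbp = list(family = "normal", mean = 135, sd = 17),
      hba1c = list(family = "lognormal", meanlog = log(7.5), sdlog = 0.13),
      heart_rate = list(family = "normal", mean = 72, sd = 11),
      wbc = list(family = "normal", mean = 7.5, sd = 1.9),
      haemoglobin = list(family = "normal", mean = 13.8, sd = 1.6),
      egfr = list(family = "normal", mean = 76, sd = 20)),
    bool_prevalence = c(smoker = 0.11, afib = 0.05, pad = 0.12,
                        albuminuria = 0.2),
    # components conditional on the ASCVD flag
    prior_given_ascvd = c(prior_mi = 0.5, prior_stroke = 0.22,
                          prior_ihd = 0.6),
    prior_other = c(prior_hf = 0.16, prior_amputation = 0.015,
                    prior_blindness = 0.01, prior_kidney_failure = 0.02,
                    prior_ulcer = 0.025),
    missingness = c(hba1c = 0.02, sbp = 0.01, weight = 0.015,
                    heart_rate = 0.03, egfr = 0.04, wbc = 0.03,
                    hdl = 0.198, ldl = 0.256, haemoglobin = 0.397),
    mnar_beta = c(hdl = mnar_beta, ldl = mnar_beta, haemoglobin = mnar_beta),
    # modest positive correlation among cardiometabolic factors
    copula = c("weight", "sbp", "hba1c", "ldl"),
    copula_rho = 0.2,
    female_fraction = 0.29)
  if (!is.null(n_active)) prof$n_active <- as.integer(n_active)
  if (!is.null(n_placebo)) prof$n_placebo <- as.integer(n_placebo)
  if (!is.null(missingness)) {
    bad <- setdiff(names(missingness), names(prof$missingness))
    if (length(bad)) .stopf("unknown missingness factor(s): %s",
                            paste(bad, collapse = ", "))
    stopifnot(all(missingness >= 0 & missingness <= 1))
    prof$missingness[names(missingness)] <- missingness
  }
  structure(prof, class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial profile '%s': %d active + %d placebo, ASCVD %.1f%%, follow-up U(%.1f, %.1f) y\n",
    x$name, x$n_active, x$n_placebo, 100 * x$ascvd_prevalence,
    x$fu_range[1], x$fu_range[2]))
  invisible(x)
}

.q_marginal <- function(p, spec) {
  switch(spec$family,
         normal    = stats::qnorm(p, spec$mean, spec$sd),
         lognormal = stats::qlnorm(p, spec$meanlog, spec$sdlog),
         gamma     = stats::qgamma(p, shape = spec$shape, rate = spec$rate),
         .stopf("unknown marginal family '%s'", spec$family))
}

# Calibrate the MNAR logistic intercept so the marginal missing rate hits
# the target on the realized values.
.mnar_prob <- function(x, rate, beta) {
  z <- as.numeric(scale(x))
  f <- function(a) mean(stats::plogis(a + beta * z)) - rate
  a <- stats::uniroot(f, c(-30, 30))$root
  stats::plogis(a + beta * z)
}

#' Generate a synthetic baseline cohort
#'
#' Draws \code{n_active + n_placebo} participants from the profile's
#' marginals (correlated through a Gaussian copula for the cardiometabolic
#' factors), assigns prior-event flags at the configured prevalences (every
#' ASCVD-flagged participant carries at least one of prior MI / stroke /
#' ischemic heart disease), draws a follow-up length per participant, and
#' then masks factor values missing at the configured rates -- by a
#' logistic missing-not-at-random rule on the factor's own value where a
#' nonzero \code{mnar_beta} is configured.
#'
#' @param profile a \code{\link{cohort_profile}}.
#' @param seed integer seed; generation is deterministic given it.
#' @return a baseline-only \code{microsim_cohort} (year-0 rows, with
#'   \code{fu_years}).
#' @export
generate_cohort <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "cohort_profile"))
  n <- profile$n_active + profile$n_placebo
  set.seed(.child_seed(seed, "cohort", profile$name))
  df <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    arm = sample(rep(c("active", "placebo"),
                     c(profile$n_active, profile$n_placebo))),
    year = 0,
    sex = ifelse(stats::runif(n) < profile$female_fraction,
                 "female", "male"),
    race = sample(c("white", "afro", "indian", "other"), n, replace = TRUE,
                  prob = c(0.72, 0.1, 0.1, 0.08)),
    stringsAsFactors = FALSE)
  # correlated uniforms for the copula block, independent elsewhere
  cop <- profile$copula
  rho <- profile$copula_rho
  R <- matrix(rho, length(cop), length(cop)); diag(R) <- 1
  Z <- matrix(stats::rnorm(n * length(cop)), n) %*% chol(R)
  U <- stats::pnorm(Z); colnames(U) <- cop
  for (f in names(profile$marginals)) {
    u <- if (f %in% cop) U[, f] else stats::runif(n)
    df[[f]] <- .q_marginal(u, profile$marginals[[f]])
  }
  df$age <- clamp(df$age, 30, 90)
  df$diabetes_duration <- clamp(df$diabetes_duration, 0, 50)
  lim <- default_factor_limits()
  for (f in .CONT_FACTORS) {
    lr <- .limits_row(lim, f)
    df[[f]] <- clamp(df[[f]], lr$min, lr$max)
  }
  for (f in names(profile$bool_prevalence))
    df[[f]] <- as.integer(stats::runif(n) < profile$bool_prevalence[[f]])
  ascvd <- stats::runif(n) < profile$ascvd_prevalence
  for (f in names(profile$prior_given_ascvd))
    df[[f]] <- as.integer(ascvd & stats::runif(n) < profile$prior_given_ascvd[[f]])
  none <- ascvd & df$prior_mi == 0 & df$prior_stroke == 0 & df$prior_ihd == 0
  df$prior_ihd[none] <- 1L
  for (f in names(profile$prior_other))
    df[[f]] <- as.integer(stats::runif(n) < profile$prior_other[[f]])
  df$fu_years <- stats::runif(n, profile$fu_range[1], profile$fu_range[2])
  complete <- df  # pre-mask ground truth, kept for outcome generation
  # missingness masks last, from the complete values
  for (f in names(profile$missingness)) {
    rate <- profile$missingness[[f]]
    if (rate <= 0) next
    beta <- profile$mnar_beta[f]
    pm <- if (!is.na(beta) && beta != 0) .mnar_prob(df[[f]], rate, beta)
          else rate
    df[[f]][stats::runif(n) < pm] <- NA_real_
  }
  out <- new_cohort(df)
  attr(out, "complete_baseline") <- complete
  out
}

#' Ground-truth outcome generator specification
#'
#' Pairs a coefficient set (its event/death equations are taken as the true
#' hazards) with a multiplicative arm effect applied to the active arm.
#'
#' @param coefficients a \code{\link{coefficient_set}}.
#' @param arm_hr true active-vs-placebo hazard ratio; scalar or named per
#'   endpoint.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(coefficients, arm_hr = 1) {
  stopifnot(inherits(coefficients, "coefficient_set"), all(arm_hr >= 0))
  structure(list(coefficients = coefficients, arm_hr = arm_hr),
            class = "ground_truth")
}

# Inverse-CDF event time for a proportional-hazards form with rate exp(lp).
.draw_event_time <- function(eq, rate, n) {
  E <- stats::rexp(n)
  switch(eq$baseline_form,
         exponential = E / rate,
         weibull     = (E / rate)^(1 / eq$shape),
         gompertz    = log1p(eq$shape * E / rate) / eq$shape,
         .stopf("unsupported hazard family '%s' for outcome generation",
                eq$baseline_form))
}

#' Generate observed time-to-event outcomes from known hazards
#'
#' Draws one latent event time per participant and endpoint from the ground
#' truth's proportional-hazards equations evaluated at the baseline state
#' (inverse-CDF sampling), multiplies the active arm's hazard by the true
#' hazard ratio, and censors at the participant's follow-up length truncated
#' to the horizon.
#'
#' @param cohort baseline cohort (complete for the covariates the true
#'   equations reference).
#' @param truth a \code{\link{ground_truth}}.
#' @param horizon administrative horizon in years.
#' @param seed integer seed.
#' @param censoring use the cohort's \code{fu_years} for censoring
#'   (default); \code{FALSE} censors administratively at the horizon only.
#' @return data frame of observed outcomes: \code{id}, \code{arm},
#'   \code{endpoint}, \code{time}, \code{event}.
#' @export
generate_outcomes <- function(cohort, truth, horizon, seed = 1,
                              censoring = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  # prefer the generator's pre-mask values: the true hazards act on the
  # complete state, missingness is an observation-level phenomenon
  base <- attr(cohort, "complete_baseline") %||%
    cohort[cohort$year == 0, , drop = FALSE]
  n <- nrow(base)
  eqs <- c(.eqs_of_kind(truth$coefficients, "event"),
           .eqs_of_kind(truth$coefficients, "death"))
  if (!length(eqs)) .stopf("ground truth has no event/death equations")
  cens <- if (censoring && !is.null(base$fu_years))
    pmin(base$fu_years, horizon) else rep(horizon, n)
  active <- base$arm == "active"
  out <- vector("list", length(eqs))
  for (i in seq_along(eqs)) {
    eq <- eqs[[i]]
    hr <- if (!is.null(names(truth$arm_hr))) {
      if (eq$name %in% names(truth$arm_hr)) truth$arm_hr[[eq$name]] else 1
    } else truth$arm_hr
    set.seed(.child_seed(seed, "outcomes", eq$name))
    rate <- exp(.lp_vector(eq, base)) * ifelse(active, hr, 1)
    tt <- .draw_event_time(eq, rate, n)
    event <- as.integer(tt <= cens)
    out[[i]] <- data.frame(id = base$id, arm = base$arm, endpoint = eq$name,
                           time = pmin(tt, cens), event = event,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate annual risk-factor follow-up trajectories
#'
#' Extends a baseline cohort with annual records for years
#' \code{1..years}: each continuous factor follows its progression
#' recurrence plus Gaussian noise, clamped to the model limits; boolean
#' factors are carried forward.  Optional observation gaps blank cells at
#' random so the follow-up fill-in machinery can be exercised.
#'
#' @param cohort baseline cohort with complete continuous factors.
#' @param coefficients a \code{\link{coefficient_set}} with progression
#'   equations for every continuous factor.
#' @param years number of annual follow-up records.
#' @param noise_sd Gaussian noise SD; scalar or named per factor.
#' @param gap_prob probability an annual cell is left unobserved (default 0).
#' @param seed integer seed.
#' @return the cohort with annual rows appended.
#' @export
generate_followup_trajectories <- function(cohort, coefficients, years,
                                           noise_sd = 0, gap_prob = 0,
                                           seed = 1) {
  base <- cohort[cohort$year == 0, , drop = FALSE]
  prog <- .eqs_of_kind(coefficients, "progression")
  lim <- default_factor_limits()
  n <- nrow(base)
  set.seed(.child_seed(seed, "trajectories"))
  sd_of <- function(f) {
    if (!is.null(names(noise_sd)))
      return(if (f %in% names(noise_sd)) noise_sd[[f]] else 0)
    noise_sd
  }
  rows <- list(as.data.frame(base))
  cur <- base
  for (y in seq_len(years)) {
    nxt <- base
    nxt$year <- y
    for (f in .CONT_FACTORS) {
      eq <- prog[[f]]
      if (is.null(eq)) .stopf("no progression equation for '%s'", f)
      st <- list(current = cur[[f]],
                 diabetes_duration = (base$diabetes_duration %||% 0) + y - 1)
      v <- eq$intercept
      for (nm in names(eq$coefficients)) {
        ctr <- if (nm %in% names(eq$centers)) eq$centers[[nm]] else 0
        v <- v + eq$coefficients[[nm]] * (st[[nm]] - ctr)
      }
      v <- v + stats::rnorm(n, 0, sd_of(f))
      lr <- .limits_row(lim, f)
      nxt[[f]] <- clamp(v, lr$min, lr$max)
    }
    cur <- nxt
    obs <- nxt
    if (gap_prob > 0)
      for (f in .CONT_FACTORS)
        obs[[f]][stats::runif(n) < gap_prob] <- NA_real_
    rows[[y + 1]] <- as.data.frame(obs)
  }
  new_cohort(do.call(rbind, rows))
}
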