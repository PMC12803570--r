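#' Construct a single annual equation specification
#'
#' The simulation engine is driven entirely by a set of parametric annual
#' equations of three kinds: \code{event} (nonfatal clinical events, with an
#' optional case-fatality term), \code{death} (fatal equations, classed
#' cardiovascular or non-cardiovascular), and \code{progression} (annual
#' risk-factor recurrences).  Event and death equations are proportional
#' hazards on an exponential, Weibull or Gompertz baseline, or an annual
#' logistic model; progression equations are linear-autoregressive.
#'
#' The linear predictor is \code{intercept + sum coef * (x - center)};
#' centering is expressed in the coefficient file so the engine itself stays
#' transform-free.  Covariate names must resolve to a risk factor,
#' demographic, prior-event flag or within-simulation event flag (see
#' \code{\link{covariate_names}}); progression equations may additionally use
#' \code{"current"}, the factor's own current value.
#'
#' @param name endpoint name (event/death) or risk-factor name (progression).
#' @param kind one of \code{"event"}, \code{"death"}, \code{"progression"}.
#' @param baseline_form \code{"exponential"}, \code{"weibull"},
#'   \code{"gompertz"} or \code{"logistic"} for event/death equations;
#'   \code{"linear"} for progression.
#' @param intercept intercept of the linear predictor (log baseline hazard
#'   scale for hazard forms; log-odds for logistic; factor units for
#'   progression).
#' @param coefficients named numeric vector of per-unit weights.
#' @param centers named numeric vector of covariate centering constants
#'   (optional, defaults to 0).
#' @param shape positive shape parameter, required for Weibull/Gompertz.
#' @param time_scale time axis for Weibull/Gompertz baselines: years since
#'   simulation entry (\code{"simulation"}, default) or current diabetes
#'   duration (\code{"duration"}).
#' @param excluded_if_prior character vector of prior-event flags; a
#'   participant with any of them set never experiences this endpoint
#'   (first-event-only equations, e.g. ischemic heart disease and heart
#'   failure).
#' @param case_fatality probability in [0,1] that a fired event is fatal
#'   (event equations only); fatal cases count as cardiovascular deaths.
#' @param fatal_class \code{"cv"} or \code{"noncv"} (death equations only).
#' @param ua_fraction probability that a fired event additionally registers a
#'   hospitalization-for-unstable-angina proxy event (default 0, i.e. off).
#' @return an object of class \code{eq_spec}.
#' @export
eq_spec <- function(name, kind, baseline_form, intercept = 0,
                    coefficients = numeric(0), centers = numeric(0),
                    shape = NULL, time_scale = "simulation",
                    excluded_if_prior = character(0),
                    case_fatality = 0, fatal_class = "noncv",
                    ua_fraction = 0) {
  kind <- match.arg(kind, c("event", "death", "progression"))
  forms <- if (kind == "progression") "linear"
           else c("exponential", "weibull", "gompertz", "logistic")
  if (!baseline_form %in% forms)
    .stopf("equation '%s': unknown baseline_form '%s'", name, baseline_form)
  if (baseline_form %in% c("weibull", "gompertz")) {
    if (is.null(shape) || !is.finite(shape) || shape <= 0)
      .stopf("equation '%s': %s form requires shape > 0", name, baseline_form)
  }
  coefficients <- unlist(coefficients)
  centers <- unlist(centers)
  allowed <- c(.ALL_COVARIATES, if (kind == "progression") "current")
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad))
    .stopf("equation '%s': unresolvable covariate(s): %s",
           name, paste(sQuote(bad), collapse = ", "))
  bad <- setdiff(names(centers), names(coefficients))
  if (length(bad))
    .stopf("equation '%s': center without coefficient: %s",
           name, paste(sQuote(bad), collapse = ", "))
  bad <- setdiff(excluded_if_prior, .PRIOR_EVENTS)
  if (length(bad))
    .stopf("equation '%s': unknown prior-event flag(s): %s",
           name, paste(sQuote(bad), collapse = ", "))
  if (case_fatality < 0 || case_fatality > 1)
    .stopf("equation '%s': case_fatality must lie in [0,1]", name)
  fatal_class <- match.arg(fatal_class, c("noncv", "cv"))
  time_scale <- match.arg(time_scale, c("simulation", "duration"))
  structure(list(name = name, kind = kind, baseline_form = baseline_form,
                 intercept = intercept, coefficients = coefficients,
                 centers = centers, shape = shape, time_scale = time_scale,
                 excluded_if_prior = excluded_if_prior,
                 case_fatality = case_fatality, fatal_class = fatal_class,
                 ua_fraction = ua_fraction),
            class = "eq_spec")
}

#' Covariate names an equation may reference
#' @return character vector of all resolvable covariate names.
#' @export
covariate_names <- function() .ALL_COVARIATES

#' Bundle equations into a coefficient set
#'
#' @param equations list of \code{\link{eq_spec}} objects.
#' @param version free-form version tag recorded in all outputs.
#' @return an object of class \code{coefficient_set}.
#' @export
coefficient_set <- function(equations, version = "unversioned") {
  nm <- vapply(equations, `[[`, "", "name")
  dup <- nm[duplicated(nm)]
  if (length(dup))
    .stopf("duplicate equation name(s): %s",
           paste(sQuote(unique(dup)), collapse = ", "))
  names(equations) <- nm
  structure(list(version = version, equations = equations),
            class = "coefficient_set")
}

.eqs_of_kind <- function(set, kind) {
  set$equations[vapply(set$equations, `[[`, "", "kind") %in% kind]
}

#' @export
print.coefficient_set <- function(x, ...) {
  kd <- vapply(x$equations, `[[`, "", "kind")
  cat(sprintf("Coefficient set '%s': %d event, %d death, %d progression equations\n",
              x$version, sum(kd == "event"), sum(kd == "death"),
              sum(kd == "progression")))
  for (eq in x$equations)
    cat(sprintf("  %-12s %-11s %-11s %d covariate(s)\n", eq$name, eq$kind,
                eq$baseline_form, length(eq$coefficients)))
  invisible(x)
}

#' Evaluate an equation's linear predictor
#'
#' \code{intercept + sum coef * (covariate - center)} over the equation's
#' named coefficients.
#'
#' @param eq an \code{\link{eq_spec}}.
#' @param state named list or numeric vector holding every covariate the
#'   equation references.
#' @return a single numeric value.
#' @export
linear_predictor <- function(eq, state) {
  lp <- eq$intercept
  for (nm in names(eq$coefficients)) {
    v <- state[[nm]]
    if (is.null(v) || is.na(v))
      .stopf("equation '%s': covariate '%s' missing from state", eq$name, nm)
    ctr <- if (nm %in% names(eq$centers)) eq$centers[[nm]] else 0
    lp <- lp + eq$coefficients[[nm]] * (as.numeric(v) - ctr)
  }
  lp
}

# Integrated baseline hazard Lambda0 on [0, t] for the hazard forms.
.Lambda0 <- function(form, t, shape) {
  switch(form,
         exponential = t,
         weibull     = t^shape,
         gompertz    = (exp(shape * t) - 1) / shape,
         .stopf("no integrated hazard for form '%s'", form))
}

#' Probability that an event/death equation fires within one cycle
#'
#' For the proportional-hazards forms the cycle probability is
#' \code{1 - exp(-H)} with \code{H = exp(lp) * (Lambda0(t + L) - Lambda0(t))},
#' the baseline form's integrated hazard over the cycle scaled by the
#' exponentiated linear predictor.  For the logistic form the annual
#' probability \code{expit(lp)} is rescaled to a partial cycle as
#' \code{1 - (1 - p)^L}.  Hazard integration is exact, so two half cycles
#' compose to one full cycle.
#'
#' @inheritParams linear_predictor
#' @param cycle_length cycle length in years, in (0, 1].
#' @param time years already elapsed on the equation's time scale at the
#'   start of the cycle (ignored by the exponential and logistic forms).
#' @return probability in [0, 1].
#' @export
annual_event_probability <- function(eq, state, cycle_length = 1, time = 0) {
  if (!eq$kind %in% c("event", "death"))
    .stopf("equation '%s' is not an event/death equation", eq$name)
  if (cycle_length <= 0 || cycle_length > 1)
    .stopf("cycle_length must lie in (0, 1]")
  lp <- linear_predictor(eq, state)
  if (eq$baseline_form == "logistic") {
    p1 <- stats::plogis(lp)
    return(1 - (1 - p1)^cycle_length)
  }
  if (eq$time_scale == "duration") time <- as.numeric(state[["diabetes_duration"]])
  H <- exp(lp) * (.Lambda0(eq$baseline_form, time + cycle_length, eq$shape) -
                    .Lambda0(eq$baseline_form, time, eq$shape))
  1 - exp(-H)
}

#' Advance a risk factor one annual step
#'
#' Applies the linear-autoregressive recurrence
#' \code{next = intercept + slope * current + drift * diabetes_duration + ...}
#' and clamps the result into the factor's admissible range when a limits
#' table is supplied.
#'
#' @inheritParams linear_predictor
#' @param limits optional \code{\link{default_factor_limits}}-shaped table.
#' @return next-cycle factor value.
#' @export
progress_risk_factor <- function(eq, state, limits = NULL) {
  if (eq$kind != "progression")
    .stopf("equation '%s' is not a progression equation", eq$name)
  st <- as.list(state)
  if (!is.null(st[[eq$name]]) && is.null(st[["current"]]))
    st[["current"]] <- st[[eq$name]]
  v <- linear_predictor(eq, st)
  if (!is.null(limits)) {
    lr <- .limits_row(limits, eq$name)
    v <- clamp(v, lr$min, lr$max)
  }
  v
}

#' Read a coefficient set from JSON
#'
#' The file format is \code{{"version": ..., "equations": [...]}} with one
#' object per equation carrying the \code{\link{eq_spec}} fields; the JSON
#' Schema shipped at \code{inst/extdata/coefficients-schema.json} documents
#' it.  Unresolvable covariate names, duplicate endpoint names, unknown
#' baseline forms and non-positive shapes are rejected at load time.
#'
#' @param path JSON file path.
#' @return a \code{\link{coefficient_set}}.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) .stopf("coefficient file not found: %s", path)
  js <- jsonlite::read_json(path)
  if (is.null(js$equations)) .stopf("coefficient file lacks 'equations'")
  eqs <- lapply(js$equations, function(e) {
    eq_spec(name = e$name, kind = e$kind, baseline_form = e$baseline_form,
            intercept = e$intercept %||% 0,
            coefficients = unlist(e$coefficients) %||% numeric(0),
            centers = unlist(e$centers) %||% numeric(0),
            shape = e$shape, time_scale = e$time_scale %||% "simulation",
            excluded_if_prior = unlist(e$excluded_if_prior) %||% character(0),
            case_fatality = e$case_fatality %||% 0,
            fatal_class = e$fatal_class %||% "noncv",
            ua_fraction = e$ua_fraction %||% 0)
  })
  coefficient_set(eqs, version = js$version %||% "unversioned")
}

#' Write a coefficient set to JSON
#' @param set a \code{\link{coefficient_set}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_coefficients <- function(set, path) {
  eqs <- lapply(set$equations, function(eq) {
    e <- list(name = eq$name, kind = eq$kind,
              baseline_form = eq$baseline_form, intercept = eq$intercept)
    if (length(eq$coefficients)) e$coefficients <- as.list(eq$coefficients)
    if (length(eq$centers)) e$centers <- as.list(eq$centers)
    if (!is.null(eq$shape)) e$shape <- eq$shape
    if (eq$time_scale != "simulation") e$time_scale <- eq$time_scale
    if (length(eq$excluded_if_prior))
      e$excluded_if_prior <- as.list(eq$excluded_if_prior)
    if (eq$case_fatality > 0) e$case_fatality <- eq$case_fatality
    if (eq$kind == "death") e$fatal_class <- eq$fatal_class
    if (eq$ua_fraction > 0) e$ua_fraction <- eq$ua_fraction
    e
  })
  jsonlite::write_json(list(version = set$version, equations = unname(eqs)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Illustrative (non-canonical) coefficient set
#'
#' A complete, clearly synthetic coefficient set with clinically plausible
#' magnitudes, shipped so the whole pipeline is runnable and testable without
#' the published model coefficients.  It is \emph{not} the published UKPDS
#' Outcomes Model: users wishing to reproduce that model supply its published
#' coefficient values in the same JSON format.
#'
#' Event equations: myocardial infarction (\code{mi}, case fatality 0.15),
#' stroke (case fatality 0.12), first ischemic heart disease (\code{ihd},
#' excluded for prior IHD), first heart failure (\code{hf}, excluded for
#' prior HF).  Death equations: \code{cv_death} and \code{noncv_death}.
#' Progression equations cover every continuous annualized factor
#' (identity with small drifts).
#'
#' @return a \code{\link{coefficient_set}}.
#' @export
illustrative_coefficients <- function() {
  path <- system.file("extdata", "illustrative-coefficients.json",
                      package = "t2dsim")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "illustrative-coefficients.json")
  read_coefficients(path)
}
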