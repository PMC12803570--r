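#' Construct an annual-cycle outcomes microsimulation model
#'
#' Binds a coefficient set (the parametric annual event, death and
#' risk-factor progression equations) to a factor-limits table, producing
#' the model object everything else operates on: \code{\link{simulate.outcomes_model}}
#' runs the probabilistic discrete-time illness-death microsimulation,
#' \code{\link{predict.outcomes_model}} returns analytic per-participant
#' risks, and \code{\link{validate_model}} compares simulated with observed
#' outcomes.
#'
#' @param coefficients a \code{\link{coefficient_set}} (default: the shipped
#'   clearly-labelled illustrative set; supply the published coefficients of
#'   the model you wish to reproduce).
#' @param limits factor limits table, see \code{\link{default_factor_limits}}.
#' @return an object of class \code{outcomes_model}.
#' @export
outcomes_model <- function(coefficients = illustrative_coefficients(),
                           limits = default_factor_limits()) {
  stopifnot(inherits(coefficients, "coefficient_set"))
  structure(list(coefficients = coefficients, limits = limits),
            class = "outcomes_model")
}

#' @export
print.outcomes_model <- function(x, ...) {
  cat("Discrete-time illness-death outcomes microsimulation model\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.outcomes_model <- function(object, ...) {
  print(object)
  ev <- .eqs_of_kind(object$coefficients, "event")
  restricted <- names(ev)[vapply(ev, function(e)
    length(e$excluded_if_prior) > 0, TRUE)]
  if (length(restricted))
    cat("First-event-only endpoints (participants with the prior event are excluded):",
        paste(restricted, collapse = ", "), "\n")
  invisible(object)
}

#' Extract model coefficients
#'
#' @param object an \code{outcomes_model}.
#' @param ... unused.
#' @return named list, one numeric vector per equation
#'   (\code{(Intercept)} followed by the covariate weights).
#' @export
coef.outcomes_model <- function(object, ...) {
  lapply(object$coefficients$equations, function(eq)
    c("(Intercept)" = eq$intercept, eq$coefficients))
}

#' Analytic per-participant event risks
#'
#' Cumulative first-event risk by the horizon for each endpoint, computed by
#' chaining the annual cycle probabilities deterministically
#' (\code{1 - prod(1 - p_cycle)}) with within-simulation event flags held at
#' zero.  This ignores competing mortality and event-feedback on hazards and
#' so is an upper-bound analytic summary; Monte Carlo risks from
#' \code{\link{simulate.outcomes_model}} are the validation quantity.
#'
#' @param object an \code{outcomes_model}.
#' @param cohort a fully imputed \code{microsim_cohort} (see
#'   \code{\link{impute_cohort}}).
#' @param horizon horizon in years (fractional allowed).
#' @param endpoints endpoint names (default: all event and death equations).
#' @param ... unused.
#' @return data frame: \code{id}, then one risk column per endpoint.
#' @export
predict.outcomes_model <- function(object, cohort, horizon,
                                   endpoints = NULL, ...) {
  eqs <- c(.eqs_of_kind(object$coefficients, "event"),
           .eqs_of_kind(object$coefficients, "death"))
  if (is.null(endpoints)) endpoints <- names(eqs)
  layout <- .engine_layout(cohort, horizon)
  out <- data.frame(id = layout$ids, stringsAsFactors = FALSE)
  for (nm in endpoints) {
    eq <- eqs[[nm]]
    if (is.null(eq)) .stopf("unknown endpoint '%s'", nm)
    surv <- rep(1, layout$n)
    excl <- .excluded_participants(eq, layout)
    for (cyc in seq_along(layout$cycle_len)) {
      p <- .cycle_probability(eq, layout, cyc, flags = NULL)
      surv <- surv * (1 - p)
    }
    risk <- 1 - surv
    risk[excl] <- 0
    out[[nm]] <- risk
  }
  out
}
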