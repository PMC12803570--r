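#' Build the observed-versus-simulated validation report
#'
#' For each endpoint: observed per-arm first-event counts and proportions
#' with the unadjusted Cox hazard ratio; simulated (mean across
#' replications) per-arm counts and proportions with the simulated relative
#' risk; and the patient-level accuracy battery computed from the
#' across-replication event frequencies -- Brier score at the fixed horizon
#' (participants censored early event-free are excluded), calibration
#' intercept and slope with the decile curve, and Harrell's C over the
#' censored observed outcomes.  First-event-only endpoints restrict both
#' numerator and denominator to participants without the prior event.
#' Per-subgroup count summaries (age below/at-or-above 65, sex, prior
#' cardiovascular events) are attached for the requested endpoints.
#'
#' @param observed data frame of observed outcomes: \code{id}, \code{arm},
#'   \code{endpoint}, \code{time} (years), \code{event} (0/1).
#' @param sim a \code{simulated_outcomes} from
#'   \code{\link{simulate.outcomes_model}} over the same cohort.
#' @param endpoints endpoints to report (default: those present in both
#'   \code{observed} and the simulation, composites included).
#' @param subgroups subgroup axes among \code{"age"}, \code{"sex"},
#'   \code{"prior_cv"} (default all three).
#' @param age_cut age boundary for the age subgroup (default 65).
#' @return object of class \code{validation_report}.
#' @export
build_validation_report <- function(observed, sim, endpoints = NULL,
                                    subgroups = c("age", "sex", "prior_cv"),
                                    age_cut = 65) {
  stopifnot(all(c("id", "arm", "endpoint", "time", "event") %in%
                  names(observed)))
  offenders <- setdiff(unique(observed$id), sim$ids)
  if (length(offenders))
    .stopf("observed ids absent from simulation: %s%s",
           paste(utils::head(offenders, 5), collapse = ", "),
           if (length(offenders) > 5) ", ..." else "")
  if (is.null(endpoints))
    endpoints <- intersect(unique(observed$endpoint), sim_endpoints(sim))
  if (!length(endpoints)) .stopf("no endpoint present in both observed and simulated data")
  horizon <- sim$horizon
  meta <- sim$meta
  per_ep <- lapply(endpoints, function(ep) {
    m <- .endpoint_matrices(sim, ep)
    elig <- !m$excluded
    obs_ep <- observed[observed$endpoint == ep, , drop = FALSE]
    oi <- match(sim$ids, obs_ep$id)
    if (anyNA(oi[elig]))
      .stopf("endpoint '%s': no observed record for %d participant(s)",
             ep, sum(is.na(oi[elig])))
    otime <- obs_ep$time[oi]
    oevent <- obs_ep$event[oi]
    arms <- c("active", "placebo")
    obs_arm <- lapply(arms, function(a) {
      e <- elig & sim$arm == a
      data.frame(arm = a, count = sum(oevent[e]), denominator = sum(e),
                 proportion = sum(oevent[e]) / max(sum(e), 1))
    })
    obs_arm <- do.call(rbind, obs_arm)
    sim_arm <- first_event_summary(sim, ep)
    rr <- if (any(sim_arm$denominator == 0) || sim_arm$count[2] == 0)
      NA_real_
    else relative_risk(sim_arm$count[1], sim_arm$denominator[1],
                       sim_arm$count[2], sim_arm$denominator[2])
    hr <- tryCatch(cox_hr(data.frame(arm = sim$arm[elig], time = otime[elig],
                                     event = oevent[elig])),
                   error = function(e) list(hr = NA_real_, lower = NA_real_,
                                            upper = NA_real_, flagged = TRUE))
    risk <- predicted_risk(sim, ep)
    hz <- horizon_outcomes(otime[elig], oevent[elig], horizon)
    keep <- hz$keep
    br <- brier(risk[elig][keep], hz$obs[keep])
    cal <- calibration(risk[elig][keep], hz$obs[keep])
    cc <- harrell_c(risk[elig], otime[elig], oevent[elig])
    obs_ci <- lapply(arms, function(a) {
      e <- elig & sim$arm == a
      ci <- cumulative_incidence(otime[e], oevent[e])
      cbind(arm = a, source = "observed", ci)
    })
    sim_ci <- lapply(arms, function(a) {
      e <- elig & sim$arm == a
      cyc <- m$cycle[, e, drop = FALSE]
      ev <- m$event[, e, drop = FALSE]
      tt <- seq_len(length(.cycle_structure(horizon)$len))
      inc <- vapply(tt, function(cmax)
        mean(rowSums(ev & !is.na(cyc) & cyc <= cmax)) / max(sum(e), 1), 0)
      data.frame(arm = a, source = "simulated",
                 time = pmin(cumsum(.cycle_structure(horizon)$len), horizon),
                 incidence = inc)
    })
    list(endpoint = ep, restricted = any(m$excluded),
         observed = obs_arm, simulated = sim_arm, rr = rr, hr = hr,
         brier = br, calibration = cal, harrell_c = cc,
         incidence = rbind(do.call(rbind, obs_ci), do.call(rbind, sim_ci)))
  })
  names(per_ep) <- endpoints
  sub_rows <- list()
  sub_defs <- list(
    age = list(label = function(m) ifelse(m$age < age_cut,
                                          sprintf("age<%d", age_cut),
                                          sprintf("age>=%d", age_cut))),
    sex = list(label = function(m) m$sex),
    prior_cv = list(label = function(m) ifelse(m$prior_cv == 1,
                                               "prior CV events",
                                               "no prior CV events")))
  for (sg in intersect(subgroups, names(sub_defs))) {
    lab <- sub_defs[[sg]]$label(meta)
    for (ep in endpoints) {
      m <- .endpoint_matrices(sim, ep)
      obs_ep <- observed[observed$endpoint == ep, , drop = FALSE]
      oi <- match(sim$ids, obs_ep$id)
      for (lv in sort(unique(lab))) {
        for (a in c("active", "placebo")) {
          e <- !m$excluded & sim$arm == a & lab == lv
          n_e <- sum(e)
          sim_cnt <- if (n_e) mean(rowSums(m$event[, e, drop = FALSE])) else 0
          obs_cnt <- if (n_e) sum(obs_ep$event[oi][e], na.rm = TRUE) else 0
          sub_rows[[length(sub_rows) + 1]] <- data.frame(
            subgroup = sg, level = lv, endpoint = ep, arm = a, n = n_e,
            observed = obs_cnt, simulated = sim_cnt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(endpoints = per_ep,
                 subgroups = if (length(sub_rows)) do.call(rbind, sub_rows)
                             else NULL,
                 horizon = horizon, nsim = sim$nsim, seed = sim$seed,
                 coefficient_version = sim$coefficient_version),
            class = "validation_report")
}

#' Convenience wrapper: simulate then validate
#'
#' Runs the microsimulation over a fully imputed cohort and compares it with
#' the supplied observed outcomes.
#'
#' @param model an \code{\link{outcomes_model}}.
#' @param cohort fully imputed \code{microsim_cohort}.
#' @param observed observed-outcome data frame
#'   (see \code{\link{build_validation_report}}).
#' @param horizon simulated follow-up in years.
#' @param nsim replications (default 200).
#' @param seed integer master seed.
#' @param ... passed to \code{\link{build_validation_report}}.
#' @return a \code{validation_report}.
#' @export
validate_model <- function(model, cohort, observed, horizon, nsim = 200,
                           seed = 1, ...) {
  sim <- simulate(model, nsim = nsim, seed = seed, cohort = cohort,
                  horizon = horizon)
  build_validation_report(observed, sim, ...)
}

#' Format the report as trial-table rows
#'
#' One row per endpoint in the column order of a cardiovascular-outcome
#' validation table: observed and simulated events per arm as
#' \code{"count (x.x\%)"} cells, the observed hazard ratio with its 95\% CI,
#' the simulated relative risk, and the C-statistic.  Restricted endpoints
#' carry a footnote marker on the denominator restriction.
#'
#' @param report a \code{validation_report}.
#' @return data frame of formatted cells.
#' @export
format_outcome_table <- function(report) {
  rows <- lapply(report$endpoints, function(r) {
    oc <- r$observed; sc <- r$simulated
    data.frame(
      outcome = paste0(r$endpoint, if (r$restricted) " [a]" else ""),
      observed_active = format_count_pct(oc$count[1], oc$denominator[1]),
      simulated_active = format_count_pct(sc$count[1], sc$denominator[1]),
      observed_placebo = format_count_pct(oc$count[2], oc$denominator[2]),
      simulated_placebo = format_count_pct(sc$count[2], sc$denominator[2]),
      hazard_ratio = if (is.na(r$hr$hr)) "-" else
        sprintf("%.2f (%.2f-%.2f)", round_half_up(r$hr$hr, 2),
                round_half_up(r$hr$lower, 2), round_half_up(r$hr$upper, 2)),
      relative_risk = if (is.na(r$rr)) "-" else sprintf("%.2f", r$rr),
      c_statistic = if (is.na(r$harrell_c$c)) "-" else
        sprintf("%.2f", round_half_up(r$harrell_c$c, 2)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(grepl("\\[a\\]", out$outcome)))
    attr(out, "footnote") <- "[a] In those without the prior event."
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation report: %d endpoint(s), horizon %.2f y, %d replications (coefficients '%s')\n\n",
    length(x$endpoints), x$horizon, x$nsim, x$coefficient_version))
  tab <- format_outcome_table(x)
  print(tab, right = FALSE)
  if (!is.null(attr(tab, "footnote"))) cat(attr(tab, "footnote"), "\n")
  invisible(x)
}

#' @export
summary.validation_report <- function(object, ...) {
  print(object)
  cat("\nPatient-level accuracy:\n")
  for (r in object$endpoints) {
    cat(sprintf(
      "  %-10s Brier %.3f%s | calibration intercept %+.3f, slope %s | C %.3f\n",
      r$endpoint, r$brier$score,
      if (r$brier$informative) " (informative)" else "",
      r$calibration$intercept,
      if (r$calibration$flagged) "n/a"
      else sprintf("%.3f", r$calibration$slope),
      r$harrell_c$c))
  }
  invisible(object)
}

#' Tidy calibration-curve data for all endpoints
#' @param report a \code{validation_report}.
#' @return data frame: endpoint, bin, mean_pred, obs_prop, n.
#' @export
calibration_data <- function(report) {
  do.call(rbind, lapply(report$endpoints, function(r)
    cbind(endpoint = r$endpoint, r$calibration$deciles)))
}

#' Tidy cumulative-incidence plot data for all endpoints
#' @param report a \code{validation_report}.
#' @return data frame: endpoint, arm, source, time, incidence.
#' @export
incidence_data <- function(report) {
  out <- do.call(rbind, lapply(report$endpoints, function(r)
    cbind(endpoint = r$endpoint, r$incidence)))
  rownames(out) <- NULL
  out
}

#' Plot observed versus simulated calibration
#'
#' Base-graphics decile calibration plot (mean predicted risk against
#' observed proportion) for one endpoint, with the identity line.
#'
#' @param x a \code{validation_report}.
#' @param endpoint endpoint to plot (default: first).
#' @param ... passed to \code{plot}.
#' @export
plot.validation_report <- function(x, endpoint = NULL, ...) {
  if (is.null(endpoint)) endpoint <- names(x$endpoints)[1]
  r <- x$endpoints[[endpoint]]
  d <- r$calibration$deciles
  lim <- range(c(d$mean_pred, d$obs_prop, 0))
  plot(d$mean_pred, d$obs_prop, xlim = lim, ylim = lim,
       xlab = "Mean predicted risk", ylab = "Observed proportion",
       main = sprintf("Calibration: %s", endpoint), pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
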