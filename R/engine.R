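# Simulation engine internals: cycle layout, vectorised cycle probabilities,
# and the per-participant replication loop behind simulate.outcomes_model().

# Cycle structure for a horizon: floor(horizon) full annual cycles plus one
# partial cycle of length horizon - floor(horizon) when positive.
.cycle_structure <- function(horizon) {
  if (horizon <= 0) .stopf("horizon must be > 0")
  nfull <- floor(horizon + 1e-9)
  part <- horizon - nfull
  len <- c(rep(1, nfull), if (part > 1e-9) part)
  list(len = len, start = cumsum(c(0, len))[seq_along(len)])
}

# Map a registry covariate name to a numeric column of the cohort frame.
.cov_column <- function(df, nm) {
  v <- switch(nm,
    male        = as.numeric(df$sex == "male"),
    race_afro   = as.numeric((df$race %||% "white") == "afro"),
    race_indian = as.numeric((df$race %||% "white") == "indian"),
    race_other  = as.numeric((df$race %||% "white") == "other"),
    df[[nm]])
  if (is.null(v))
    .stopf("covariate '%s' absent from cohort", nm)
  as.numeric(v)
}

# Precompute everything cycle-state-dependent once per (cohort, horizon):
# per-equation linear-predictor matrices (cycle x participant) excluding the
# within-simulation event flags, whose coefficients are kept separately.
.engine_layout <- function(cohort, horizon) {
  cyc <- .cycle_structure(horizon)
  ncyc <- length(cyc$len)
  base <- cohort[cohort$year == 0, , drop = FALSE]
  ids <- base$id
  n <- length(ids)
  if (!n) .stopf("empty cohort")
  years_have <- sort(unique(cohort$year))
  state_year <- pmin(seq_len(ncyc) - 1, max(years_have))
  rowidx <- matrix(NA_integer_, ncyc, n)
  key <- paste(cohort$id, cohort$year)
  for (c_ in seq_len(ncyc)) {
    rowidx[c_, ] <- match(paste(ids, state_year[c_]), key)
    if (anyNA(rowidx[c_, ]))
      .stopf("cohort lacks year-%d rows; run fill_followup/impute_cohort first",
             state_year[c_])
  }
  dur0 <- as.numeric(base$diabetes_duration %||% rep(0, n))
  dur0[is.na(dur0)] <- 0
  list(ids = ids, n = n, arm = base$arm, cohort = cohort,
       base = base, rowidx = rowidx, cycle_len = cyc$len,
       cycle_start = cyc$start, dur0 = dur0)
}

# Row-wise linear predictor over a cohort frame, sim-event-flag terms left
# out (they are zero at baseline and handled separately in the engine).
.lp_vector <- function(eq, df) {
  static <- setdiff(names(eq$coefficients), .SIM_EVENT_FLAGS)
  lp_rows <- rep(eq$intercept, nrow(df))
  for (nm in static) {
    ctr <- if (nm %in% names(eq$centers)) eq$centers[[nm]] else 0
    v <- .cov_column(df, nm)
    if (anyNA(v))
      .stopf("equation '%s': covariate '%s' has missing values", eq$name, nm)
    lp_rows <- lp_rows + eq$coefficients[[nm]] * (v - ctr)
  }
  lp_rows
}

# Linear-predictor matrix (cycle x participant) for one equation, with the
# age/duration clock advanced per cycle.
.lp_matrix <- function(eq, layout) {
  clock <- sum(eq$coefficients[intersect(names(eq$coefficients),
                                         c("age", "diabetes_duration"))])
  lp_rows <- .lp_vector(eq, layout$cohort)
  m <- matrix(lp_rows[layout$rowidx], nrow(layout$rowidx), layout$n)
  if (clock != 0)
    m <- m + clock * (seq_along(layout$cycle_len) - 1)
  m
}

.flag_coefs <- function(eq) {
  fc <- stats::setNames(numeric(length(.SIM_EVENT_FLAGS)), .SIM_EVENT_FLAGS)
  hit <- intersect(names(eq$coefficients), .SIM_EVENT_FLAGS)
  fc[hit] <- eq$coefficients[hit]
  fc
}

.excluded_participants <- function(eq, layout) {
  out <- rep(FALSE, layout$n)
  for (fl in eq$excluded_if_prior) {
    v <- layout$base[[fl]]
    if (!is.null(v)) out <- out | (!is.na(v) & v == 1)
  }
  out
}

# Cycle event probability from linear predictor(s); lp may be a vector.
.haz_p <- function(eq, lp, L, t) {
  if (eq$baseline_form == "logistic") return(1 - (1 - stats::plogis(lp))^L)
  H <- exp(lp) * (.Lambda0(eq$baseline_form, t + L, eq$shape) -
                    .Lambda0(eq$baseline_form, t, eq$shape))
  1 - exp(-H)
}

# Deterministic per-participant probability for predict(): flags at zero.
.cycle_probability <- function(eq, layout, cyc, flags = NULL) {
  lp <- .lp_matrix(eq, layout)[cyc, ]
  t0 <- if (eq$time_scale == "duration") layout$dur0 + layout$cycle_start[cyc]
        else layout$cycle_start[cyc]
  .haz_p(eq, lp, layout$cycle_len[cyc], t0)
}

# Row-wise ranks of a uniform matrix: a fresh random permutation of the
# equation evaluation order for every replication x cycle.
.row_permutation <- function(U) {
  o <- order(row(U), U)
  rk <- U
  rk[o] <- rep(seq_len(ncol(U)), nrow(U))
  rk
}

#' Run the microsimulation over a cohort
#'
#' Simulates every participant for \code{floor(horizon)} full annual cycles
#' plus one partial cycle when the horizon is fractional.  Within each cycle
#' the event and death equations are visited in a fresh uniformly-random
#' permutation; each applicable equation fires by an independent uniform
#' draw against its cycle probability.  A fatal outcome (a death equation,
#' or an event drawn fatal by its case-fatality term) ends the cycle: events
#' earlier in the permutation still count, later ones do not.  Fired events
#' raise the within-simulation event flags that enter subsequent cycles'
#' linear predictors; risk factors follow the cohort's (observed or filled)
#' annualized records.  Event equations are evaluated until their first
#' firing per replication: the engine simulates first events, with
#' post-event mortality carried by the death equations' event-flag terms.
#'
#' Participants with a prior event named in an equation's
#' \code{excluded_if_prior} never experience that endpoint and are excluded
#' from its denominators.  Per-participant RNG substreams are derived from
#' \code{(seed, participant id)}, so results do not depend on cohort row
#' order.
#'
#' @param object an \code{\link{outcomes_model}}.
#' @param nsim number of replications (default 200).
#' @param seed integer master seed.
#' @param cohort fully imputed \code{microsim_cohort}.
#' @param horizon simulated follow-up in years (fractional allowed).
#' @param ... unused.
#' @return an object of class \code{simulated_outcomes}: per-endpoint
#'   replication-by-participant event indicator and event-cycle matrices for
#'   every event equation plus \code{ua}, \code{cv_death} and \code{acm},
#'   with derived composites (\code{mace3}, \code{mace4}) available through
#'   \code{\link{predicted_risk}} and \code{\link{first_event_summary}}.
#' @export
simulate.outcomes_model <- function(object, nsim = 200, seed = NULL,
                                    cohort, horizon, ...) {
  if (nsim < 1) .stopf("nsim must be >= 1")
  if (is.null(seed)) seed <- 1L
  layout <- .engine_layout(cohort, horizon)
  set <- object$coefficients
  ev_eqs <- .eqs_of_kind(set, "event")
  de_eqs <- .eqs_of_kind(set, "death")
  eqs <- c(ev_eqs, de_eqs)
  k <- length(eqs)
  if (!k) .stopf("coefficient set has no event or death equations")
  ke <- length(ev_eqs)
  is_event <- seq_len(k) <= ke
  cfat <- vapply(eqs, function(e) e$case_fatality %||% 0, 0)
  uafr <- vapply(eqs, function(e) e$ua_fraction %||% 0, 0)
  is_cv_death <- vapply(eqs, function(e)
    e$kind == "death" && e$fatal_class == "cv", TRUE)
  lp <- lapply(eqs, .lp_matrix, layout = layout)
  fc <- lapply(eqs, .flag_coefs)
  has_flags <- vapply(fc, function(v) any(v != 0), TRUE)
  excl <- lapply(eqs, .excluded_participants, layout = layout)
  ncyc <- length(layout$cycle_len)
  n <- layout$n
  endpoints <- c(names(ev_eqs), "ua", "cv_death", "acm")
  evres <- lapply(endpoints, function(.) matrix(FALSE, nsim, n))
  cyres <- lapply(endpoints, function(.) matrix(NA_integer_, nsim, n))
  names(evres) <- names(cyres) <- endpoints
  i_ua <- match("ua", endpoints)
  i_cvd <- match("cv_death", endpoints)
  i_acm <- match("acm", endpoints)
  flag_idx <- match(paste0("event_", names(ev_eqs)), .SIM_EVENT_FLAGS)

  for (j in seq_len(n)) {
    set.seed(.child_seed(seed, layout$ids[j]))
    flags <- matrix(0, nsim, length(.SIM_EVENT_FLAGS))
    alive <- rep(TRUE, nsim)
    fired_before <- matrix(FALSE, nsim, ke)
    for (c_ in seq_len(ncyc)) {
      if (!any(alive)) break
      U <- matrix(stats::runif(nsim * k), nsim, k)
      PRM <- matrix(stats::runif(nsim * k), nsim, k)
      V <- matrix(stats::runif(nsim * k), nsim, k)
      W <- matrix(stats::runif(nsim * k), nsim, k)
      L <- layout$cycle_len[c_]
      P <- matrix(0, nsim, k)
      for (e in seq_len(k)) {
        if (excl[[e]][j]) next
        lpe <- lp[[e]][c_, j]
        if (has_flags[e]) lpe <- lpe + as.vector(flags %*% fc[[e]])
        t0 <- if (eqs[[e]]$time_scale == "duration")
          layout$dur0[j] + layout$cycle_start[c_] else layout$cycle_start[c_]
        P[, e] <- .haz_p(eqs[[e]], lpe, L, t0)
      }
      if (ke) P[, seq_len(ke)][fired_before] <- 0
      fired <- (U < P) & alive
      if (!any(fired)) next
      pos <- .row_permutation(PRM)
      fatal <- fired & (matrix(!is_event, nsim, k, byrow = TRUE) |
                          (matrix(is_event, nsim, k, byrow = TRUE) &
                             V < matrix(cfat, nsim, k, byrow = TRUE)))
      posF <- pos
      posF[!fatal] <- Inf
      dpos <- do.call(pmin, lapply(seq_len(k), function(e) posF[, e]))
      counted <- fired & pos <= dpos
      for (e in seq_len(ke)) {
        new <- counted[, e]
        if (!any(new)) next
        evres[[e]][new, j] <- TRUE
        cyres[[e]][new, j] <- c_
        fired_before[new, e] <- TRUE
        if (!is.na(flag_idx[e])) flags[new, flag_idx[e]] <- 1
        if (uafr[e] > 0) {
          ua_new <- new & W[, e] < uafr[e] & !evres[[i_ua]][, j]
          evres[[i_ua]][ua_new, j] <- TRUE
          cyres[[i_ua]][ua_new, j] <- c_
        }
      }
      died <- is.finite(dpos)
      if (any(died)) {
        killer_cv <- rowSums((fatal & pos == dpos) &
                               matrix(is_cv_death | is_event, nsim, k,
                                      byrow = TRUE)) > 0
        cvd <- died & killer_cv
        evres[[i_cvd]][cvd, j] <- TRUE
        cyres[[i_cvd]][cvd, j] <- c_
        evres[[i_acm]][died, j] <- TRUE
        cyres[[i_acm]][died, j] <- c_
        alive <- alive & !died
      }
    }
  }
  excluded <- stats::setNames(lapply(endpoints, function(nm) {
    e <- match(nm, names(eqs))
    if (is.na(e)) rep(FALSE, n) else excl[[e]]
  }), endpoints)
  structure(list(event = evres, cycle = cyres, endpoints = endpoints,
                 ids = layout$ids, arm = layout$arm, n = n, nsim = nsim,
                 seed = seed, horizon = horizon,
                 coefficient_version = set$version,
                 excluded = excluded,
                 meta = data.frame(id = layout$ids, arm = layout$arm,
                                   age = layout$base$age,
                                   sex = layout$base$sex,
                                   prior_cv = .prior_cv(layout$base),
                                   stringsAsFactors = FALSE)),
            class = "simulated_outcomes")
}

#' @export
print.simulated_outcomes <- function(x, ...) {
  cat(sprintf(
    "Simulated outcomes: %d participants x %d replications, horizon %.2f y (coefficients '%s', seed %s)\n",
    x$n, x$nsim, x$horizon, x$coefficient_version, format(x$seed)))
  for (nm in x$endpoints)
    cat(sprintf("  %-10s mean events/replication: %.1f\n", nm,
                mean(rowSums(x$event[[nm]]))))
  invisible(x)
}

# Event/cycle matrices for an endpoint, deriving the MACE composites from
# their components when not directly simulated.
.endpoint_matrices <- function(sim, endpoint) {
  if (endpoint %in% sim$endpoints)
    return(list(event = sim$event[[endpoint]], cycle = sim$cycle[[endpoint]],
                excluded = sim$excluded[[endpoint]]))
  comp <- switch(endpoint,
                 mace3 = c("cv_death", "mi", "stroke"),
                 mace4 = c("cv_death", "mi", "stroke", "ua"),
                 .stopf("unknown endpoint '%s'", endpoint))
  comp <- intersect(comp, sim$endpoints)
  if (!length(comp)) .stopf("endpoint '%s' has no simulated components", endpoint)
  ev <- Reduce(`|`, sim$event[comp])
  cy <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), sim$cycle[comp])
  list(event = ev, cycle = cy, excluded = rep(FALSE, sim$n))
}

#' Endpoints available from a simulation
#' @param sim a \code{simulated_outcomes}.
#' @return character vector including derivable composites.
#' @export
sim_endpoints <- function(sim) {
  comps <- c(if (all(c("cv_death", "mi", "stroke") %in% sim$endpoints)) "mace3",
             if (all(c("cv_death", "mi", "stroke", "ua") %in% sim$endpoints)) "mace4")
  c(sim$endpoints, comps)
}

#' Per-participant predicted risk for an endpoint
#'
#' The across-replication event frequency: the fraction of replications in
#' which the participant experienced the endpoint by the horizon.  This is
#' the patient-level predicted risk fed to the calibration, Brier and
#' concordance metrics.
#'
#' @param sim a \code{simulated_outcomes}.
#' @param endpoint endpoint name (composites allowed).
#' @return numeric vector aligned with \code{sim$ids}.
#' @export
predicted_risk <- function(sim, endpoint) {
  m <- .endpoint_matrices(sim, endpoint)
  colMeans(m$event)
}

#' Per-arm expected first-event counts and proportions
#'
#' The per-arm mean, across replications, of the number of participants with
#' the endpoint by the horizon, and that count over the arm's eligible
#' denominator.  For first-event-only endpoints the denominator (and, by
#' construction, the numerator) excludes participants with the
#' corresponding prior event.
#'
#' @param sim a \code{simulated_outcomes}.
#' @param endpoint endpoint name (composites allowed).
#' @return data frame: \code{arm}, \code{count} (mean over replications),
#'   \code{denominator}, \code{proportion}.
#' @export
first_event_summary <- function(sim, endpoint) {
  m <- .endpoint_matrices(sim, endpoint)
  arms <- c("active", "placebo")
  out <- lapply(arms, function(a) {
    elig <- sim$arm == a & !m$excluded
    cnt <- if (any(elig)) mean(rowSums(m$event[, elig, drop = FALSE])) else 0
    data.frame(arm = a, count = cnt, denominator = sum(elig),
               proportion = if (sum(elig)) cnt / sum(elig) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write simulated outcomes to disk
#'
#' Long-format CSV of event records (participant, replication, endpoint,
#' event, cycle); replication-participant-endpoint triples without an event
#' are omitted and implied by the metadata sidecar, which records the seed,
#' horizon, replication count and coefficient version as JSON.
#'
#' @param sim a \code{simulated_outcomes}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_outcomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(sim$endpoints, function(nm) {
    w <- which(sim$event[[nm]], arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(participant = sim$ids[w[, 2]], replication = w[, 1],
               endpoint = nm, event = 1L,
               cycle = sim$cycle[[nm]][w], stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(participant = character(0), replication = integer(0),
                       endpoint = character(0), event = integer(0),
                       cycle = integer(0))
  utils::write.csv(rows, file.path(dir, "simulated-events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = sim$seed, horizon = sim$horizon,
                            replications = sim$nsim, participants = sim$n,
                            coefficient_version = sim$coefficient_version,
                            omitted_rows_are_nonevents = TRUE),
                       file.path(dir, "run-metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
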