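#' Read a participant-level cohort from delimited text
#'
#' The cohort dialect is one CSV row per participant-year, year 0 being
#' baseline.  Canonical columns are \code{id}, \code{arm}
#' (\code{active}/\code{placebo}), \code{year}, the demographics \code{age}
#' (years), \code{sex} (\code{male}/\code{female}), \code{race}
#' (\code{white}/\code{afro}/\code{indian}/\code{other}),
#' \code{diabetes_duration} (years), \code{height} (cm), the continuous
#' annualized risk factors \code{weight} (kg), \code{hdl}, \code{ldl}
#' (mmol/L), \code{sbp} (mmHg), \code{hba1c} (\%), \code{heart_rate} (bpm),
#' \code{wbc} (10^9/L), \code{haemoglobin} (g/dL), \code{egfr}
#' (mL/min/1.73m2), the boolean factors \code{smoker}, \code{afib},
#' \code{pad}, \code{albuminuria} (0/1), the eight baseline prior-event
#' flags \code{prior_ihd}, \code{prior_hf}, \code{prior_amputation},
#' \code{prior_blindness}, \code{prior_kidney_failure}, \code{prior_mi},
#' \code{prior_stroke}, \code{prior_ulcer} (0/1), and optionally
#' \code{fu_years} (observed follow-up length).  Missing cells are empty.
#' A JSON schema file may map non-canonical column names onto these.
#'
#' @param path CSV file path.
#' @param schema optional path to a JSON object mapping canonical column
#'   names to the file's column names, or an equivalent named list.
#' @return a \code{microsim_cohort} data frame (row per participant-year)
#'   with an \code{imputed} attribute tracking imputed cells.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) .stopf("cohort file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  if (!is.null(schema)) {
    map <- if (is.character(schema)) jsonlite::read_json(schema) else schema
    for (canon in names(map)) {
      src <- map[[canon]]
      if (!src %in% names(df))
        .stopf("schema maps '%s' to missing column '%s'", canon, src)
      names(df)[names(df) == src] <- canon
    }
  }
  req <- c("id", "arm", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss))
    .stopf("cohort file lacks required column(s): %s",
           paste(miss, collapse = ", "))
  if (!"year" %in% names(df)) df$year <- "0"
  num_cols <- intersect(c("year", "age", "diabetes_duration", "height",
                          "fu_years", .CONT_FACTORS), names(df))
  bool_cols <- intersect(c(.BOOL_FACTORS, .PRIOR_EVENTS), names(df))
  for (cl in c(num_cols, bool_cols)) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      .stopf("unparseable value '%s' in field '%s' for participant id '%s'",
             raw[bad[1]], cl, df$id[bad[1]])
    if (cl %in% bool_cols && any(!val[!is.na(val)] %in% 0:1))
      .stopf("field '%s' must be 0/1", cl)
    df[[cl]] <- val
  }
  bad_arm <- setdiff(unique(df$arm), c("active", "placebo"))
  if (length(bad_arm))
    .stopf("unknown arm label(s): %s",
           paste(sQuote(bad_arm), collapse = ", "))
  new_cohort(df)
}

#' Construct/validate a cohort object
#'
#' Checks the cohort invariants (positive age, non-negative diabetes
#' duration, strictly increasing year indices within participant, two-level
#' arm) and attaches the imputation-tracking attribute.
#'
#' @param df data frame in the \code{\link{read_cohort}} dialect.
#' @return a \code{microsim_cohort}.
#' @export
new_cohort <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"year" %in% names(df)) df$year <- 0
  if (nrow(df)) {
    if (any(bad <- !df$arm %in% c("active", "placebo")))
      .stopf("unknown arm label(s): %s",
             paste(sQuote(unique(df$arm[bad])), collapse = ", "))
    base <- df[df$year == 0, ]
    if (any(!is.na(base$age) & base$age <= 0)) .stopf("age must be > 0")
    if (!is.null(df$diabetes_duration) &&
        any(!is.na(base$diabetes_duration) & base$diabetes_duration < 0))
      .stopf("diabetes_duration must be >= 0")
    ord <- order(df$id, df$year)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    inc <- tapply(df$year, df$id, function(y) all(diff(y) > 0))
    if (any(!inc)) .stopf("year indices must be strictly increasing per id")
  }
  imp <- matrix(FALSE, nrow(df), length(.CONT_FACTORS),
                dimnames = list(NULL, .CONT_FACTORS))
  structure(df, imputed = imp, class = c("microsim_cohort", "data.frame"))
}

#' @export
print.microsim_cohort <- function(x, ...) {
  n <- length(unique(x$id))
  cat(sprintf("Cohort: %d participants, %d participant-year rows, arms: %s\n",
              n, nrow(x),
              paste(sprintf("%s=%d", names(table(x$arm[x$year == 0])),
                            table(x$arm[x$year == 0])), collapse = ", ")))
  invisible(x)
}

#' Number of participants in a cohort
#' @param cohort a \code{microsim_cohort}.
#' @return integer count of distinct participants.
#' @export
n_participants <- function(cohort) length(unique(cohort$id))

#' Fraction of cells flagged as imputed for a factor
#' @param cohort a \code{microsim_cohort} after imputation.
#' @param factor continuous factor name.
#' @param years restrict to these year indices (default baseline only).
#' @return fraction in [0, 1].
#' @export
imputed_fraction <- function(cohort, factor, years = 0) {
  imp <- attr(cohort, "imputed")
  sel <- cohort$year %in% years
  mean(imp[sel, factor])
}

.set_imputed <- function(cohort, rows, factor) {
  imp <- attr(cohort, "imputed")
  imp[rows, factor] <- TRUE
  attr(cohort, "imputed") <- imp
  cohort
}

# Values outside the admissible window count as missing.
.in_range <- function(x, lr) !is.na(x) & x >= lr$min & x <= lr$max

#' Replace missing baseline values by age- and sex-adjusted means
#'
#' For each covered factor, baseline values that are missing or lie outside
#' the prespecified model limits are replaced by the mean of in-range
#' observed values among participants of the same sex and age band.  An
#' empty stratum falls back to the whole-study in-range mean; a factor
#' missing for the whole study falls back to the configured population
#' average from the limits table.
#'
#' Covers the factors whose missingness is low (by default HbA1c, systolic
#' blood pressure, weight, heart rate and eGFR); factors that are missing
#' not at random are handled by \code{\link{impute_stratified}}.
#'
#' @param cohort a \code{microsim_cohort}.
#' @param limits factor limits table, see \code{\link{default_factor_limits}}.
#' @param age_bands interior age band edges (default 55/65/75).
#' @param factors factors to cover.
#' @return the cohort with covered baseline cells complete and flagged.
#' @export
impute_mean_substitution <- function(cohort, limits = default_factor_limits(),
                                     age_bands = default_age_bands(),
                                     factors = c("hba1c", "sbp", "weight",
                                                 "heart_rate", "egfr")) {
  if (!nrow(cohort)) return(cohort)
  b <- cohort$year == 0
  band <- .age_band(cohort$age, age_bands)
  for (f in factors) {
    lr <- .limits_row(limits, f)
    x <- cohort[[f]]
    if (is.null(x)) x <- rep(NA_real_, nrow(cohort))
    ok <- .in_range(x, lr)
    need <- b & !ok
    if (!any(need)) { cohort[[f]] <- x; next }
    study_mean <- if (any(b & ok)) mean(x[b & ok]) else lr$population_mean
    key <- paste(cohort$sex, band)
    means <- tapply(x[b & ok], key[b & ok], mean)
    fill <- means[key[need]]
    fill[is.na(fill)] <- study_mean
    x[need] <- as.numeric(fill)
    cohort[[f]] <- x
    cohort <- .set_imputed(cohort, which(need), f)
  }
  cohort
}

# Baseline prior-cardiovascular-event indicator used as an imputation stratum.
.prior_cv <- function(cohort) {
  flags <- intersect(c("prior_mi", "prior_stroke", "prior_ihd"), names(cohort))
  if (!length(flags)) return(rep(0L, nrow(cohort)))
  v <- rep(0L, nrow(cohort))
  for (f in flags) v <- pmax(v, ifelse(is.na(cohort[[f]]), 0L, cohort[[f]]))
  v
}

#' Stratified imputation for factors missing not at random
#'
#' HDL-cholesterol, LDL-cholesterol and haemoglobin are typically missing at
#' high frequencies and not at random, so rather than a global mean they are
#' imputed within sex x age-band x prior-cardiovascular-event strata: each
#' missing baseline cell is drawn from the empirical distribution (or, per
#' \code{method}, the mean) of in-range observed values in its stratum, with
#' a fallback chain that drops the prior-event split, then the age band,
#' then uses the whole study.  Draws are deterministic given \code{seed}.
#'
#' @param cohort a \code{microsim_cohort}.
#' @param factors factors to cover.
#' @param limits factor limits table.
#' @param age_bands interior age band edges.
#' @param method \code{"sample"} (empirical draw, default) or \code{"mean"}.
#' @param seed integer seed controlling the empirical draws.
#' @return the cohort with covered baseline cells complete and flagged.
#' @export
impute_stratified <- function(cohort, factors = c("hdl", "ldl", "haemoglobin"),
                              limits = default_factor_limits(),
                              age_bands = default_age_bands(),
                              method = c("sample", "mean"), seed = 1) {
  method <- match.arg(method)
  if (!nrow(cohort)) return(cohort)
  b <- cohort$year == 0
  band <- .age_band(cohort$age, age_bands)
  cv <- .prior_cv(cohort)
  strata <- list(paste(cohort$sex, band, cv),
                 paste(cohort$sex, band),
                 cohort$sex,
                 rep("all", nrow(cohort)))
  for (f in factors) {
    lr <- .limits_row(limits, f)
    x <- cohort[[f]]
    if (is.null(x)) x <- rep(NA_real_, nrow(cohort))
    ok <- .in_range(x, lr)
    need <- which(b & !ok)
    if (!length(need)) { cohort[[f]] <- x; next }
    if (!any(b & ok))
      .stopf("factor '%s': no observed in-range values in any stratum", f)
    set.seed(.child_seed(seed, "stratified", f))
    unfilled <- need
    for (s in strata) {
      if (!length(unfilled)) break
      pools <- split(x[b & ok], s[b & ok])
      for (lv in unique(s[unfilled])) {
        cells <- unfilled[s[unfilled] == lv]
        donors <- pools[[lv]]
        if (is.null(donors)) next
        x[cells] <- if (method == "mean") mean(donors)
                    else donors[sample.int(length(donors), length(cells),
                                           replace = TRUE)]
        unfilled <- setdiff(unfilled, cells)
      }
    }
    cohort[[f]] <- x
    cohort <- .set_imputed(cohort, need, f)
  }
  cohort
}

#' Fill missing annualized follow-up values from progression equations
#'
#' Ensures every participant has a complete risk-factor record for years
#' 1..floor(horizon).  Missing continuous cells are generated by applying
#' the factor's progression equation forward from the most recent available
#' (observed or previously filled) value, so observed mid-trial values
#' anchor later fills; generated values are clamped to the model limits.
#' Observed values are never overwritten.  Boolean factors carry the last
#' observation forward.
#'
#' @param cohort a \code{microsim_cohort} with complete baseline.
#' @param coefficients a \code{\link{coefficient_set}} whose progression
#'   equations cover every continuous annualized factor.
#' @param horizon follow-up horizon in years.
#' @param limits factor limits table.
#' @return the cohort, with one row per participant for every year
#'   0..floor(horizon) and no missing risk-factor cells.
#' @export
fill_followup <- function(cohort, coefficients, horizon,
                          limits = default_factor_limits()) {
  if (!nrow(cohort)) return(cohort)
  years <- 0:floor(horizon)
  prog <- .eqs_of_kind(coefficients, "progression")
  old_imp <- attr(cohort, "imputed")
  old_key <- paste(cohort$id, cohort$year)
  base <- cohort[cohort$year == 0, , drop = FALSE]
  for (f in .CONT_FACTORS) {
    if (is.null(base[[f]]) || anyNA(base[[f]]))
      .stopf("baseline must be fully imputed before fill_followup ('%s' missing)", f)
  }
  # expand to a full participant x year grid, keeping observed rows
  full <- merge(data.frame(id = base$id), data.frame(year = years))
  df <- merge(full, as.data.frame(cohort), by = c("id", "year"),
              all.x = TRUE, sort = FALSE)
  df <- df[order(df$id, df$year), , drop = FALSE]
  rownames(df) <- NULL
  # demographics and prior flags are baseline-constant: propagate
  const_cols <- intersect(c("arm", "age", "sex", "race", "diabetes_duration",
                            "height", "fu_years", .PRIOR_EVENTS), names(df))
  bidx <- match(df$id, base$id)
  for (cl in const_cols) df[[cl]] <- base[[cl]][bidx]
  observed <- !is.na(as.matrix(df[, intersect(.CONT_FACTORS, names(df)),
                                  drop = FALSE]))
  ny <- length(years)
  for (f in .CONT_FACTORS) {
    x <- df[[f]]
    fills <- is.na(x)
    if (any(fills) && is.null(prog[[f]]))
      .stopf("factor '%s' has missing follow-up values and no progression equation", f)
    if (!any(fills)) next
    lr <- .limits_row(limits, f)
    eq <- prog[[f]]
    xm <- matrix(x, nrow = ny)       # years x participants
    dur0 <- base$diabetes_duration[match(unique(df$id), base$id)]
    if (is.null(dur0)) dur0 <- rep(0, ncol(xm))
    dur0[is.na(dur0)] <- 0
    for (y in seq_len(ny)[-1]) {
      missy <- is.na(xm[y, ])
      if (!any(missy)) next
      st <- list(current = xm[y - 1, missy],
                 diabetes_duration = dur0[missy] + (y - 1))
      nxt <- eq$intercept
      for (nm in names(eq$coefficients)) {
        v <- st[[nm]]
        if (is.null(v))
          .stopf("progression equation '%s': covariate '%s' unavailable in follow-up fill",
                 f, nm)
        ctr <- if (nm %in% names(eq$centers)) eq$centers[[nm]] else 0
        nxt <- nxt + eq$coefficients[[nm]] * (v - ctr)
      }
      xm[y, missy] <- clamp(nxt, lr$min, lr$max)
    }
    df[[f]] <- as.vector(xm)
  }
  for (f in .BOOL_FACTORS) {
    if (is.null(df[[f]])) { df[[f]] <- 0; next }
    xm <- matrix(df[[f]], nrow = ny)
    for (y in seq_len(ny)[-1]) {
      missy <- is.na(xm[y, ])
      xm[y, missy] <- xm[y - 1, missy]
    }
    xm[is.na(xm)] <- 0
    df[[f]] <- as.vector(xm)
  }
  out <- new_cohort(df)
  imp <- attr(out, "imputed")
  cf <- intersect(.CONT_FACTORS, colnames(observed))
  imp[, cf] <- !observed[, cf]
  # carry forward flags set by the baseline imputation steps
  m <- match(paste(out$id, out$year), old_key)
  hit <- which(!is.na(m))
  imp[hit, ] <- imp[hit, , drop = FALSE] | old_imp[m[hit], , drop = FALSE]
  attr(out, "imputed") <- imp
  out
}

#' One-call imputation policy
#'
#' Applies, in order: mean substitution for the low-missingness factors,
#' stratified imputation for the missing-not-at-random factors, a population
#' -average backstop for any continuous factor still incomplete at baseline,
#' defaulting of missing boolean/prior flags to 0, and follow-up fill-in
#' from the progression equations.
#'
#' @inheritParams fill_followup
#' @param age_bands interior age band edges.
#' @param seed seed for the stratified empirical draws.
#' @return a complete cohort ready for simulation.
#' @export
impute_cohort <- function(cohort, coefficients, horizon,
                          limits = default_factor_limits(),
                          age_bands = default_age_bands(), seed = 1) {
  cohort <- impute_mean_substitution(cohort, limits, age_bands)
  cohort <- impute_stratified(cohort, limits = limits, age_bands = age_bands,
                              seed = seed)
  b <- cohort$year == 0
  for (f in .CONT_FACTORS) {
    lr <- .limits_row(limits, f)
    x <- cohort[[f]]
    if (is.null(x)) x <- rep(NA_real_, nrow(cohort))
    need <- b & !.in_range(x, lr)
    if (any(need)) {
      fallback <- if (any(b & .in_range(x, lr)))
        mean(x[b & .in_range(x, lr)]) else lr$population_mean
      x[need] <- fallback
      cohort[[f]] <- x
      cohort <- .set_imputed(cohort, which(need), f)
    } else cohort[[f]] <- x
  }
  for (f in c(.BOOL_FACTORS, .PRIOR_EVENTS)) {
    if (is.null(cohort[[f]])) cohort[[f]] <- 0
    cohort[[f]][is.na(cohort[[f]])] <- 0
  }
  if (is.null(cohort$diabetes_duration)) cohort$diabetes_duration <- 0
  cohort$diabetes_duration[is.na(cohort$diabetes_duration)] <- 0
  if (is.null(cohort$height)) cohort$height <- 168
  if (is.null(cohort$race)) cohort$race <- "white"
  fill_followup(cohort, coefficients, horizon, limits)
}
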