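# Fixtures are built in code; nothing is read from disk.

# A complete baseline cohort with constant, in-range risk factors.
make_cohort <- function(n = 10, arm = rep(c("active", "placebo"), length.out = n),
                        age = 65, hba1c = 7.5, sbp = 135, seed = NULL, ...) {
  extra <- list(...)
  df <- data.frame(
    id = sprintf("S%04d", seq_len(n)), arm = arm, year = 0,
    age = age, sex = rep(c("male", "female"), length.out = n),
    race = "white", diabetes_duration = 8, height = 168,
    weight = 85, hdl = 1.1, ldl = 2.5, sbp = sbp, hba1c = hba1c,
    heart_rate = 72, wbc = 7.5, haemoglobin = 13.8, egfr = 75,
    smoker = 0, afib = 0, pad = 0, albuminuria = 0,
    prior_ihd = 0, prior_hf = 0, prior_amputation = 0, prior_blindness = 0,
    prior_kidney_failure = 0, prior_mi = 0, prior_stroke = 0, prior_ulcer = 0,
    stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  new_cohort(df)
}

# Identity progression equations (next = current) for every continuous factor.
identity_progressions <- function() {
  lapply(t2dsim:::.CONT_FACTORS, function(f)
    eq_spec(f, "progression", "linear", intercept = 0,
            coefficients = c(current = 1)))
}

# Coefficient set with one constant-hazard death equation (all-cause).
const_death_set <- function(h) {
  coefficient_set(c(list(eq_spec("noncv_death", "death", "exponential",
                                 intercept = log(h))),
                    identity_progressions()),
                  version = "const-death-test")
}

# Single-endpoint event set with covariate-driven exponential hazard and
# identity progression: the engine's discrete annual incidence then equals
# the continuous-time exponential incidence exactly.
single_event_set <- function(name = "mace3", intercept = log(0.04),
                             coefficients = c(hba1c = 0.25, sbp = 0.01),
                             centers = c(hba1c = 7.5, sbp = 135)) {
  coefficient_set(c(list(eq_spec(name, "event", "exponential",
                                 intercept = intercept,
                                 coefficients = coefficients,
                                 centers = centers)),
                    identity_progressions()),
                  version = "single-event-test")
}

# Brute-force Harrell's C by exhaustive pair enumeration.
brute_force_c <- function(risk, time, event) {
  n <- length(risk); conc <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    first <- if (time[i] < time[j]) i
             else if (time[j] < time[i]) j
             else if (event[i] != event[j]) c(i, j)[which.max(c(event[i], event[j]))]
             else next
    other <- c(i, j)[c(i, j) != first]
    if (event[first] != 1) next
    pairs <- pairs + 1
    conc <- conc + (risk[first] > risk[other]) +
      0.5 * (risk[first] == risk[other])
  }
  conc / pairs
}

# Brute-force Cox partial likelihood (no ties) maximised on a grid.
grid_cox <- function(time, event, x, lo = -3, hi = 3, step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  ll <- vapply(betas, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    s
  }, 0)
  betas[which.max(ll)]
}

# Two-stage grid maximisation of the 2-parameter logistic log-likelihood
# of obs on logit(pred).
grid_logistic <- function(lg, obs) {
  ll <- function(a, b) {
    eta <- a + b * lg
    sum(obs * eta - log1p(exp(eta)))
  }
  best <- c(0, 1)
  for (step in c(0.1, 0.01, 1e-3)) {
    as <- seq(best[1] - 10 * step, best[1] + 10 * step, by = step)
    bs <- seq(best[2] - 10 * step, best[2] + 10 * step, by = step)
    vals <- outer(as, bs, Vectorize(ll))
    w <- arrayInd(which.max(vals), dim(vals))
    best <- c(as[w[1]], bs[w[2]])
  }
  c(intercept = best[1], slope = best[2])
}

# One-parameter grid for the offset calibration intercept.
grid_offset_intercept <- function(lg, obs) {
  ll <- function(a) { eta <- a + lg; sum(obs * eta - log1p(exp(eta))) }
  best <- 0
  for (step in c(0.1, 0.01, 1e-3)) {
    as <- seq(best - 10 * step, best + 10 * step, by = step)
    best <- as[which.max(vapply(as, ll, 0))]
  }
  best
}

write_temp_cohort_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  f
}
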