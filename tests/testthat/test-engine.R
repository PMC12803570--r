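test_that("cycle structure splits a fractional horizon into full plus partial cycles", {
  cs3 <- t2dsim:::.cycle_structure(3.0)
  expect_equal(cs3$len, c(1, 1, 1))
  cs32 <- t2dsim:::.cycle_structure(3.2)
  expect_equal(cs32$len, c(1, 1, 1, 0.2), tolerance = 1e-9)
  expect_equal(cs32$start, c(0, 1, 2, 3), tolerance = 1e-9)
  expect_error(t2dsim:::.cycle_structure(0), "horizon")
})

test_that("null hazards advance the cohort without events; certain death absorbs", {
  coh <- make_cohort(4)
  null_set <- coefficient_set(c(list(
    eq_spec("mi", "event", "exponential", intercept = -Inf),
    eq_spec("noncv_death", "death", "exponential", intercept = -Inf)),
    identity_progressions()), version = "null")
  sim <- simulate(outcomes_model(null_set), nsim = 10, seed = 1,
                  cohort = coh, horizon = 3)
  expect_equal(sum(sim$event$mi), 0)
  expect_equal(sum(sim$event$acm), 0)

  sure <- coefficient_set(c(list(
    eq_spec("mi", "event", "exponential", intercept = -Inf),
    eq_spec("noncv_death", "death", "exponential", intercept = 20)),
    identity_progressions()), version = "sure-death")
  sim2 <- simulate(outcomes_model(sure), nsim = 10, seed = 1,
                   cohort = coh, horizon = 3)
  expect_true(all(sim2$event$acm))
  expect_true(all(sim2$cycle$acm == 1))   # death in the first cycle
  expect_equal(sum(sim2$event$mi), 0)     # no events after death
  expect_equal(sum(sim2$event$cv_death), 0)  # non-CV death class
})

test_that("simulation is seed-reproducible and independent of cohort row order", {
  coh <- make_cohort(6, hba1c = seq(6, 9, length.out = 6))
  m <- outcomes_model(single_event_set())
  s1 <- simulate(m, nsim = 50, seed = 9, cohort = coh, horizon = 3)
  s2 <- simulate(m, nsim = 50, seed = 9, cohort = coh, horizon = 3)
  expect_identical(s1$event, s2$event)
  expect_identical(s1$cycle, s2$cycle)

  perm <- sample(nrow(coh))
  coh_shuffled <- new_cohort(as.data.frame(coh)[perm, ])
  s3 <- simulate(m, nsim = 50, seed = 9, cohort = coh_shuffled, horizon = 3)
  o <- match(s1$ids, s3$ids)
  expect_identical(s1$event$mace3, s3$event$mace3[, o])

  s4 <- simulate(m, nsim = 50, seed = 10, cohort = coh, horizon = 3)
  expect_false(identical(s1$event$mace3, s4$event$mace3))
})

test_that("death is absorbing and composites nest in every replication", {
  coh <- make_cohort(40, hba1c = runif(40, 6, 10))
  sim <- simulate(outcomes_model(illustrative_coefficients()), nsim = 40,
                  seed = 3, cohort = coh, horizon = 3)
  acm_cyc <- sim$cycle$acm
  for (nm in c("mi", "stroke", "ihd", "hf", "cv_death")) {
    cyc <- sim$cycle[[nm]]
    both <- !is.na(cyc) & !is.na(acm_cyc)
    expect_true(all(cyc[both] <= acm_cyc[both]), info = nm)
  }
  expect_true(all(sim$event$cv_death <= sim$event$acm))
  mace3 <- t2dsim:::.endpoint_matrices(sim, "mace3")$event
  mace4 <- t2dsim:::.endpoint_matrices(sim, "mace4")$event
  expect_true(all(sim$event$cv_death <= mace3))
  expect_true(all(mace3 <= mace4))
  expect_identical(mace3, sim$event$cv_death | sim$event$mi | sim$event$stroke)
})

test_that("equation evaluation order is a fair permutation", {
  set.seed(1)
  U <- matrix(runif(6000 * 4), 6000, 4)
  pos <- t2dsim:::.row_permutation(U)
  expect_true(all(apply(pos, 1, sort) == 1:4))
  # each equation occupies each position with frequency ~ 1/4
  freq <- colMeans(pos == 1)
  se <- sqrt(0.25 * 0.75 / 6000)
  expect_true(all(abs(freq - 0.25) < 4 * se))
})

test_that("constant-hazard mortality matches the closed-form survival curve", {
  h <- 0.2; horizon <- 3; reps <- 4000
  coh <- make_cohort(1)
  sim <- simulate(outcomes_model(const_death_set(h)), nsim = reps, seed = 11,
                  cohort = coh, horizon = horizon)
  p_true <- 1 - exp(-h * horizon)
  se <- sqrt(p_true * (1 - p_true) / reps)
  expect_lt(abs(mean(sim$event$acm) - p_true), 3 * se)
})

test_that("a fractional horizon adds a shortened final cycle", {
  h <- 0.3
  coh <- make_cohort(1)
  reps <- 4000
  sim <- simulate(outcomes_model(const_death_set(h)), nsim = reps, seed = 13,
                  cohort = coh, horizon = 3.2)
  expect_true(all(sim$cycle$acm[sim$event$acm] <= 4))
  p_true <- 1 - exp(-h * 3.2)
  se <- sqrt(p_true * (1 - p_true) / reps)
  expect_lt(abs(mean(sim$event$acm) - p_true), 3 * se)
  # deaths recorded in the partial cycle occur at its shortened rate
  p4 <- mean(!is.na(sim$cycle$acm) & sim$cycle$acm == 4)
  p4_true <- exp(-h * 3) * (1 - exp(-h * 0.2))
  expect_lt(abs(p4 - p4_true), 3 * sqrt(p4_true * (1 - p4_true) / reps))
})

test_that("first-event summaries match a binomial oracle and honour restrictions", {
  # single arm of 1000, known constant event hazard
  h <- 0.05
  coh <- make_cohort(1000, arm = rep(c("active", "placebo"), 500))
  set <- coefficient_set(c(list(
    eq_spec("mace3", "event", "exponential", intercept = log(h))),
    identity_progressions()), version = "binom")
  sim <- simulate(outcomes_model(set), nsim = 50, seed = 21,
                  cohort = coh, horizon = 3)
  fes <- first_event_summary(sim, "mace3")
  p_true <- 1 - exp(-3 * h)
  se <- sqrt(p_true * (1 - p_true) / (500 * 50))
  expect_lt(abs(fes$proportion[1] - p_true), 3 * se)
  expect_lt(abs(fes$proportion[2] - p_true), 3 * se)

  # zero hazards: zero counts in both arms
  null_sim <- simulate(outcomes_model(const_death_set(1e-12)), nsim = 5,
                       seed = 1, cohort = coh, horizon = 3)
  expect_equal(first_event_summary(null_sim, "acm")$count, c(0, 0))

  # prior-HF participants leave both numerator and denominator of hf
  coh2 <- make_cohort(100, prior_hf = rep(c(1, 0), 50))
  sim2 <- simulate(outcomes_model(illustrative_coefficients()), nsim = 20,
                   seed = 5, cohort = coh2, horizon = 3)
  fes2 <- first_event_summary(sim2, "hf")
  expect_equal(sum(fes2$denominator), 50)
  prior_idx <- which(as.data.frame(coh2)$prior_hf == 1)
  expect_equal(sum(sim2$event$hf[, prior_idx]), 0)
})

test_that("event flags feed back into later-cycle hazards", {
  # an MI raises subsequent CV-death hazard via the event_mi flag
  set <- coefficient_set(c(list(
    eq_spec("mi", "event", "exponential", intercept = log(0.4)),
    eq_spec("cv_death", "death", "exponential", intercept = log(0.01),
            coefficients = c(event_mi = 3), fatal_class = "cv")),
    identity_progressions()), version = "feedback")
  coh <- make_cohort(1)
  sim <- simulate(outcomes_model(set), nsim = 3000, seed = 8,
                  cohort = coh, horizon = 3)
  had_mi_y1 <- sim$event$mi[, 1] & sim$cycle$mi[, 1] == 1
  died_later <- sim$event$cv_death[, 1] & sim$cycle$cv_death[, 1] > 1
  p_death_mi <- mean(died_later[had_mi_y1])
  p_death_nomi <- mean(died_later[!sim$event$mi[, 1]])
  expect_gt(p_death_mi, 2 * p_death_nomi)
})

test_that("analytic predictions match Monte Carlo risks for a single endpoint", {
  coh <- make_cohort(5, hba1c = seq(6, 10, 1))
  m <- outcomes_model(single_event_set())
  pr <- predict(m, coh, horizon = 3)
  h <- exp(log(0.04) + 0.25 * (seq(6, 10, 1) - 7.5))
  expect_equal(pr$mace3, 1 - exp(-3 * h), tolerance = 1e-9)
  sim <- simulate(m, nsim = 4000, seed = 2, cohort = coh, horizon = 3)
  mc <- predicted_risk(sim, "mace3")
  se <- sqrt(pr$mace3 * (1 - pr$mace3) / 4000)
  expect_true(all(abs(mc - pr$mace3) < 4 * se))
})

test_that("simulated outcomes serialise with their metadata sidecar", {
  coh <- make_cohort(5)
  sim <- simulate(outcomes_model(const_death_set(0.3)), nsim = 5, seed = 4,
                  cohort = coh, horizon = 2)
  d <- tempfile()
  write_outcomes(sim, d)
  ev <- utils::read.csv(file.path(d, "simulated-events.csv"))
  expect_equal(sum(ev$endpoint == "acm"), sum(sim$event$acm))
  meta <- jsonlite::read_json(file.path(d, "run-metadata.json"))
  expect_equal(meta$replications, 5)
  expect_equal(meta$seed, 4)
})
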