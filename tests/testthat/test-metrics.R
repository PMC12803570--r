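test_that("relative risk divides arm proportions and rounds half-up", {
  expect_equal(relative_risk(100, 1000, 100, 1000), 1.00)  # symmetry
  expect_equal(relative_risk(30, 200, 20, 300), 2.25)  # (0.15)/(0.0667)
  expect_warning(rr <- relative_risk(5, 100, 0, 100), "undefined")
  expect_true(is.na(rr))
  expect_equal(relative_risk(1, 8, 2, 8, dp = NULL), 0.5)
  expect_error(relative_risk(10, 5, 1, 8), "events_a")
})

test_that("half-up rounding follows report-table convention", {
  expect_equal(t2dsim:::round_half_up(0.985, 2), 0.99)
  expect_equal(t2dsim:::round_half_up(0.105, 2), 0.11)
  expect_equal(t2dsim:::round_half_up(11.45, 1), 11.5)
  expect_equal(t2dsim:::round_half_up(-0.985, 2), -0.99)
})

test_that("Cox hazard ratio matches exchangeability and a grid-search oracle", {
  # identical arms: HR 1 within 1e-6
  tt <- c(1, 2, 3, 4, 5)
  obs <- data.frame(arm = rep(c("active", "placebo"), each = 5),
                    time = c(tt, tt), event = 1)
  expect_equal(cox_hr(obs)$hr, 1, tolerance = 1e-6)

  # 6-subject no-ties instance against brute-force partial likelihood
  time <- c(1.2, 2.5, 4.0, 0.8, 3.1, 5.0)
  event <- c(1, 1, 0, 1, 1, 1)
  arm <- c("active", "active", "active", "placebo", "placebo", "placebo")
  fit <- cox_hr(data.frame(arm = arm, time = time, event = event))
  beta_grid <- grid_cox(time, event, as.numeric(arm == "active"))
  expect_lt(abs(log(fit$hr) - beta_grid), 1e-4)

  expect_error(cox_hr(data.frame(arm = arm, time = time, event = 0)),
               "no events")
  expect_error(cox_hr(data.frame(arm = "active", time = 1, event = 1)),
               "arms")
})

test_that("Kaplan-Meier cumulative incidence matches the hand product-limit table", {
  time <- c(1, 2, 2, 3, 4, 5, 6, 7)
  event <- c(1, 1, 1, 0, 1, 0, 1, 0)
  ci <- cumulative_incidence(time, event)
  # hand product-limit: S(1)=7/8, S(2)=7/8*5/7, S(4)=...*3/4, S(6)=...*1/2
  fn <- attr(ci, "fn")
  expect_equal(fn(1), 1 - 7/8)
  expect_equal(fn(2.5), 1 - 7/8 * 5/7)
  expect_equal(fn(4), 1 - 7/8 * 5/7 * 3/4)
  expect_equal(fn(6.9), 1 - 7/8 * 5/7 * 3/4 * 1/2)
  expect_true(all(diff(ci$incidence) >= 0))
  expect_equal(fn(0.5), 0)

  # no censoring: reduces to the empirical CDF
  t2 <- c(3, 1, 2, 5)
  ci2 <- cumulative_incidence(t2, rep(1, 4))
  expect_equal(attr(ci2, "fn")(c(1, 2, 3, 5)), c(1, 2, 3, 4) / 4)
  # all censored: identically zero
  ci3 <- cumulative_incidence(t2, rep(0, 4))
  expect_true(all(ci3$incidence == 0))
  expect_error(cumulative_incidence(c(-1, 2), c(1, 1)), "negative")
})

test_that("Brier score is the mean squared risk error with the 0.25 informativeness bound", {
  expect_equal(brier(c(0, 1, 1, 0), c(0, 1, 1, 0))$score, 0)
  expect_equal(brier(rep(1, 5), rep(0, 5))$score, 1)
  b <- brier(c(0.2, 0.6, 0.9), c(0, 1, 1))
  expect_equal(b$score, (0.04 + 0.16 + 0.01) / 3, tolerance = 1e-12)
  expect_true(b$informative)
  expect_false(brier(rep(1, 5), rep(0, 5))$informative)
})

test_that("Harrell's C matches exhaustive pair enumeration and flips under negation", {
  # perfect discrimination, no censoring
  risk <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  time <- 1:5
  expect_equal(harrell_c(risk, time, rep(1, 5))$c, 1)

  # 5-subject hand example with one censored subject
  risk2 <- c(0.8, 0.3, 0.6, 0.2, 0.5)
  time2 <- c(1, 4, 2, 5, 3)
  event2 <- c(1, 1, 0, 1, 1)
  got <- harrell_c(risk2, time2, event2)
  expect_equal(got$c, brute_force_c(risk2, time2, event2))
  # comparable pairs: all pairs except those where the censored subject (3)
  # has the shorter or equal time and no event: (3,2),(3,4),(3,5) drop
  expect_equal(got$pairs, 10 - 3)

  # negating the ranking maps C to 1 - C
  expect_equal(harrell_c(-risk2, time2, event2)$c, 1 - got$c)

  # random risks at large n sit near 0.5
  set.seed(77)
  n <- 3000
  rc <- harrell_c(runif(n), rexp(n), rbinom(n, 1, 0.7))
  expect_lt(abs(rc$c - 0.5), 0.03)

  # enumeration agreement on random censored instances
  for (i in 1:5) {
    set.seed(i)
    nn <- 12
    r <- runif(nn); tm <- round(rexp(nn), 1); ev <- rbinom(nn, 1, 0.6)
    got_i <- harrell_c(r, tm, ev)
    if (got_i$flagged) next
    expect_equal(got_i$c, brute_force_c(r, tm, ev), info = i)
  }

  # no comparable pairs: flagged
  expect_true(harrell_c(c(1, 2), c(1, 2), c(0, 0))$flagged)
})

test_that("concordance agrees with the survival package on tie-free data", {
  set.seed(123)
  n <- 400
  risk <- runif(n)
  time <- rexp(n, 0.2 * exp(risk))
  event <- as.integer(runif(n) < 0.8)
  ours <- harrell_c(risk, time, event)$c
  ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("calibration recovers its target values under self-consistency", {
  set.seed(31)
  n <- 50000
  pred <- stats::rbeta(n, 2, 8)
  obs <- stats::rbinom(n, 1, pred)
  cal <- calibration(pred, obs)
  expect_lt(abs(cal$slope - 1), 3 * cal$slope_se)
  expect_lt(abs(cal$intercept - 0), 3 * cal$intercept_se)
  expect_equal(sum(cal$deciles$n), n)
  expect_true(all(cal$deciles$obs_prop >= 0 & cal$deciles$obs_prop <= 1))
})

test_that("uniformly doubled odds shifts the calibration intercept to -log 2", {
  set.seed(32)
  n <- 60000
  p0 <- stats::rbeta(n, 2, 6)
  obs <- stats::rbinom(n, 1, p0)                   # true risks
  pred <- stats::plogis(stats::qlogis(p0) + log(2))  # overestimated risks
  cal <- calibration(pred, obs)
  expect_lt(abs(cal$intercept - (-log(2))), 3 * cal$intercept_se)
  expect_lt(cal$intercept, 0)  # overestimation is negative
})

test_that("calibration fits match a brute-force likelihood grid on a hand dataset", {
  set.seed(33)
  pred <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5,
            0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.12, 0.48)
  obs <- c(0, 0, 0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0, 0)
  lg <- stats::qlogis(pred)
  cal <- calibration(pred, obs)
  gr <- grid_logistic(lg, obs)
  expect_lt(abs(cal$slope - gr["slope"]), 1e-3)
  gi <- grid_offset_intercept(lg, obs)
  expect_lt(abs(cal$intercept - gi), 1e-3)
})

test_that("degenerate calibration inputs are flagged, not fabricated", {
  cal <- calibration(rep(0.3, 50), rbinom(50, 1, 0.3))
  expect_true(cal$flagged)
  expect_true(is.na(cal$slope))
  expect_false(is.na(cal$intercept))  # offset intercept still defined
})

test_that("fixed-horizon outcomes exclude early-censored subjects", {
  hz <- horizon_outcomes(time = c(1, 2, 3, 2.5, 3.5),
                         event = c(1, 0, 0, 1, 0), horizon = 3)
  expect_equal(hz$obs, c(1, 0, 0, 1, 0))
  expect_equal(hz$keep, c(TRUE, FALSE, TRUE, TRUE, TRUE))
})
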