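test_that("cohort CSV ingestion preserves rows, missing cells, and errors on contract violations", {
  df <- as.data.frame(make_cohort(5))
  df$hba1c[2] <- NA
  f <- write_temp_cohort_csv(df)
  coh <- read_cohort(f)
  expect_equal(n_participants(coh), 5)
  expect_true(is.na(coh$hba1c[coh$id == "S0002"]))

  # header-only file: empty cohort, no error
  f0 <- write_temp_cohort_csv(df[0, ])
  expect_equal(n_participants(read_cohort(f0)), 0)

  # third arm label rejected, naming the offender
  df2 <- df; df2$arm[3] <- "openlabel"
  expect_error(read_cohort(write_temp_cohort_csv(df2)), "openlabel")

  # missing required column named
  df3 <- df; df3$arm <- NULL
  expect_error(read_cohort(write_temp_cohort_csv(df3)), "arm")

  # unparseable numeric cell names id and field
  df4 <- df; df4$sbp <- as.character(df4$sbp); df4$sbp[4] <- "high"
  expect_error(read_cohort(write_temp_cohort_csv(df4)), "sbp.*S0004")

  # schema mapping of non-canonical column names
  df5 <- df; names(df5)[names(df5) == "hba1c"] <- "A1C"
  coh5 <- read_cohort(write_temp_cohort_csv(df5), schema = list(hba1c = "A1C"))
  expect_true("hba1c" %in% names(coh5))
})

test_that("mean substitution uses the age- and sex-adjusted stratum mean", {
  set.seed(3)
  n <- 120
  coh <- make_cohort(n, age = sample(40:85, n, TRUE),
                     hba1c = runif(n, 6, 10))
  df <- as.data.frame(coh)
  # a 60-year-old man with missing HbA1c
  df$age[1] <- 60; df$sex[1] <- "male"; df$hba1c[1] <- NA
  # and a woman with an impossible (out-of-range) value
  df$age[2] <- 48; df$sex[2] <- "female"; df$hba1c[2] <- 99
  coh <- new_cohort(df)
  out <- impute_mean_substitution(coh)

  # brute-force group-by oracle: males aged 55-64, observed in-range values
  band <- findInterval(df$age, c(55, 65, 75))
  ok <- !is.na(df$hba1c) & df$hba1c >= 4 & df$hba1c <= 15
  oracle1 <- mean(df$hba1c[ok & df$sex == "male" & band == 1])
  expect_equal(out$hba1c[1], oracle1, tolerance = 1e-12)
  oracle2 <- mean(df$hba1c[ok & df$sex == "female" & band == 0])
  expect_equal(out$hba1c[2], oracle2, tolerance = 1e-12)
  # observed in-range values untouched
  expect_equal(out$hba1c[-(1:2)], df$hba1c[-(1:2)])
  expect_equal(imputed_fraction(out, "hba1c"), 2 / n)

  # identity on a complete cohort
  full <- make_cohort(10)
  expect_equal(as.data.frame(impute_mean_substitution(full)),
               as.data.frame(full))
})

test_that("mean substitution equals an independent group-by oracle on random cohorts", {
  set.seed(19)
  for (rep in 1:3) {
    n <- 150
    coh <- make_cohort(n, age = sample(35:90, n, TRUE),
                       sbp = runif(n, 90, 200))
    df <- as.data.frame(coh)
    df$sbp[sample(n, 30)] <- NA
    out <- impute_mean_substitution(new_cohort(df))
    band <- findInterval(df$age, c(55, 65, 75))
    key <- paste(df$sex, band)
    ok <- !is.na(df$sbp)
    oracle <- tapply(df$sbp[ok], key[ok], mean)
    need <- which(!ok)
    expect_equal(out$sbp[need], as.numeric(oracle[key[need]]),
                 tolerance = 1e-12)
  }
})

test_that("stratified imputation fills all cells deterministically from stratum donors", {
  set.seed(5)
  n <- 200
  coh <- make_cohort(n, age = sample(40:85, n, TRUE),
                     haemoglobin = runif(n, 11, 16),
                     prior_mi = rbinom(n, 1, 0.4))
  df <- as.data.frame(coh)
  miss <- sample(n, 80)  # 40% missing
  df$haemoglobin[miss] <- NA
  coh <- new_cohort(df)
  out1 <- impute_stratified(coh, seed = 42)
  out2 <- impute_stratified(coh, seed = 42)
  expect_false(anyNA(out1$haemoglobin))
  expect_identical(out1$haemoglobin, out2$haemoglobin)  # seed determinism
  expect_equal(imputed_fraction(out1, "haemoglobin"), length(miss) / n)
  # observed values untouched; imputed values are actual donor values
  expect_equal(out1$haemoglobin[-miss], df$haemoglobin[-miss])
  expect_true(all(out1$haemoglobin[miss] %in% df$haemoglobin[-miss]))
  # different seed gives a different draw (overwhelmingly)
  out3 <- impute_stratified(coh, seed = 43)
  expect_false(identical(out1$haemoglobin, out3$haemoglobin))
  # identity when nothing is missing
  full <- make_cohort(10)
  expect_equal(as.data.frame(impute_stratified(full, seed = 1)),
               as.data.frame(full))
})

test_that("follow-up fill-in anchors on the last observed value and never overwrites", {
  coefs <- coefficient_set(c(list(
    eq_spec("mace3", "event", "exponential", intercept = log(0.02))),
    lapply(t2dsim:::.CONT_FACTORS, function(f)
      eq_spec(f, "progression", "linear",
              intercept = if (f == "hba1c") 0.1 else 0,
              coefficients = c(current = 1)))),
    version = "fill-test")

  coh <- make_cohort(2, hba1c = 7.0)
  out <- fill_followup(coh, coefs, horizon = 3)
  expect_equal(nrow(out), 2 * 4)
  # +0.1/yr drift from baseline 7.0 gives 7.3 at year 3 (direct recursion)
  expect_equal(out$hba1c[out$id == "S0001" & out$year == 3], 7.3)
  # all other factors follow identity dynamics: constant at baseline
  expect_true(all(out$sbp == 135))

  # an observed mid-trial value anchors later fills
  df <- as.data.frame(coh[coh$id == "S0001", ])
  y2 <- df; y2$year <- 2; y2$hba1c <- 9.0
  coh2 <- new_cohort(rbind(df, y2))
  out2 <- fill_followup(coh2, coefs, horizon = 4)
  expect_equal(out2$hba1c[out2$year == 2], 9.0)   # observed, untouched
  expect_equal(out2$hba1c[out2$year == 1], 7.1)   # forward from baseline
  expect_equal(out2$hba1c[out2$year == 3], 9.1)   # forward from observation
  expect_equal(out2$hba1c[out2$year == 4], 9.2)

  # complete follow-up is returned unchanged
  out3 <- fill_followup(out, coefs, horizon = 3)
  expect_equal(out3$hba1c, out$hba1c)
})

test_that("generated values are clamped to the model limits", {
  coefs <- coefficient_set(c(list(
    eq_spec("mace3", "event", "exponential", intercept = log(0.02))),
    lapply(t2dsim:::.CONT_FACTORS, function(f)
      eq_spec(f, "progression", "linear",
              intercept = if (f == "egfr") -40 else 0,
              coefficients = c(current = 1)))),
    version = "clamp-test")
  coh <- make_cohort(1, egfr = 50)
  out <- fill_followup(coh, coefs, horizon = 3)
  lim <- default_factor_limits()
  lo <- lim$min[lim$factor == "egfr"]
  expect_equal(out$egfr[out$year == 3], lo)  # would be -70 unclamped
  expect_true(all(out$egfr >= lo))
})

test_that("the one-call imputation policy yields a complete, in-range cohort", {
  prof <- cohort_profile("tecos", n_active = 150, n_placebo = 150)
  coh <- generate_cohort(prof, seed = 21)
  out <- impute_cohort(coh, illustrative_coefficients(), horizon = 3, seed = 2)
  lim <- default_factor_limits()
  for (f in t2dsim:::.CONT_FACTORS) {
    expect_false(anyNA(out[[f]]), info = f)
    lr <- lim[lim$factor == f, ]
    expect_true(all(out[[f]] >= lr$min & out[[f]] <= lr$max), info = f)
  }
  expect_equal(nrow(out), 300 * 4)
  # observed in-range baseline values never altered
  base_in <- as.data.frame(coh)
  obs <- which(!is.na(base_in$hba1c) & base_in$hba1c >= 4 & base_in$hba1c <= 15)
  m <- match(paste(base_in$id[obs], 0), paste(out$id, out$year))
  expect_equal(out$hba1c[m], base_in$hba1c[obs])
})
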