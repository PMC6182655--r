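cfg <- study_config()

test_that("rate intervals follow the zero-case and scaling conventions", {
  r0 <- rate_with_ci(0, 1000)
  expect_equal(r0$rate, 0)
  expect_true(is.na(r0$ci_low) && is.na(r0$ci_high))
  expect_error(rate_with_ci(5, 0), "positive")

  # scale equivariance: doubling cases and exposure keeps the rate and
  # narrows the interval
  a <- rate_with_ci(50, 10000)
  b <- rate_with_ci(100, 20000)
  expect_equal(a$rate, b$rate)
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)

  # exact-Poisson alternative brackets the point estimate too
  e <- rate_with_ci(28, 4327, method = "exact")
  expect_lt(e$ci_low, e$rate)
  expect_gt(e$ci_high, e$rate)
})

test_that("log-linear trend fits interpolate exact data", {
  py <- rep(1e4, 6)
  # constant expected counts: APC exactly zero
  fit <- poisson_apc(2009:2014, rep(100, 6), py)
  expect_equal(fit$apc, 0, tolerance = 1e-8)
  # exact geometric decline: APC exactly -10
  cases <- py * 500 / 1e5 * 0.9^(0:5)
  fit <- poisson_apc(2009:2014, cases, py)
  expect_equal(fit$apc, -10, tolerance = 1e-8)
  expect_lt(fit$ci_low, -10); expect_gt(fit$ci_high, -10)
  expect_error(poisson_apc(2010, 5, 100), "two periods")
  expect_error(poisson_apc(2009:2014, rep(0, 6), py), "all-zero")
  expect_error(poisson_apc(2009:2014, cases, rep(0, 6)), "positive")
})

test_that("the segmented model recovers exact piecewise slopes", {
  t <- seq(2009, 2014.4, by = 1 / 12)
  tb <- 2012 + 8 / 12
  b1 <- log(0.88); b2 <- log(0.921) - log(0.88)
  py <- rep(2e5, length(t))
  mu <- py * 600 / 1e5 * exp(b1 * (t - 2009) + b2 * pmax(0, t - tb))
  fit <- its_fit(t, mu, py, break_time = tb)
  expect_equal(fit$pre_slope_apc, -12, tolerance = 1e-6)
  expect_equal(fit$post_slope_apc, -7.9, tolerance = 1e-6)
  # equal slopes on both sides: the change term is exactly zero
  mu0 <- py * 600 / 1e5 * exp(b1 * (t - 2009))
  fit0 <- its_fit(t, mu0, py, break_time = tb)
  expect_equal(fit0$slope_change, 0, tolerance = 1e-8)
  expect_error(its_fit(t[t < tb], mu[t < tb], py[t < tb], tb),
               "three periods")
})

test_that("the slope-change test has power at the study's effect size", {
  t <- seq(2009, 2014.4, by = 1 / 12)
  tb <- 2012 + 8 / 12
  b1 <- log(0.88); b2 <- log(0.921) - log(0.88)
  py <- rep(2.3e5, length(t))  # nationwide-scale monthly exposure
  mu <- py * 600 / 1e5 * exp(b1 * (t - 2009) + b2 * pmax(0, t - tb))
  set.seed(123)
  p <- replicate(50, {
    fit <- its_fit(t, rpois(length(t), mu), py, break_time = tb)
    fit$slope_change_p
  })
  expect_gt(mean(p < 0.05), 0.8)
})

test_that("proportional-hazards estimates agree with a grid-search oracle", {
  set.seed(11)
  n <- 30
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.1 * exp(0.6 * x))
  event <- as.integer(stats::runif(n) < 0.8)
  start <- data.table::as.IDate("2009-01-01")
  p <- mk_persons(sprintf("C%02d", 1:n), birth = "1960-01-01",
                  sex = ifelse(x == 1, "female", "male"))
  w <- data.table(person_id = p$person_id, entry_date = start,
                  exit_date = start + pmax(1L, as.integer(
                    round(time * 365.25))),
                  exit_reason = "period_end")
  cs <- data.table(person_id = p$person_id,
                   status = ifelse(event == 1, "incident_case",
                                   "non_case"),
                   onset_date = data.table::as.IDate(NA_integer_),
                   index_date = data.table::as.IDate(NA_integer_))
  fit <- cox_fit(w, cs, p, covariates = "sex", mode = "unadjusted",
                 config = cfg)
  hr <- fit$table[level == "female", hr]
  t_years <- as.numeric(w$exit_date - w$entry_date) / 365.25
  beta_grid <- oracle_cox_grid(t_years, event, x)
  expect_equal(log(hr), beta_grid, tolerance = 2e-3)
})

test_that("a covariate independent of the event process has HR near 1", {
  set.seed(5)
  n <- 4000
  start <- data.table::as.IDate("2009-01-01")
  p <- mk_persons(sprintf("N%04d", 1:n), birth = "1955-01-01",
                  sex = sample(c("male", "female"), n, TRUE))
  time <- rexp(n, 0.05)
  event <- as.integer(time < 5)
  exit <- start + pmax(1L, as.integer(round(pmin(time, 5) * 365.25)))
  w <- data.table(person_id = p$person_id, entry_date = start,
                  exit_date = exit, exit_reason = "period_end")
  cs <- data.table(person_id = p$person_id,
                   status = ifelse(event == 1, "incident_case",
                                   "non_case"),
                   onset_date = data.table::as.IDate(NA_integer_),
                   index_date = data.table::as.IDate(NA_integer_))
  fit <- cox_fit(w, cs, p, covariates = "sex", mode = "unadjusted",
                 config = cfg)
  row <- fit$table[level == "female"]
  expect_gt(row$ci_high, 1)
  expect_lt(row$ci_low, 1)
  # absent levels are reported as non-estimable rather than erroring
  fit2 <- cox_fit(w, cs, p, covariates = c("sex", "place_of_birth"),
                  config = cfg)
  expect_true(all(is.na(
    fit2$table[term == "place_of_birth" & level != "Norway", hr])))
})

test_that("period prevalence counts 'that year or earlier' correctly", {
  p <- mk_persons(c("A", "B"), birth = "1950-01-01")
  prev <- data.table(person_id = c("A", "B"),
                     qualified = c(TRUE, FALSE),
                     onset_date = data.table::as.IDate(
                       c("2010-05-01", NA)),
                     qualify_date = data.table::as.IDate(
                       c("2010-06-15", NA)))
  pp <- period_prevalence(p, prev, config = cfg)
  expect_equal(pp$calendar_year, 2009:2014)
  expect_equal(pp$numerator, c(0L, rep(1L, 5)))
  expect_equal(pp$denominator, rep(2L, 6))
  expect_error(period_prevalence(p, prev, years = 2031, config = cfg),
               "outside")

  # no qualifying cases at all: zero prevalence everywhere
  prev0 <- data.table(person_id = c("A", "B"), qualified = FALSE,
                      onset_date = data.table::as.IDate(NA_integer_),
                      qualify_date = data.table::as.IDate(NA_integer_))
  expect_true(all(period_prevalence(p, prev0,
                                    config = cfg)$numerator == 0L))

  # a person dying mid-period leaves the denominator the next year
  p2 <- mk_persons(c("A", "B"), birth = "1950-01-01",
                   death = c(NA, "2011-03-01"))
  pp2 <- period_prevalence(p2, prev, config = cfg)
  expect_equal(pp2$denominator, c(2L, 2L, 2L, 1L, 1L, 1L))
})

test_that("monthly series conserve cases and person-time", {
  sim <- simulate_registry(sim_config(n_persons = 4000, seed = 23))
  cases <- phenotype_registry(sim$bundle, cfg)
  w <- eligibility_windows(sim$bundle$persons, cases, cfg)
  ms <- monthly_series(w, cases, cfg)
  expect_equal(sum(ms$person_years) * 365.25,
               sum(as.numeric(w$exit_date - w$entry_date)))
  in_cohort <- cases[status == "incident_case"][
    w, on = "person_id", nomatch = NULL][
      onset_date >= entry_date & onset_date < exit_date]
  expect_equal(sum(ms$cases), nrow(in_cohort))
  expect_equal(nrow(ms), 66L)  # Jan 2009 .. Jun 2014
})
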