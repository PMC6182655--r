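#' Incidence rate with confidence interval
#'
#' Rate per `rate_scale` person-years with a 95% interval. The default
#' interval is log-normal, `rate * exp(+/- z / sqrt(cases))`, which
#' matches the printed intervals of registry incidence tables even at
#' small counts; an exact Poisson interval (`stats::poisson.test`) is
#' available as an alternative. With zero cases the rate is 0 and the
#' interval is absent.
#'
#' @param cases Case counts (vectorised).
#' @param person_years Person-years at risk (vectorised, positive).
#' @param config A [study_config()] (supplies `ci_z` and `rate_scale`).
#' @param method `"lognormal"` (default) or `"exact"`.
#' @return `data.table` with `cases`, `person_years`, `rate`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' rate_with_ci(75496, 15463691)
rate_with_ci <- function(cases, person_years, config = study_config(),
                         method = c("lognormal", "exact")) {
  method <- match.arg(method)
  if (any(person_years <= 0)) stop("person_years must be positive")
  if (any(cases < 0)) stop("cases must be non-negative")
  rate <- cases / person_years * config$rate_scale
  if (method == "lognormal") {
    f <- exp(config$ci_z / sqrt(cases))
    lo <- ifelse(cases > 0, rate / f, NA_real_)
    hi <- ifelse(cases > 0, rate * f, NA_real_)
  } else {
    conf <- 2 * stats::pnorm(config$ci_z) - 1
    ci <- vapply(seq_along(cases), function(i) {
      if (cases[i] == 0) return(c(NA_real_, NA_real_))
      stats::poisson.test(cases[i], person_years[i],
                          conf.level = conf)$conf.int *
        config$rate_scale
    }, numeric(2))
    lo <- ci[1, ]; hi <- ci[2, ]
  }
  data.table::data.table(cases = cases, person_years = person_years,
                         rate = rate, ci_low = lo, ci_high = hi)
}

#' Attach rates to a stratum table
#'
#' @param strata Output of [aggregate_strata()].
#' @param config A [study_config()].
#' @param method Passed to [rate_with_ci()].
#' @return The stratum table with `rate`, `ci_low`, `ci_high` appended.
#' @export
add_rates <- function(strata, config = study_config(),
                      method = "lognormal") {
  r <- rate_with_ci(strata$cases, strata$person_years, config, method)
  out <- data.table::copy(strata)
  out[, `:=`(rate = r$rate, ci_low = r$ci_low, ci_high = r$ci_high)]
  out[]
}

#' Period prevalence by calendar year
#'
#' For each year, the numerator counts persons whose case criteria were
#' met in that year or earlier and who were alive, resident and aged
#' 30-89 at some time during the year; the denominator counts all persons
#' alive, resident and in the age range at some time during the year.
#'
#' @param persons Person table.
#' @param prev_cases Prevalence-mode [phenotype_registry()] output.
#' @param years Calendar years (default: study start to prevalence end).
#' @param config A [study_config()].
#' @return `data.table` with `calendar_year`, `numerator`, `denominator`,
#'   `proportion`.
#' @export
period_prevalence <- function(persons, prev_cases, years = NULL,
                              config = study_config()) {
  persons <- normalise_persons(persons)
  if (is.null(years))
    years <- seq(iyear(config$study_start), iyear(config$prevalence_end))
  years <- as.integer(years)
  if (any(years < iyear(config$prescription_start)) ||
      any(years > iyear(config$prevalence_end)))
    stop("year outside the data range")
  p <- prev_cases[, .(person_id, qualified, qualify_date)][
    persons, on = "person_id"]
  b30 <- anniversary(p$birth_date, config$min_age_years)
  b90 <- anniversary(p$birth_date, config$max_age_years)
  out <- data.table::rbindlist(lapply(years, function(y) {
    y0 <- jan1(y); y1 <- jan1(y + 1L) - 1L
    in_pop <- b30 <= y1 & b90 > y0 &
      (is.na(p$death_date) | p$death_date > y0) &
      (is.na(p$immigration_date) | p$immigration_date <= y1) &
      (is.na(p$emigration_date) | p$emigration_date > y0)
    num <- in_pop & !is.na(p$qualified) & p$qualified &
      p$qualify_date <= y1
    data.table::data.table(calendar_year = y, numerator = sum(num),
                           denominator = sum(in_pop))
  }))
  out[, proportion := ifelse(denominator > 0, numerator / denominator,
                             NA_real_)]
  out[]
}

#' Annual percent change by log-linear count regression
#'
#' Fits a Poisson log-linear model of case counts on continuous time with
#' a log person-years offset; the annual percent change is
#' `100 * (exp(beta) - 1)` with a Wald interval on the log scale. Exact
#' log-linear inputs are interpolated exactly.
#'
#' @param time Numeric time in years (e.g. calendar year).
#' @param cases Case counts per period.
#' @param person_years Exposure per period (positive).
#' @param config A [study_config()].
#' @return Object of class `apc_fit` with components `apc`, `ci_low`,
#'   `ci_high`, `beta`, `se`, `model` and `data`; methods `print`,
#'   `coef`, `confint`, `summary`.
#' @export
#' @examples
#' py <- rep(1e4, 6)
#' cases <- py * 500 / 1e5 * 0.9^(0:5)
#' poisson_apc(2009:2014, cases, py)   # APC -10 exactly
poisson_apc <- function(time, cases, person_years,
                        config = study_config()) {
  if (length(unique(time)) < 2L)
    stop("need at least two periods with positive exposure")
  if (any(person_years <= 0)) stop("person_years must be positive")
  if (all(cases == 0)) stop("all-zero case counts")
  dt <- data.table::data.table(time = as.numeric(time),
                               cases = as.numeric(cases),
                               person_years = as.numeric(person_years))
  fit <- suppressWarnings(stats::glm(
    cases ~ time + offset(log(person_years)),
    family = stats::poisson(), data = dt))
  beta <- stats::coef(fit)[["time"]]
  se <- sqrt(stats::vcov(fit)["time", "time"])
  z <- config$ci_z
  structure(list(
    apc = 100 * (exp(beta) - 1),
    ci_low = 100 * (exp(beta - z * se) - 1),
    ci_high = 100 * (exp(beta + z * se) - 1),
    beta = beta, se = se, model = fit, data = dt), class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf(
    "Annual percent change: %.1f%% (95%% CI %.1f, %.1f) over %d periods\n",
    x$apc, x$ci_low, x$ci_high, nrow(x$data)))
  invisible(x)
}

#' @export
coef.apc_fit <- function(object, ...) c(apc = object$apc,
                                        beta = object$beta)

#' @export
confint.apc_fit <- function(object, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("apc", c("2.5 %", "97.5 %")))
}

#' @export
summary.apc_fit <- function(object, ...) {
  print(object)
  invisible(summary(object$model))
}

#' @export
plot.apc_fit <- function(x, ...) {
  d <- x$data
  rate <- d$cases / d$person_years * 1e5
  graphics::plot(d$time, rate, pch = 16, xlab = "time",
                 ylab = "rate per 100,000 person-years", ...)
  graphics::lines(d$time, stats::fitted(x$model) / d$person_years * 1e5)
  invisible(x)
}

#' Interrupted time series: segmented log-linear count model
#'
#' Fits `log E[cases] = b0 + b1 t + b2 (t - t_break)+ [+ b3 1(t>t_break)]`
#' with a log-exposure offset. Reports the pre- and post-break annual
#' percent change and the Wald p value for the slope-change term. The
#' level-change term is excluded by default.
#'
#' @param time Numeric time in years (use mid-period coding), or dates.
#' @param cases,person_years Counts and exposure per period.
#' @param break_time The interruption, as a decimal year or a date.
#' @param level_change Include a level-change step term (default `FALSE`).
#' @param config A [study_config()].
#' @return Object of class `its_fit` with `pre_slope_apc`,
#'   `post_slope_apc`, `slope_change`, `slope_change_p`, intervals, and
#'   the underlying `model`.
#' @export
its_fit <- function(time, cases, person_years,
                    break_time = study_config()$its_break_date,
                    level_change = FALSE, config = study_config()) {
  to_year <- function(t)
    if (inherits(t, "Date")) decimal_year(t) else as.numeric(t)
  t <- to_year(time); tb <- to_year(break_time)
  if (sum(t < tb) < 3L || sum(t > tb) < 3L)
    stop("need at least three periods on each side of the break")
  if (any(person_years <= 0)) stop("person_years must be positive")
  dt <- data.table::data.table(time = t, cases = as.numeric(cases),
                               person_years = as.numeric(person_years))
  dt[, post_slope := pmax(0, time - tb)]
  dt[, post := as.numeric(time > tb)]
  form <- if (level_change)
    cases ~ time + post_slope + post + offset(log(person_years))
  else cases ~ time + post_slope + offset(log(person_years))
  fit <- suppressWarnings(stats::glm(form, family = stats::poisson(),
                                     data = dt))
  cf <- stats::coef(fit); V <- stats::vcov(fit)
  b1 <- cf[["time"]]; b2 <- cf[["post_slope"]]
  se1 <- sqrt(V["time", "time"]); se2 <- sqrt(V["post_slope", "post_slope"])
  se_post <- sqrt(V["time", "time"] + V["post_slope", "post_slope"] +
                    2 * V["time", "post_slope"])
  z <- config$ci_z
  structure(list(
    pre_slope_apc = 100 * (exp(b1) - 1),
    pre_ci = 100 * (exp(b1 + c(-1, 1) * z * se1) - 1),
    post_slope_apc = 100 * (exp(b1 + b2) - 1),
    post_ci = 100 * (exp(b1 + b2 + c(-1, 1) * z * se_post) - 1),
    slope_change = b2, slope_change_se = se2,
    slope_change_p = 2 * stats::pnorm(-abs(b2 / se2)),
    break_time = tb, level_change = level_change,
    model = fit, data = dt), class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Interrupted time series (break at %.2f)\n", x$break_time))
  cat(sprintf("  pre-break APC:  %.1f%% (95%% CI %.1f, %.1f)\n",
              x$pre_slope_apc, x$pre_ci[1], x$pre_ci[2]))
  cat(sprintf("  post-break APC: %.1f%% (95%% CI %.1f, %.1f)\n",
              x$post_slope_apc, x$post_ci[1], x$post_ci[2]))
  cat(sprintf("  slope change:   %.4f per year (p = %.3g)\n",
              x$slope_change, x$slope_change_p))
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...)
  c(pre_slope_apc = object$pre_slope_apc,
    post_slope_apc = object$post_slope_apc,
    slope_change = object$slope_change)

# decimal calendar year of a date
decimal_year <- function(d) {
  d <- data.table::as.IDate(d)
  y <- iyear(d)
  y + as.numeric(d - jan1(y)) / as.numeric(jan1(y + 1L) - jan1(y))
}

#' Monthly case/exposure series from follow-up windows
#'
#' Tabulates incident cases and person-years by calendar month, for the
#' segmented trend model. Times are coded at mid-month.
#'
#' @param windows Output of [eligibility_windows()].
#' @param cases Incidence-mode [phenotype_registry()] output.
#' @param config A [study_config()].
#' @return `data.table` with `month_start`, `time` (decimal year at
#'   mid-month), `cases`, `person_years`.
#' @export
monthly_series <- function(windows, cases, config = study_config()) {
  m0 <- seq(as.Date(config$study_start),
            as.Date(config$incidence_follow_up_end), by = "month")
  months <- data.table::data.table(
    month_start = data.table::as.IDate(m0),
    month_end = data.table::as.IDate(c(m0[-1L],
                                       seq(m0[length(m0)], by = "month",
                                           length.out = 2L)[2L])))
  ov <- windows[months, on = .(entry_date < month_end,
                               exit_date > month_start),
                .(person_id, month_start = i.month_start,
                  month_end = i.month_end,
                  entry = x.entry_date, exit = x.exit_date),
                nomatch = NULL, allow.cartesian = TRUE]
  ov[, days := as.numeric(pmin(exit, month_end) -
                            pmax(entry, month_start))]
  py <- ov[, .(person_years = sum(days) / 365.25), by = month_start]
  inc <- cases[status == "incident_case" &
                 person_id %in% windows$person_id]
  inc[, month_start := data.table::as.IDate(
    sprintf("%d-%02d-01", iyear(onset_date),
            data.table::month(onset_date)))]
  cs <- inc[, .(cases = .N), by = month_start]
  out <- months[, .(month_start)]
  out <- cs[py[out, on = "month_start"], on = "month_start"]
  data.table::set(out, which(is.na(out$cases)), "cases", 0L)
  data.table::set(out, which(is.na(out$person_years)), "person_years", 0)
  out[, time := decimal_year(month_start) +
        as.numeric(month_end_days(month_start)) / 2 / 365.25]
  data.table::setcolorder(out, c("month_start", "time", "cases",
                                 "person_years"))
  out[order(month_start)]
}

month_end_days <- function(month_start) {
  nxt <- data.table::as.IDate(vapply(as.character(month_start), function(s)
    as.integer(seq(as.Date(s), by = "month", length.out = 2L)[2L]),
    integer(1)))
  as.integer(nxt - month_start)
}

#' Cox proportional-hazards fit for cohort covariates
#'
#' One row per person (time from entry to exit, event = incident case),
#' fixed covariates. `mode = "adjusted"` fits all covariates jointly;
#' `mode = "unadjusted"` fits each requested covariate alone. The default
#' time scale is follow-up time; attained age with delayed entry is
#' available as an option. Covariate levels that are absent or cause a
#' degenerate fit are reported as non-estimable (`NA`).
#'
#' @param windows Output of [eligibility_windows()].
#' @param cases Incidence-mode [phenotype_registry()] output.
#' @param persons Person table.
#' @param covariates Covariates to model; any of `"sex"`,
#'   `"birth_decade"`, `"education_level"`, `"place_of_birth"`.
#' @param mode `"adjusted"` (default) or `"unadjusted"`.
#' @param timescale `"followup"` (default) or `"age"`.
#' @param config A [study_config()].
#' @return Object of class `cox_hr_fit`: the tidy table (`term`, `level`,
#'   `hr`, `ci_low`, `ci_high`, `mode`) plus the underlying
#'   `survival::coxph` fit(s).
#' @export
cox_fit <- function(windows, cases, persons,
                    covariates = c("sex", "birth_decade",
                                   "education_level", "place_of_birth"),
                    mode = c("adjusted", "unadjusted"),
                    timescale = c("followup", "age"),
                    config = study_config()) {
  mode <- match.arg(mode)
  timescale <- match.arg(timescale)
  covariates <- match.arg(covariates, several.ok = TRUE)

  persons <- normalise_persons(persons)
  d <- persons[, .(person_id, birth_date, sex, education_level,
                   place_of_birth)][windows, on = "person_id",
                                    nomatch = NULL]
  d <- cases[, .(person_id, status)][d, on = "person_id"]
  d[, event := as.integer(!is.na(status) & status == "incident_case")]
  d[, birth_decade := sprintf("%d-%d",
                              10L * (iyear(birth_date) %/% 10L),
                              10L * (iyear(birth_date) %/% 10L) + 9L)]
  d[, sex := factor(sex, levels = c("male", "female"))]
  d[, education_level := factor(education_level,
                                levels = c("high", "low", "medium",
                                           "missing"))]
  d[, place_of_birth := factor(place_of_birth,
                               levels = c("Norway", setdiff(pob_levels(),
                                                            "Norway")))]
  dec <- sort(unique(d$birth_decade), decreasing = TRUE)
  d[, birth_decade := factor(birth_decade, levels = dec)]

  if (timescale == "followup") {
    d[, `:=`(t0 = 0,
             t1 = as.numeric(exit_date - entry_date) / 365.25)]
  } else {
    d[, `:=`(t0 = years_between(birth_date, entry_date),
             t1 = years_between(birth_date, exit_date))]
  }

  fit_one <- function(vars) {
    df <- droplevels(as.data.frame(d))
    form <- stats::as.formula(paste(
      "survival::Surv(t0, t1, event) ~", paste(vars, collapse = " + ")))
    fit <- tryCatch(survival::coxph(form, data = df),
                    error = function(e) NULL,
                    warning = function(w) suppressWarnings(
                      survival::coxph(form, data = df)))
    rows <- data.table::rbindlist(lapply(vars, function(v) {
      lev <- levels(df[[v]])
      data.table::data.table(term = v, level = lev)
    }))
    rows[, `:=`(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_)]
    if (!is.null(fit)) {
      cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
      for (v in vars) {
        lev <- levels(df[[v]])
        ref <- lev[1L]
        rows[term == v & level == ref, `:=`(hr = 1, ci_low = NA_real_,
                                            ci_high = NA_real_)]
        for (l in lev[-1L]) {
          nm <- paste0(v, l)
          if (nm %in% names(cf) && is.finite(cf[nm]) && is.finite(se[nm])) {
            z <- config$ci_z
            rows[term == v & level == l, `:=`(
              hr = exp(cf[nm]),
              ci_low = exp(cf[nm] - z * se[nm]),
              ci_high = exp(cf[nm] + z * se[nm]))]
          }
        }
      }
    }
    list(fit = fit, rows = rows)
  }

  if (mode == "adjusted") {
    res <- fit_one(covariates)
    tab <- res$rows[, mode := "adjusted"]
    fits <- list(adjusted = res$fit)
  } else {
    parts <- lapply(covariates, function(v) fit_one(v))
    tab <- data.table::rbindlist(lapply(parts, `[[`, "rows"))
    tab[, mode := "unadjusted"]
    fits <- lapply(parts, `[[`, "fit")
    names(fits) <- covariates
  }
  structure(list(table = tab[], fits = fits, mode = mode,
                 timescale = timescale), class = "cox_hr_fit")
}

#' @export
print.cox_hr_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Proportional-hazards estimates (%s, %s time scale)\n",
              x$mode, x$timescale))
  t <- data.table::copy(x$table)
  t[, est := ifelse(is.na(hr), "not estimable",
                    ifelse(is.na(ci_low),
                           sprintf("%.*f (ref)", digits, hr),
                           sprintf("%.*f (%.*f, %.*f)", digits, hr,
                                   digits, ci_low, digits, ci_high)))]
  print(t[, .(term, level, est)], row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_hr_fit <- function(object, ...) {
  with(object$table, stats::setNames(hr, paste(term, level, sep = ":")))
}
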