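#' Simulation configuration for the synthetic registry
#'
#' Defines the data-generating process for a synthetic national registry:
#' population demography, a latent disease model (piecewise-exponential
#' onset hazard on calendar time, log-linear with an optional slope break,
#' multiplied by covariate effects), and a care/recording model that turns
#' each latent onset into dispensing and diagnosis events across the three
#' registers.
#'
#' Covariate rate ratios are mean-centred over the realised population, so
#' `baseline_rate_per_100k` is the population-marginal true onset rate at
#' `reference_date`. The slope of the log-hazard is
#' `log(1 + annual_percent_change/100)` per year before `break_date` and
#' `log(1 + apc_after_break/100)` after it.
#'
#' Register assignment uses a per-person register profile (specialist-only,
#' primary-care-only, or both; occasions of "both"-profile persons are
#' assigned to each diagnosis register independently). The default profile
#' probabilities are a frozen calibration preset chosen so the one/two/three
#' register overlap among incident cases approximates 26/36/39 percent.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output tables.
#' @param demography,disease_model,care_model Named lists overriding
#'   individual defaults (see Details); only supplied elements are replaced.
#' @return An object of class `sim_config`.
#' @details
#' Demography defaults: birth-decade shares spanning 1910-1989 matching a
#' nationwide 30-89-year-old population; equal sex ratio; education shares
#' low/medium/high/missing = 0.23/0.42/0.31/0.04; place-of-birth shares
#' dominated by native-born; Gompertz mortality; constant emigration hazard;
#' immigration dates for the foreign-born.
#'
#' Disease-model defaults: marginal onset rate 609 per 100,000 person-years
#' at 2009-01-01, annual percent change -10.1, no slope break, and covariate
#' log rate-ratios (female 0.66; education low 2.10, medium 1.60 vs high;
#' birth-decade gradient 8.73 down to 1; place-of-birth ratios between 0.76
#' and 3.08) on the scale of adjusted hazard ratios typical for type 2
#' diabetes risk.
#'
#' Care-model defaults: 48.1% of onsets pharmacologically treated; initial
#' regimen shares metformin/sulfonylurea/other-oral/insulin-only/multi-drug
#' = 82.6/4.4/0.3/0.9/11.0 (renormalised); mean 30-day delay from onset to
#' first registration; a scheduled confirmatory contact a mean of 45 days
#' later; thereafter contacts at 4 per year (quarterly reviews are standard
#' care for diagnosed diabetes); dispensing refills every 90
#' days on average; a constant-flow background population (0.8% over the
#' 1994-2014 span) carrying type-1/unspecific diabetes codes only (E10/T89:
#' type 1 patients and coding noise, never qualifying as type 2 cases);
#' 0.2% of unaffected persons dispensed glucose-lowering drugs without any
#' diagnosis; 2% of the population prevalent long before data
#' availability.
#' @export
sim_config <- function(n_persons = 10000L, seed = 1L,
                       demography = list(), disease_model = list(),
                       care_model = list()) {
  demo <- utils::modifyList(list(
    birth_decade_shares = c(`1910` = 0.003, `1920` = 0.054, `1930` = 0.081,
                            `1940` = 0.144, `1950` = 0.183, `1960` = 0.218,
                            `1970` = 0.222, `1980` = 0.095),
    sex_female_share = 0.5,
    education_shares = c(low = 0.23, medium = 0.42, high = 0.31,
                         missing = 0.04),
    pob_shares = c("Norway" = 0.8513, "Europe-excl-Norway" = 0.0881,
                   "Africa" = 0.0137, "Asia" = 0.0364,
                   "North-Central-America" = 0.0061,
                   "South-America" = 0.0043, "Oceania" = 0.0007),
    death_log_hazard_at_0 = -10.3, death_gompertz_slope = 0.092,
    emigration_rate_per_year = 0.003,
    immigration_age_range = c(18, 60)
  ), demography)
  if (all(demo$birth_decade_shares == 0)) stop("degenerate demography")
  demo$birth_decade_shares <- demo$birth_decade_shares /
    sum(demo$birth_decade_shares)
  demo$education_shares <- demo$education_shares / sum(demo$education_shares)
  demo$pob_shares <- demo$pob_shares / sum(demo$pob_shares)

  dis <- utils::modifyList(list(
    baseline_rate_per_100k = 609,
    annual_percent_change = -10.1,
    apc_after_break = NULL,     # NULL: no slope change at the break date
    reference_date = "2009-01-01",
    onset_start = "2004-01-01",
    prevalent_onset_start = "1994-01-01",
    min_onset_age_years = 20,
    log_hr_sex_female = log(0.66),
    log_hr_education = c(low = log(2.10), medium = log(1.60), high = 0,
                         missing = log(1.60)),
    log_hr_birth_decade = c(`1910` = log(8.73), `1920` = log(6.60),
                            `1930` = log(4.15), `1940` = log(2.73),
                            `1950` = log(1.98), `1960` = log(1.57),
                            `1970` = log(1.29), `1980` = 0),
    log_hr_pob = c("Norway" = 0, "Europe-excl-Norway" = log(1.14),
                   "Africa" = log(2.72), "Asia" = log(3.08),
                   "North-Central-America" = log(1.02),
                   "South-America" = log(1.83), "Oceania" = log(0.76))
  ), disease_model)

  care <- utils::modifyList(list(
    p_treated = 0.481,
    regimen_probs = c(metformin_mono = 0.826, sulfonylurea_mono = 0.044,
                      other_oral_mono = 0.003, insulin_only = 0.009,
                      multi_drug = 0.110),
    first_registration_delay_days = 30,
    confirmation_delay_days = 45,
    visit_rate_per_year = 4.0,
    refill_interval_days = 90,
    register_profile_treated = c(both = 0.80, specialist = 0.10,
                                 primary = 0.10),
    register_profile_untreated = c(both = 0.50, specialist = 0.25,
                                   primary = 0.25),
    p_register_per_visit = 0.7,
    p_unclassifiable_coding = 0.008,
    p_drug_without_diagnosis = 0.002,
    prevalent_fraction = 0.02
  ), care_model)
  care$regimen_probs <- care$regimen_probs / sum(care$regimen_probs)
  for (nm in c("register_profile_treated", "register_profile_untreated"))
    care[[nm]] <- care[[nm]] / sum(care[[nm]])

  probs <- c(care$p_treated, care$p_register_per_visit,
             care$p_unclassifiable_coding, care$p_drug_without_diagnosis,
             care$prevalent_fraction, demo$sex_female_share)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")

  structure(list(n_persons = as.integer(n_persons), seed = as.integer(seed),
                 demography = demo, disease_model = dis, care_model = care),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-registry simulation configuration\n")
  cat(sprintf("  persons: %d  seed: %d\n", x$n_persons, x$seed))
  cat(sprintf("  baseline onset rate: %.1f per 100,000 PY at %s\n",
              x$disease_model$baseline_rate_per_100k,
              x$disease_model$reference_date))
  apc2 <- x$disease_model$apc_after_break
  cat(sprintf("  annual percent change: %.1f%s\n",
              x$disease_model$annual_percent_change,
              if (is.null(apc2)) "" else sprintf(" (after break: %.1f)", apc2)))
  cat(sprintf("  treated share of onsets: %.3f\n", x$care_model$p_treated))
  invisible(x)
}

# fan a master seed out to per-stage seeds (deterministic, < 2^31)
derive_seeds <- function(seed, n = 2L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic person table
#'
#' Samples demographics per the configuration: birth dates uniform within
#' sampled birth decades, sex, education and place of birth from the
#' configured shares, immigration dates for the foreign-born, Gompertz
#' mortality and a constant emigration hazard.
#'
#' @param config A [sim_config()].
#' @param n Number of persons (default `config$n_persons`).
#' @param seed Seed (default `config$seed`).
#' @param data_end Last day of data availability; deaths/emigrations after
#'   it are recorded as absent.
#' @return A persons `data.table` satisfying the person-table invariants.
#' @export
generate_population <- function(config, n = config$n_persons,
                                seed = config$seed,
                                data_end = study_config()$prevalence_end) {
  d <- config$demography
  empty <- data.table::data.table(
    person_id = character(), sex = character(),
    birth_date = data.table::as.IDate(integer()),
    death_date = data.table::as.IDate(integer()),
    immigration_date = data.table::as.IDate(integer()),
    emigration_date = data.table::as.IDate(integer()),
    education_level = character(), place_of_birth = character())
  if (n == 0L) return(empty)
  set.seed(seed)
  data_end <- data.table::as.IDate(data_end)

  dec <- sample(names(d$birth_decade_shares), n, replace = TRUE,
                prob = d$birth_decade_shares)
  dec_start <- jan1(dec)
  dec_len <- as.integer(jan1(as.integer(dec) + 10L) - dec_start)
  birth <- dec_start + as.integer(floor(stats::runif(n) * dec_len))

  sex <- ifelse(stats::runif(n) < d$sex_female_share, "female", "male")
  edu <- sample(names(d$education_shares), n, TRUE, prob = d$education_shares)
  pob <- sample(names(d$pob_shares), n, TRUE, prob = d$pob_shares)

  foreign <- pob != "Norway"
  imm_age <- stats::runif(n, d$immigration_age_range[1],
                          d$immigration_age_range[2])
  imm <- data.table::as.IDate(ifelse(
    foreign, birth + as.integer(round(imm_age * 365.25)), NA_integer_))

  # Gompertz death age by inversion of the cumulative hazard
  b0 <- d$death_log_hazard_at_0; b1 <- d$death_gompertz_slope
  age_death <- log1p(b1 * stats::rexp(n) / exp(b0)) / b1
  death <- birth + as.integer(round(age_death * 365.25))
  death[death > data_end] <- NA_integer_

  emig_from <- pmax(jan1(2004L), data.table::fifelse(foreign, imm, birth))
  emig <- emig_from + pmax(1L, as.integer(round(
    stats::rexp(n, d$emigration_rate_per_year) * 365.25)))
  emig[emig > data_end] <- NA_integer_
  # once emigrated, any later death is unobserved by the registries
  death[!is.na(emig) & !is.na(death) & emig <= death] <- NA_integer_
  emig[!is.na(death) & !is.na(emig) & death <= emig] <- NA_integer_

  p <- data.table::data.table(
    person_id = sprintf("P%07d", seq_len(n)), sex = sex,
    birth_date = data.table::as.IDate(birth),
    death_date = data.table::as.IDate(death),
    immigration_date = imm,
    emigration_date = data.table::as.IDate(emig),
    education_level = edu, place_of_birth = pob)
  data.table::setkey(p, person_id)
  p
}

# inversion sampler for a piecewise log-linear hazard on calendar time:
# lambda(u) = c * g1^u for u <= ub, continuous with slope g2 after ub
# (u in years from the reference date); returns onset u or NA
draw_onset_years <- function(u_start, u_end, c_rate, g1, g2, u_break) {
  n <- length(u_start)
  E <- stats::rexp(n)
  cumhaz <- function(cc, g, u1, u2) {
    len <- pmax(0, u2 - u1)
    if (abs(g - 1) < 1e-12) cc * len
    else ifelse(len <= 0, 0, cc * (g^u2 - g^u1) / log(g))
  }
  invert <- function(cc, g, u1, Ew) {
    # solve cumulative hazard from u1 equal to Ew
    if (abs(g - 1) < 1e-12) return(u1 + Ew / cc)
    arg <- g^u1 + Ew * log(g) / cc
    out <- rep(Inf, length(arg))
    ok <- is.finite(arg) & arg > 0
    out[ok] <- log(arg[ok]) / log(g)
    out
  }
  uA2 <- pmin(u_end, u_break)
  H1 <- ifelse(u_start < uA2, cumhaz(c_rate, g1, u_start, uA2), 0)
  u <- rep(NA_real_, n)
  inA <- E <= H1 & u_start < uA2
  u[inA] <- invert(c_rate[inA], g1, u_start[inA], E[inA])
  # remaining hazard spent in the post-break segment
  rem <- !inA & u_end > u_break
  if (any(rem)) {
    u2s <- pmax(u_start[rem], u_break)
    c2 <- c_rate[rem] * g1^(u_break - 0) * g2^(u2s - u_break) / g2^0
    # hazard at segment start u2s: c * g1^ub * g2^(u2s-ub); reparametrise
    E2 <- E[rem] - H1[rem]
    ub <- invert(c2, g2, 0, E2) # years past u2s on the g2 slope
    cand <- u2s + ub
    cand[!is.finite(cand) | cand > u_end[rem]] <- NA_real_
    u[rem] <- cand
  }
  u[!is.na(u) & u > u_end] <- NA_real_
  u
}

#' Generate registry events for a person table
#'
#' Draws latent onsets from the configured calendar-time hazard, assigns
#' treatment behaviour and register profiles, and emits the three event
#' tables plus a hidden truth table. Events respect the source availability
#' windows (prescriptions from 2004, primary care from 2006, specialist
#' care from 2008) and stop at death or emigration.
#'
#' @param persons Person table from [generate_population()].
#' @param config A [sim_config()].
#' @param study A [study_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return List with elements `prescriptions`, `specialist_dx`,
#'   `primary_dx` (event tables) and `truth` (one row per person:
#'   `onset_date`, `treated`, `regimen`, `prevalent`,
#'   `unclassifiable_coded`, `drug_without_diagnosis`).
#' @export
generate_events <- function(persons, config, study = study_config(),
                            seed = derive_seeds(config$seed, 2L)[2L]) {
  dis <- config$disease_model; care <- config$care_model
  set.seed(seed)
  n <- nrow(persons)
  data_end <- study$prevalence_end
  ref <- data.table::as.IDate(dis$reference_date)

  empty_rx <- data.table::data.table(person_id = character(),
    dispense_date = data.table::as.IDate(integer()), atc_code = character())
  empty_dx <- data.table::data.table(person_id = character(),
    event_date = data.table::as.IDate(integer()), code = character())
  truth0 <- data.table::data.table(person_id = persons$person_id,
    onset_date = data.table::as.IDate(rep(NA_integer_, n)),
    treated = rep(NA, n), regimen = rep(NA_character_, n),
    prevalent = rep(FALSE, n), unclassifiable_coded = rep(FALSE, n),
    drug_without_diagnosis = rep(FALSE, n))
  if (n == 0L)
    return(list(prescriptions = empty_rx, specialist_dx = empty_dx,
                primary_dx = empty_dx, truth = truth0))

  # covariate rate ratios, mean-centred so the baseline is marginal
  loghr <- dis$log_hr_sex_female * (persons$sex == "female") +
    dis$log_hr_education[persons$education_level] +
    dis$log_hr_birth_decade[as.character(
      10L * (data.table::year(persons$birth_date) %/% 10L))] +
    dis$log_hr_pob[persons$place_of_birth]
  rr <- exp(loghr); rr <- rr / mean(rr)

  censor <- pmin(data_end,
                 data.table::fifelse(is.na(persons$death_date), data_end,
                                     persons$death_date),
                 data.table::fifelse(is.na(persons$emigration_date), data_end,
                                     persons$emigration_date))

  g1 <- 1 + dis$annual_percent_change / 100
  g2 <- if (is.null(dis$apc_after_break)) g1 else
    1 + dis$apc_after_break / 100
  u_break <- years_between(ref, study$its_break_date)
  adult <- anniversary(persons$birth_date, dis$min_onset_age_years)
  u_start <- years_between(ref, pmax(data.table::as.IDate(dis$onset_start),
                                     adult))
  u_end <- years_between(ref, censor)
  c_rate <- dis$baseline_rate_per_100k / 1e5 * rr
  u_on <- draw_onset_years(u_start, u_end, c_rate, g1, g2, u_break)
  onset <- ref + as.integer(round(u_on * 365.25))

  # long-standing prevalent pool with onsets before data availability
  prev_draw <- stats::runif(n) < care$prevalent_fraction
  p0 <- data.table::as.IDate(dis$prevalent_onset_start)
  p1 <- data.table::as.IDate(dis$onset_start)
  prev_onset <- p0 + as.integer(floor(stats::runif(n) * as.integer(p1 - p0)))
  take_prev <- prev_draw & prev_onset >= adult & prev_onset < censor
  onset[take_prev] <- prev_onset[take_prev]
  is_case <- !is.na(onset)

  treated <- is_case & stats::runif(n) < care$p_treated
  regimen <- rep(NA_character_, n)
  regimen[treated] <- sample(names(care$regimen_probs), sum(treated),
                             TRUE, prob = care$regimen_probs)
  # separate constant-flow population with type-1/unspecific coding
  # (E10/T89): onsets uniform over the full span, so the in-study flow of
  # never-qualifying persons is calendar-stable
  type1 <- !is_case & stats::runif(n) < care$p_unclassifiable_coding
  t1_onset <- p0 + as.integer(floor(stats::runif(n) *
                                      as.integer(data_end - p0)))
  type1 <- type1 & t1_onset >= adult & t1_onset < censor
  drug_no_dx <- !is_case & !type1 &
    stats::runif(n) < care$p_drug_without_diagnosis &
    censor > data.table::as.IDate(study$prescription_start)

  truth <- data.table::data.table(
    person_id = persons$person_id, onset_date = onset,
    treated = ifelse(is_case, treated, NA),
    regimen = regimen,
    prevalent = is_case & onset < study$study_start,
    unclassifiable_coded = type1,
    drug_without_diagnosis = drug_no_dx)

  # diagnosis-occasion population: true cases plus the type-1-coded flow
  contact_onset <- onset
  contact_onset[type1] <- t1_onset[type1]
  is_contact <- is_case | type1
  ci <- which(is_contact)
  nc <- length(ci)
  if (nc == 0L && !any(drug_no_dx))
    return(list(prescriptions = empty_rx, specialist_dx = empty_dx,
                primary_dx = empty_dx, truth = truth))

  rdelay <- function(k, mean_days)
    if (mean_days <= 0) rep(0L, k) else
      as.integer(round(stats::rexp(k, 1 / mean_days)))

  # ---- diagnosis occasions -------------------------------------------------
  on_c <- contact_onset[ci]; end_c <- censor[ci]
  t0 <- on_c + rdelay(nc, care$first_registration_delay_days)
  t1 <- t0 + pmax(1L, rdelay(nc, care$confirmation_delay_days))
  kv <- stats::rpois(nc, care$visit_rate_per_year *
                       pmax(0, years_between(t1, end_c)))
  vis_id <- rep(ci, kv)
  vis_t <- data.table::as.IDate(rep(t1, kv) + as.integer(floor(
    stats::runif(sum(kv)) * rep(pmax(1L, as.integer(end_c - t1)), kv))))
  occ <- data.table::data.table(
    idx = c(ci, ci, vis_id),
    date = data.table::as.IDate(c(t0, t1, vis_t)))
  occ <- occ[date <= censor[idx] & date >= contact_onset[idx]]

  # register profile per case person
  prof_probs_t <- care$register_profile_treated
  prof_probs_u <- care$register_profile_untreated
  prof <- rep(NA_character_, n)
  prof[ci] <- ifelse(treated[ci],
    sample(names(prof_probs_t), nc, TRUE, prob = prof_probs_t),
    sample(names(prof_probs_u), nc, TRUE, prob = prof_probs_u))

  q <- care$p_register_per_visit
  m <- nrow(occ)
  pp <- prof[occ$idx]
  to_spec <- pp == "specialist"
  to_prim <- pp == "primary"
  both <- pp == "both"
  s_draw <- stats::runif(m) < q
  p_draw <- stats::runif(m) < q
  neither <- both & !s_draw & !p_draw
  coin <- stats::runif(m) < 0.5
  s_draw[neither] <- coin[neither]
  p_draw[neither] <- !coin[neither]
  occ_spec <- occ[(to_spec | (both & s_draw))]
  occ_prim <- occ[(to_prim | (both & p_draw))]

  code_t1 <- type1  # type-1/unspecific coding population
  specialist_dx <- occ_spec[date >= study$specialist_start,
    .(person_id = persons$person_id[idx], event_date = date,
      code = ifelse(code_t1[idx], "E10", "E11"))]
  primary_dx <- occ_prim[date >= study$primary_care_start,
    .(person_id = persons$person_id[idx], event_date = date,
      code = ifelse(code_t1[idx], "T89", "T90"))]

  # ---- dispensings ---------------------------------------------------------
  regimen_atc <- list(metformin_mono = "A10BA02",
                      sulfonylurea_mono = "A10BB01",
                      other_oral_mono = "A10BX02",
                      insulin_only = "A10AB05",
                      multi_drug = c("A10BA02", "A10BB01"))
  ti <- which(!is.na(truth$treated) & truth$treated)
  rx_list <- vector("list", 3L)
  if (length(ti)) {
    d0 <- t0[match(ti, ci)] + as.integer(floor(stats::runif(length(ti)) * 91))
    subs1 <- vapply(regimen_atc[regimen[ti]], `[`, character(1), 1L)
    first <- data.table::data.table(idx = ti, date = data.table::as.IDate(d0),
                                    atc = subs1)
    multi <- regimen[ti] == "multi_drug"
    second <- data.table::data.table(
      idx = ti[multi],
      date = data.table::as.IDate(d0[multi] +
        as.integer(floor(stats::runif(sum(multi)) * 26))),
      atc = "A10BB01")
    # refills of every substance until end of care
    base <- rbind(first, second)
    span <- pmax(0, years_between(base$date, censor[base$idx]))
    kr <- stats::rpois(nrow(base), span * 365.25 / care$refill_interval_days)
    rid <- rep(seq_len(nrow(base)), kr)
    refills <- data.table::data.table(
      idx = base$idx[rid],
      date = data.table::as.IDate(base$date[rid] + as.integer(floor(
        stats::runif(length(rid)) *
          rep(pmax(1L, as.integer(censor[base$idx] - base$date)), kr)))),
      atc = base$atc[rid])
    rx_list[[1L]] <- rbind(base, refills)
  }
  di <- which(drug_no_dx)
  if (length(di)) {
    s0 <- data.table::as.IDate(study$prescription_start)
    dstart <- s0 + as.integer(floor(stats::runif(length(di)) *
                                      pmax(1L, as.integer(censor[di] - s0))))
    span <- pmax(0, years_between(dstart, censor[di]))
    kr <- stats::rpois(length(di), span * 365.25 / care$refill_interval_days)
    rid <- rep(seq_along(di), kr)
    rx_list[[2L]] <- rbind(
      data.table::data.table(idx = di, date = dstart, atc = "A10BA02"),
      data.table::data.table(
        idx = di[rid],
        date = data.table::as.IDate(dstart[rid] + as.integer(floor(
          stats::runif(length(rid)) *
            rep(pmax(1L, as.integer(censor[di] - dstart)), kr)))),
        atc = "A10BA02"))
  }
  rx <- data.table::rbindlist(rx_list[!vapply(rx_list, is.null, logical(1))])
  prescriptions <- if (nrow(rx) == 0L) empty_rx else
    rx[date >= study$prescription_start & date <= censor[idx],
       .(person_id = persons$person_id[idx], dispense_date = date,
         atc_code = atc)]

  data.table::setkey(prescriptions, person_id, dispense_date)
  data.table::setkey(specialist_dx, person_id, event_date)
  data.table::setkey(primary_dx, person_id, event_date)
  list(prescriptions = prescriptions, specialist_dx = specialist_dx,
       primary_dx = primary_dx, truth = truth)
}

#' Simulate a complete synthetic registry
#'
#' Runs [generate_population()] and [generate_events()] with seeds derived
#' deterministically from `config$seed` and assembles a validated
#' [registry_bundle()] plus the hidden truth table.
#'
#' @param config A [sim_config()].
#' @param study A [study_config()].
#' @return A list of class `registry_sim` with elements `bundle` (a
#'   `registry_bundle`) and `truth`.
#' @export
#' @examples
#' sim <- simulate_registry(sim_config(n_persons = 500, seed = 7))
#' sim$bundle
simulate_registry <- function(config, study = study_config()) {
  seeds <- derive_seeds(config$seed, 2L)
  persons <- generate_population(config, seed = seeds[1L],
                                 data_end = study$prevalence_end)
  ev <- generate_events(persons, config, study, seed = seeds[2L])
  bundle <- registry_bundle(persons, ev$prescriptions, ev$specialist_dx,
                            ev$primary_dx, config = study)
  structure(list(bundle = bundle, truth = ev$truth), class = "registry_sim")
}

#' @export
print.registry_sim <- function(x, ...) {
  print(x$bundle)
  tr <- x$truth
  cat(sprintf("  true cases: %d (%d prevalent at baseline)\n",
              sum(!is.na(tr$onset_date)), sum(tr$prevalent)))
  invisible(x)
}
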