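cfg <- study_config()

no_case <- function(ids)
  data.table(person_id = ids, status = "non_case",
             onset_date = data.table::as.IDate(NA_integer_),
             index_date = data.table::as.IDate(NA_integer_))

test_that("entry and exit follow the participation rules", {
  p <- mk_persons("A", birth = "1980-03-10")
  w <- eligibility_windows(p, no_case("A"), cfg)
  expect_equal(w$entry_date, data.table::as.IDate("2010-03-10"))
  expect_equal(w$exit_date, data.table::as.IDate("2014-06-30"))
  expect_equal(w$exit_reason, "period_end")

  p <- mk_persons("A", birth = "1920-05-01")
  w <- eligibility_windows(p, no_case("A"), cfg)
  expect_equal(w$entry_date, data.table::as.IDate("2009-01-01"))
  expect_equal(w$exit_date, data.table::as.IDate("2010-05-01"))
  expect_equal(w$exit_reason, "age_90")

  p <- mk_persons("A", birth = "1970-01-01", immigration = "2011-02-01")
  w <- eligibility_windows(p, no_case("A"), cfg)
  expect_equal(w$entry_date, data.table::as.IDate("2012-02-01"))

  # too young to enter: dropped with a reason
  p <- mk_persons("A", birth = "1986-01-01")
  w <- eligibility_windows(p, no_case("A"), cfg)
  expect_equal(nrow(w), 0L)
  expect_equal(attr(w, "dropped")$drop_reason, "no_person_time")

  # death before other candidates, and tie-breaking by the listed order
  p <- mk_persons("A", birth = "1950-01-01", death = "2011-03-05",
                  emigration = "2011-03-05")
  w <- eligibility_windows(p, no_case("A"), cfg)
  expect_equal(w$exit_date, data.table::as.IDate("2011-03-05"))
  expect_equal(w$exit_reason, "emigration")
})

test_that("case onset ends follow-up the day after the onset", {
  p <- mk_persons("A", birth = "1950-01-01")
  cs <- data.table(person_id = "A", status = "incident_case",
                   onset_date = data.table::as.IDate("2011-06-10"),
                   index_date = data.table::as.IDate("2011-06-10"))
  w <- eligibility_windows(p, cs, cfg)
  expect_equal(w$exit_date, data.table::as.IDate("2011-06-11"))
  expect_equal(w$exit_reason, "case_onset")
  # washed-out persons contribute no window
  cs2 <- data.table(person_id = "A", status = "excluded_washout",
                    onset_date = data.table::as.IDate(NA_integer_),
                    index_date = data.table::as.IDate(NA_integer_))
  w2 <- eligibility_windows(p, cs2, cfg)
  expect_equal(nrow(w2), 0L)
  expect_equal(attr(w2, "dropped")$drop_reason, "washout")
})

test_that("Lexis segments cut at year and age-band boundaries", {
  p <- mk_persons("A", birth = "1959-06-15")
  w <- data.table(person_id = "A",
                  entry_date = data.table::as.IDate("2009-01-01"),
                  exit_date = data.table::as.IDate("2010-01-01"),
                  exit_reason = "period_end")
  seg <- lexis_split(w, p, cfg)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$start, data.table::as.IDate(c("2009-01-01",
                                                 "2009-06-15")))
  expect_equal(seg$end, data.table::as.IDate(c("2009-06-15",
                                               "2010-01-01")))
  expect_equal(seg$age_band, c("30-49", "50-69"))
  expect_equal(seg$calendar_year, c(2009L, 2009L))
  expect_equal(seg$birth_decade, rep("1950-1959", 2))
})

test_that("segments tile every window exactly, in days", {
  set.seed(42)
  n <- 400
  birth <- data.table::as.IDate("1910-01-01") +
    sample.int(as.integer(data.table::as.IDate("1984-06-30") -
                            data.table::as.IDate("1910-01-01")), n, TRUE)
  p <- mk_persons(sprintf("R%03d", 1:n), birth = format(birth))
  cs <- no_case(p$person_id)
  w <- eligibility_windows(p, cs, cfg)
  seg <- lexis_split(w, p, cfg)
  # global and per-person conservation, exact in days
  days_seg <- seg[, .(d = sum(as.integer(end - start))), by = person_id]
  days_win <- w[, .(d0 = as.integer(exit_date - entry_date)),
                by = person_id]
  m <- merge(days_seg, days_win, by = "person_id")
  expect_equal(m$d, m$d0)
  expect_equal(sum(seg$duration_years) * 365.25,
               sum(as.numeric(w$exit_date - w$entry_date)))
  # no segment outside the age range or the study period
  expect_true(all(seg$start >= cfg$study_start))
  expect_true(all(seg$end <= cfg$incidence_follow_up_end))
  expect_true(all(seg$age_band %in% c("30-49", "50-69", "70-89")))
})

test_that("cell assignment matches the day-by-day counting oracle", {
  set.seed(7)
  n <- 120
  birth <- data.table::as.IDate("1915-01-01") +
    sample.int(25000, n, TRUE)
  p <- mk_persons(sprintf("R%03d", 1:n), birth = format(birth))
  w <- eligibility_windows(p, no_case(p$person_id), cfg)
  seg <- lexis_split(w, p, cfg)
  got <- seg[, .(days = sum(as.integer(end - start))),
             by = .(person_id, calendar_year, age_band)]
  for (pid in w$person_id) {
    want <- oracle_day_count(w[person_id == pid, entry_date],
                             w[person_id == pid, exit_date],
                             p[person_id == pid, birth_date])
    have <- got[person_id == pid, .(calendar_year, age_band, days)]
    data.table::setkey(want, calendar_year, age_band)
    data.table::setkey(have, calendar_year, age_band)
    expect_equal(as.data.frame(have), as.data.frame(want), info = pid)
  }
})

test_that("strata aggregate person-years and attribute cases correctly", {
  p <- mk_persons("A", birth = "1950-06-01")
  w <- data.table(person_id = "A",
                  entry_date = data.table::as.IDate("2010-01-01"),
                  exit_date = data.table::as.IDate("2011-01-01"),
                  exit_reason = "period_end")
  seg <- lexis_split(w, p, cfg)
  st <- aggregate_strata(seg, no_case("A"), by = "calendar_year")
  expect_equal(st$cases, 0L)
  expect_equal(st$person_years, 365 / 365.25, tolerance = 1e-12)

  # additivity: sex strata sum to the all-participants totals
  sim <- simulate_registry(sim_config(n_persons = 4000, seed = 17))
  cases <- phenotype_registry(sim$bundle, cfg)
  w <- eligibility_windows(sim$bundle$persons, cases, cfg)
  seg <- lexis_split(w, sim$bundle$persons, cfg)
  by_sex <- aggregate_strata(seg, cases, by = c("calendar_year", "sex"))
  by_year <- aggregate_strata(seg, cases, by = "calendar_year")
  tot <- by_sex[, .(cases = sum(cases), person_years = sum(person_years)),
                by = calendar_year]
  expect_equal(tot$cases, by_year$cases)
  expect_equal(tot$person_years, by_year$person_years)
  grand <- aggregate_strata(seg, cases, by = character(0))
  expect_equal(grand$cases, sum(by_year$cases))
  expect_equal(grand$person_years, sum(by_year$person_years))
  # every counted case contributed at least one day in its onset stratum
  expect_equal(grand$cases,
               nrow(cases[status == "incident_case"][
                 w, on = "person_id", nomatch = NULL][
                   onset_date >= entry_date & onset_date < exit_date]))
})
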