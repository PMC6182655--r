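cfg <- study_config()

classify1 <- function(kinds, dates, ...) {
  b <- mk_bundle1(kinds, dates, ...)
  phenotype_registry(b, cfg)
}

test_that("washout excludes any pre-study diabetes evidence", {
  w <- washout_flag(mk_bundle1("A10BA02", "2007-04-01"), cfg)
  expect_true(w$excluded_washout)
  w <- washout_flag(mk_bundle1("E14", "2008-11-30"), cfg)
  expect_true(w$excluded_washout)
  # boundary: evidence on or after study start is not washout
  w <- washout_flag(mk_bundle1("T90", "2009-01-02"), cfg)
  expect_false(w$excluded_washout)
  w <- washout_flag(mk_bundle1("T90", "2009-01-01"), cfg)
  expect_false(w$excluded_washout)
  # washout dominates later qualifying events
  r <- classify1(c("A10BA02", "T90", "T90", "A10BA02"),
                 c("2008-12-31", "2010-03-01", "2010-06-01", "2010-03-10"))
  expect_equal(r$status, "excluded_washout")
})

test_that("the two qualifying rules classify the worked examples", {
  # one diagnosis plus a non-insulin dispensing within the window
  r <- classify1(c("T90", "A10BA02"), c("2010-03-01", "2010-03-15"))
  expect_equal(r$status, "incident_case")
  expect_equal(r$treatment_class, "pharmacological")
  expect_equal(r$qualifying_rule, "one_dx_plus_A10B")
  expect_equal(r$onset_date, data.table::as.IDate("2010-03-01"))

  # two occasions across the two diagnosis sources, no drugs
  r <- classify1(c("E11", "T90"), c("2011-05-02", "2011-08-10"))
  expect_equal(r$status, "incident_case")
  expect_equal(r$treatment_class, "non_pharmacological")
  expect_equal(r$qualifying_rule, "two_occasions")
  expect_equal(r$onset_date, data.table::as.IDate("2011-05-02"))
  expect_equal(r$registers_involved, "specialist,primary_care")
  expect_equal(r$n_registers, 2L)

  # a lone registration never confirmed
  r <- classify1("E11", "2011-05-02")
  expect_equal(r$status, "possible_unclassified")

  # dispensing outside the 183-day window does not qualify
  r <- classify1(c("T90", "A10BA02"), c("2010-03-01", "2010-09-15"))
  expect_equal(r$status, "possible_unclassified")

  # same-day duplicate registrations collapse to one occasion
  r <- classify1(c("T90", "T90"), c("2010-03-01", "2010-03-01"))
  expect_equal(r$status, "possible_unclassified")

  # insulin-only within the window: pharmacological only via two occasions
  r <- classify1(c("E11", "A10AB05"), c("2010-03-01", "2010-03-20"))
  expect_equal(r$status, "possible_unclassified")
  r <- classify1(c("E11", "T90", "A10AB05"),
                 c("2010-03-01", "2010-06-01", "2010-03-20"))
  expect_equal(r$status, "incident_case")
  expect_equal(r$treatment_class, "pharmacological")
  expect_equal(r$qualifying_rule, "two_occasions")

  # type 1 / unspecific codes never qualify on their own
  r <- classify1(c("E10", "T89", "E10"),
                 c("2010-03-01", "2010-06-01", "2011-01-10"))
  expect_equal(r$status, "possible_unclassified")

  # drugs dispensed before the first T2D registration break the
  # follow-up ordering and leave the person unclassified
  r <- classify1(c("A10BA02", "T90", "T90"),
                 c("2010-01-05", "2010-03-01", "2010-06-01"))
  expect_equal(r$status, "possible_unclassified")

  # onset after the incidence follow-up end is not an incident case
  r <- classify1(c("T90", "A10BA02"), c("2014-09-01", "2014-09-10"))
  expect_equal(r$status, "non_case")
})

test_that("initial regimens classify by first-month substances", {
  r <- classify1(c("T90", "A10BA02"), c("2010-03-01", "2010-03-05"))
  expect_equal(r$initial_regimen, "metformin_mono")
  r <- classify1(c("T90", "A10BA02", "A10BB01"),
                 c("2010-03-01", "2010-03-05", "2010-03-25"))
  expect_equal(r$initial_regimen, "multi_drug")
  # a second substance after the first month does not change the regimen
  r <- classify1(c("T90", "A10BA02", "A10BB01"),
                 c("2010-03-01", "2010-03-05", "2010-06-25"))
  expect_equal(r$initial_regimen, "metformin_mono")
  r <- classify1(c("T90", "A10BB01"), c("2010-03-01", "2010-03-05"))
  expect_equal(r$initial_regimen, "sulfonylurea_mono")
  r <- classify1(c("T90", "A10BX02"), c("2010-03-01", "2010-03-05"))
  expect_equal(r$initial_regimen, "other_oral_mono")
  # insulin-only starter, qualified via two occasions
  r <- classify1(c("E11", "T90", "A10AB05"),
                 c("2010-03-01", "2010-06-01", "2010-03-20"))
  expect_equal(r$initial_regimen, "insulin_only")
})

test_that("sensitivity categories are tabulated by year", {
  b <- mk_bundle_streams(list(
    U1 = data.table(kind = "A10BA02", date = "2011-04-01"),
    U2 = data.table(kind = "E11", date = "2012-07-01"),
    N1 = data.table(kind = character(), date = character())))
  cases <- phenotype_registry(b, cfg)
  s <- unclassified_summary(cases, cfg)
  expect_equal(s$calendar_year, 2009:2014)
  expect_equal(s[calendar_year == 2011, medication_without_diagnosis], 1L)
  expect_equal(s[calendar_year == 2012, possible_unclassified], 1L)
  expect_equal(sum(s$medication_without_diagnosis), 1L)
  expect_equal(sum(s$possible_unclassified), 1L)
  # and an empty cohort gives an all-zero table
  s0 <- unclassified_summary(phenotype_registry(
    mk_bundle_streams(list(X = data.table(kind = character(),
                                          date = character()))), cfg), cfg)
  expect_true(all(s0$possible_unclassified == 0L))
  expect_true(all(s0$medication_without_diagnosis == 0L))
})

test_that("register overlap proportions are well formed", {
  b <- mk_bundle_streams(list(
    A = data.table(kind = c("T90", "T90"),
                   date = c("2010-03-01", "2010-06-01")),
    B = data.table(kind = c("E11", "E11"),
                   date = c("2010-03-01", "2010-06-01"))))
  ov <- register_overlap_summary(phenotype_registry(b, cfg))
  expect_equal(ov$n_registers, 1L)
  expect_equal(ov$proportion, 1)
  # empty input: empty summary, not an error
  ov0 <- register_overlap_summary(phenotype_registry(
    mk_bundle_streams(list(X = data.table(kind = character(),
                                          date = character()))), cfg))
  expect_equal(nrow(ov0), 0L)
  # proportions sum to one on simulated data
  sim <- simulate_registry(sim_config(n_persons = 5000, seed = 3))
  ov2 <- register_overlap_summary(phenotype_registry(sim$bundle, cfg))
  expect_equal(sum(ov2$proportion), 1)
  expect_true(all(ov2$n_registers %in% 1:3))
})

test_that("classification is deterministic and respects monotonicity", {
  sim <- simulate_registry(sim_config(n_persons = 2000, seed = 13))
  c1 <- phenotype_registry(sim$bundle, cfg)
  c2 <- phenotype_registry(sim$bundle, cfg)
  expect_identical(c1, c2)

  # adding an A10B dispensing inside the window may switch the treatment
  # class to pharmacological but never unmakes a case
  set.seed(99)
  base <- c1[status == "incident_case"]
  pick <- base[sample(.N, min(.N, 25))]
  for (i in seq_len(nrow(pick))) {
    pid <- pick$person_id[i]
    extra <- data.table(person_id = pid,
                        dispense_date = pick$onset_date[i] + 10L,
                        atc_code = "A10BA02")
    b2 <- registry_bundle(sim$bundle$persons,
                          rbind(sim$bundle$prescriptions, extra),
                          sim$bundle$specialist_dx,
                          sim$bundle$primary_dx, config = cfg)
    r2 <- phenotype_registry(b2, cfg)[person_id == pid]
    expect_equal(r2$status, "incident_case")
    expect_equal(r2$treatment_class, "pharmacological")
  }
})
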