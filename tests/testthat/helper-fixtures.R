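library(data.table)

# minimal person/table builders for hand-constructed scenarios

mk_persons <- function(ids, birth = "1950-01-01", sex = "male",
                       death = NA, immigration = NA, emigration = NA,
                       education = "medium", pob = "Norway") {
  data.table(person_id = ids, sex = sex, birth_date = birth,
             death_date = death, immigration_date = immigration,
             emigration_date = emigration, education_level = education,
             place_of_birth = pob)
}

mk_rx <- function(id = character(), date = character(), atc = character()) {
  data.table(person_id = id, dispense_date = date, atc_code = atc)
}

mk_dx <- function(id = character(), date = character(),
                  code = character()) {
  data.table(person_id = id, event_date = date, code = code)
}

# one-person bundle from event kind strings: E* -> specialist, T* ->
# primary care, A10* -> prescriptions
mk_bundle1 <- function(kinds, dates, id = "P1", birth = "1950-01-01",
                       config = study_config()) {
  kinds <- as.character(kinds); dates <- as.character(dates)
  is_e <- startsWith(kinds, "E")
  is_t <- startsWith(kinds, "T")
  is_a <- startsWith(kinds, "A")
  registry_bundle(
    mk_persons(id, birth = birth),
    mk_rx(rep(id, sum(is_a)), dates[is_a], kinds[is_a]),
    mk_dx(rep(id, sum(is_e)), dates[is_e], kinds[is_e]),
    mk_dx(rep(id, sum(is_t)), dates[is_t], kinds[is_t]),
    config = config)
}

# multi-person bundle: one row per (person, kind, date)
mk_bundle_streams <- function(streams, birth = "1950-01-01",
                              config = study_config()) {
  ids <- rep(names(streams), vapply(streams, function(s) nrow(s), 1L))
  ev <- rbindlist(streams)
  ev[, person_id := ids]
  is_e <- startsWith(ev$kind, "E")
  is_t <- startsWith(ev$kind, "T")
  is_a <- startsWith(ev$kind, "A")
  registry_bundle(
    mk_persons(names(streams), birth = birth),
    mk_rx(ev$person_id[is_a], ev$date[is_a], ev$kind[is_a]),
    mk_dx(ev$person_id[is_e], ev$date[is_e], ev$kind[is_e]),
    mk_dx(ev$person_id[is_t], ev$date[is_t], ev$kind[is_t]),
    config = config)
}

# a small simulation preset with perfect recording: registration on the
# onset day, guaranteed next-day confirmation, both registers always
perfect_recording_config <- function(n, seed) {
  sim_config(
    n_persons = n, seed = seed,
    care_model = list(
      first_registration_delay_days = 0,
      confirmation_delay_days = 0,
      register_profile_treated = c(both = 1, specialist = 0, primary = 0),
      register_profile_untreated = c(both = 1, specialist = 0, primary = 0),
      p_register_per_visit = 1,
      p_unclassifiable_coding = 0,
      p_drug_without_diagnosis = 0,
      prevalent_fraction = 0))
}
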