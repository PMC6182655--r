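#' Open-cohort follow-up windows
#'
#' Entry is the latest of the study start, the 30th birthday and one year
#' after immigration. Exit is the earliest of: the day after the first
#' diabetes evidence (case onset for incident cases, any diagnosis or
#' dispensing otherwise; the terminating day itself contributes one day of
#' person-time), emigration, death, the 90th birthday, and the end of the
#' incidence follow-up period. All intervals are half-open
#' `[entry, exit)`; ties are resolved in that listed order. Persons whose
#' window is empty are dropped and reported in the `dropped` attribute
#' with a reason.
#'
#' @param persons Person table of a [registry_bundle()].
#' @param cases Incidence-mode [phenotype_registry()] output (supplies the
#'   onset/evidence exit; persons flagged `excluded_washout` are dropped).
#' @param config A [study_config()].
#' @return `data.table` with `person_id`, `entry_date`, `exit_date`,
#'   `exit_reason` (`case_onset`, `any_dx_or_drug`, `emigration`, `death`,
#'   `age_90`, `period_end`); attribute `dropped` holds the excluded
#'   persons and reasons.
#' @export
eligibility_windows <- function(persons, cases, config = study_config()) {
  persons <- normalise_persons(persons)
  w <- persons[, .(person_id, birth_date, death_date, immigration_date,
                   emigration_date)]
  w <- cases[, .(person_id, status, onset_date, index_date)][w,
                                                             on = "person_id"]
  lag <- config$immigration_lag_days
  w[, entry_date := data.table::as.IDate(pmax(
    as.integer(config$study_start),
    as.integer(anniversary(birth_date, config$min_age_years)),
    data.table::fifelse(is.na(immigration_date),
                        as.integer(config$study_start),
                        as.integer(immigration_date) + lag)))]

  far <- as.integer(config$prevalence_end) + 365000L
  w[, evidence_exit := data.table::fifelse(
    !is.na(status) & status == "incident_case",
    as.integer(onset_date) + 1L,
    data.table::fifelse(!is.na(index_date),
                        as.integer(index_date) + 1L, far))]
  w[, c_emig := data.table::fifelse(is.na(emigration_date), far,
                                    as.integer(emigration_date))]
  w[, c_death := data.table::fifelse(is.na(death_date), far,
                                     as.integer(death_date))]
  w[, c_age := as.integer(anniversary(birth_date, config$max_age_years))]
  w[, c_end := as.integer(config$incidence_follow_up_end)]

  cand <- as.matrix(w[, .(evidence_exit, c_emig, c_death, c_age, c_end)])
  pick <- max.col(-cand, ties.method = "first")
  w[, exit_date := data.table::as.IDate(cand[cbind(seq_len(.N), pick)])]
  reasons <- c("any_dx_or_drug", "emigration", "death", "age_90",
               "period_end")
  w[, exit_reason := reasons[pick]]
  w[exit_reason == "any_dx_or_drug" & !is.na(status) &
      status == "incident_case", exit_reason := "case_onset"]

  w[, drop_reason := data.table::fcase(
    !is.na(status) & status == "excluded_washout", "washout",
    entry_date >= exit_date, "no_person_time",
    default = NA_character_)]
  dropped <- w[!is.na(drop_reason), .(person_id, drop_reason)]
  out <- w[is.na(drop_reason),
           .(person_id, entry_date, exit_date, exit_reason)]
  data.table::setkey(out, person_id)
  data.table::setattr(out, "dropped", dropped)
  out[]
}

#' Lexis expansion of follow-up windows
#'
#' Splits each follow-up window at every 1 January and at the attained-age
#' band boundaries (the 50th and 70th birthdays; the 30th and 90th bound
#' the window itself), so every segment lies within one calendar year and
#' one age band. Segments tile the window exactly, in days. The age band
#' is assigned by attained age at segment start; a fixed 10-year birth
#' cohort label and the person's covariates are attached.
#'
#' @param windows Output of [eligibility_windows()].
#' @param persons Person table.
#' @param config A [study_config()].
#' @return `data.table` of segments: `person_id`, `start`, `end`,
#'   `calendar_year`, `age_band`, `birth_decade`, `sex`,
#'   `education_level`, `place_of_birth`, `duration_years`.
#' @export
lexis_split <- function(windows, persons, config = study_config()) {
  persons <- normalise_persons(persons)
  w <- persons[, .(person_id, birth_date, sex, education_level,
                   place_of_birth)][windows, on = "person_id"]
  n <- nrow(w)
  band_breaks <- seq(config$min_age_years + 20L, config$max_age_years - 1L,
                     by = 20L)  # 50, 70 for the 30/50/70/90 grid
  empty <- data.table::data.table(
    person_id = character(),
    start = data.table::as.IDate(integer()),
    end = data.table::as.IDate(integer()),
    calendar_year = integer(), age_band = character(),
    birth_decade = character(), sex = character(),
    education_level = character(), place_of_birth = character(),
    duration_years = numeric())
  if (n == 0L) return(empty)

  # candidate cut points: window ends, Jan 1s, band birthdays
  y0 <- iyear(w$entry_date); y1 <- iyear(w$exit_date - 1L)
  nyr <- pmax(0L, y1 - y0)
  idx <- rep(seq_len(n), nyr)
  jan_cuts <- data.table::data.table(
    i = idx, cut = jan1(y0[idx] + sequence(nyr)))
  bd <- data.table::data.table(
    i = rep(seq_len(n), length(band_breaks)),
    cut = data.table::as.IDate(unlist(lapply(
      band_breaks, function(a) anniversary(w$birth_date, a)))))
  bd <- bd[cut > w$entry_date[i] & cut < w$exit_date[i]]
  jan_cuts <- jan_cuts[cut > w$entry_date[i] & cut < w$exit_date[i]]
  cuts <- rbind(
    data.table::data.table(i = seq_len(n), cut = w$entry_date),
    jan_cuts, bd,
    data.table::data.table(i = seq_len(n), cut = w$exit_date))
  cuts <- unique(cuts)[order(i, cut)]
  cuts[, nxt := data.table::shift(cut, -1L), by = i]
  seg <- cuts[!is.na(nxt)]

  out <- data.table::data.table(
    person_id = w$person_id[seg$i],
    start = seg$cut, end = data.table::as.IDate(seg$nxt))
  birth <- w$birth_date[seg$i]
  age_lo <- c(config$min_age_years, band_breaks)
  age_hi <- c(band_breaks, config$max_age_years)
  band_lab <- sprintf("%d-%d", age_lo, age_hi - 1L)
  bidx <- rowSums(matrix(unlist(lapply(
    band_breaks, function(a) out$start >= anniversary(birth, a))),
    ncol = length(band_breaks))) + 1L
  out[, calendar_year := iyear(start)]
  out[, age_band := band_lab[bidx]]
  out[, birth_decade := sprintf("%d-%d", 10L * (iyear(birth) %/% 10L),
                                10L * (iyear(birth) %/% 10L) + 9L)]
  out[, `:=`(sex = w$sex[seg$i], education_level = w$education_level[seg$i],
             place_of_birth = w$place_of_birth[seg$i])]
  out[, duration_years := as.numeric(end - start) / 365.25]
  data.table::setkey(out, person_id, start)
  out[]
}

#' Aggregate person-time and cases into strata
#'
#' Sums person-years over Lexis segments by the grouping keys and counts
#' incident cases in the stratum containing their onset date. Person-years
#' use the 365.25-days convention. A case whose onset does not fall inside
#' one of its person's segments raises a consistency error; incident cases
#' of persons with no follow-up window (e.g. onset before cohort entry)
#' are not counted.
#'
#' @param segments Output of [lexis_split()].
#' @param cases Incidence-mode [phenotype_registry()] output.
#' @param by Character vector of grouping keys (default
#'   `"calendar_year"`); use `character(0)` for the grand total.
#' @return `data.table` of strata with `cases` and `person_years`.
#' @export
aggregate_strata <- function(segments, cases, by = "calendar_year") {
  inc <- cases[status == "incident_case", .(person_id, onset_date)]
  inc <- inc[person_id %in% segments$person_id]
  # persons who exited the cohort before onset (another exit reason won)
  # contribute no case; an onset inside the tiled span that matches no
  # segment would be a genuine inconsistency
  span <- segments[, .(span_start = min(start), span_end = max(end)),
                   by = person_id]
  inc <- span[inc, on = "person_id"]
  inc <- inc[onset_date >= span_start & onset_date < span_end]
  hit <- segments[inc, on = .(person_id, start <= onset_date,
                              end > onset_date), nomatch = NA,
                  .(person_id, onset_date = i.onset_date, x.start)]
  if (anyNA(hit$x.start))
    stop("consistency error: incident onset outside the person's ",
         "follow-up window for person(s) ",
         paste(utils::head(hit$person_id[is.na(hit$x.start)], 5L),
               collapse = ", "))
  case_seg <- segments[inc, on = .(person_id, start <= onset_date,
                                   end > onset_date), nomatch = NULL]
  if (length(by) == 0L) {
    out <- data.table::data.table(cases = nrow(case_seg),
                                  person_years =
                                    sum(segments$duration_years))
    return(out)
  }
  py <- segments[, .(person_years = sum(duration_years)), keyby = by]
  cs <- case_seg[, .(cases = .N), keyby = by]
  out <- cs[py]
  data.table::set(out, which(is.na(out$cases)), "cases", 0L)
  data.table::setcolorder(out, c(by, "cases", "person_years"))
  out[]
}
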