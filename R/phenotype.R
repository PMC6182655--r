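#' Washout flags: pre-study diabetes evidence
#'
#' A person is excluded by washout if any diabetes diagnosis of any type
#' (ICD-10 E10-E14 or ICPC-2 T89/T90) or any glucose-lowering dispensing
#' (ATC A10*) is registered strictly before the study start. Washout
#' dominates: any pre-study evidence excludes the person regardless of
#' later events.
#'
#' @param bundle A [registry_bundle()].
#' @param config A [study_config()].
#' @return `data.table` with `person_id` and logical `excluded_washout`,
#'   one row per person.
#' @export
washout_flag <- function(bundle, config = study_config()) {
  pre <- unique(c(
    bundle$prescriptions[dispense_date < config$study_start, person_id],
    bundle$specialist_dx[event_date < config$study_start, person_id],
    bundle$primary_dx[event_date < config$study_start, person_id]))
  out <- data.table::data.table(person_id = bundle$persons$person_id)
  out[, excluded_washout := person_id %in% pre]
  data.table::setkey(out, person_id)
  out[]
}

# stack the three event tables into one stream with type flags
event_stream <- function(bundle) {
  dx <- rbind(
    bundle$specialist_dx[, .(person_id, date = event_date, code,
                             source = "specialist")],
    bundle$primary_dx[, .(person_id, date = event_date, code,
                          source = "primary_care")])
  dx[, `:=`(is_dx = TRUE,
            t2d = startsWith(code, "E11") | startsWith(code, "T90"),
            a10b = FALSE, a10 = FALSE)]
  rx <- bundle$prescriptions[, .(person_id, date = dispense_date,
                                 code = atc_code, source = "prescription")]
  rx[, `:=`(is_dx = FALSE, t2d = FALSE,
            a10b = startsWith(code, "A10B"), a10 = TRUE)]
  ev <- rbind(dx, rx)
  data.table::setkey(ev, person_id, date)
  ev
}

#' Classify every person against the type 2 diabetes case definition
#'
#' Implements the register-based case-ascertainment algorithm. In
#' `"incidence"` mode, persons with any diabetes evidence before the study
#' start are excluded (washout); for the rest, the onset date is the first
#' type 2 diabetes registration (E11 from specialist care or T90 from
#' primary care), and a person is an incident case when either
#' \itemize{
#' \item at least one non-insulin glucose-lowering dispensing (A10B) falls
#'   within the treatment window after onset (`one_dx_plus_A10B`), or
#' \item type 2 diabetes is registered on at least two distinct dates,
#'   pooling both diagnosis sources (`two_occasions`); the confirmatory
#'   registration may fall any time up to the end of data availability.
#' }
#' Incident onsets are restricted to the window from `study_start` to
#' `incidence_follow_up_end`. Because follow-up ends at the first diabetes
#' evidence of any kind, an incident case additionally requires that no
#' other diabetes diagnosis and no glucose-lowering dispensing precede the
#' onset (same-day events are allowed); persons failing only this ordering
#' requirement are `possible_unclassified`.
#'
#' Treatment class: `pharmacological` when any glucose-lowering dispensing
#' (A10, insulins included for two-occasion cases) falls within the
#' treatment window after onset; otherwise `non_pharmacological`. Persons
#' with exactly one type 2 diabetes registration and no qualifying
#' dispensing are `possible_unclassified`; persons dispensed A10 drugs but
#' never registered with any diabetes diagnosis are
#' `medication_without_diagnosis`.
#'
#' In `"prevalence"` mode no washout or ordering restriction applies: a
#' person qualifies when they have at least one E11/T90 registration plus
#' at least one A10B dispensing (any time), or registrations on two
#' distinct dates; `qualify_date` is the day the criteria were first met.
#'
#' @param bundle A [registry_bundle()].
#' @param config A [study_config()].
#' @param mode `"incidence"` (default) or `"prevalence"`.
#' @return A keyed `data.table` with one row
#'   per person. In incidence mode the columns are `person_id`, `status`,
#'   `onset_date`, `index_date` (first evidence anchoring the sensitivity
#'   categories), `treatment_class`, `qualifying_rule`,
#'   `registers_involved` (comma-joined), `n_registers` and
#'   `initial_regimen`. In prevalence mode: `person_id`, `qualified`,
#'   `onset_date`, `qualify_date`.
#' @export
phenotype_registry <- function(bundle, config = study_config(),
                               mode = c("incidence", "prevalence")) {
  mode <- match.arg(mode)
  ev <- event_stream(bundle)
  if (mode == "prevalence") return(phenotype_prevalence(bundle, ev, config))

  wf <- washout_flag(bundle, config)
  W <- config$treatment_window_days

  per <- ev[, .(
    n_t2d_dates = data.table::uniqueN(date[t2d]),
    onset = suppressWarnings(min(date[t2d])),
    first_evidence = min(date),
    any_dx = any(is_dx),
    any_rx = any(!is_dx),
    first_rx = suppressWarnings(min(date[!is_dx]))
  ), by = person_id]
  per[, onset := data.table::as.IDate(ifelse(is.finite(onset), onset,
                                             NA_integer_))]
  per[, first_rx := data.table::as.IDate(ifelse(is.finite(first_rx),
                                                first_rx, NA_integer_))]
  # window-dependent quantities need the onset joined back onto events
  evo <- ev[per[!is.na(onset)], on = "person_id"]
  win <- evo[, .(
    a10b_in_window = any(a10b & date >= onset & date <= onset + W),
    a10_in_window = any(a10 & date >= onset & date <= onset + W),
    spec_t2d = any(t2d & source == "specialist"),
    prim_t2d = any(t2d & source == "primary_care")
  ), by = person_id]
  per <- win[per, on = "person_id"]
  per <- per[wf, on = "person_id"]
  per[is.na(n_t2d_dates), `:=`(n_t2d_dates = 0L, any_dx = FALSE,
                               any_rx = FALSE)]
  for (col in c("a10b_in_window", "a10_in_window", "spec_t2d", "prim_t2d"))
    data.table::set(per, which(is.na(per[[col]])), col, FALSE)

  per[, status := "non_case"]
  per[, `:=`(treatment_class = NA_character_,
             qualifying_rule = NA_character_,
             registers_involved = NA_character_,
             index_date = data.table::as.IDate(NA_integer_))]

  per[excluded_washout == TRUE, status := "excluded_washout"]

  # no T2D registration ever
  per[excluded_washout == FALSE & n_t2d_dates == 0L & any_rx & !any_dx,
      `:=`(status = "medication_without_diagnosis", index_date = first_rx)]
  per[excluded_washout == FALSE & n_t2d_dates == 0L & any_dx,
      `:=`(status = "possible_unclassified", index_date = first_evidence)]

  # T2D registered: evaluate the two qualifying rules
  has <- per[excluded_washout == FALSE & n_t2d_dates > 0L, which = TRUE]
  per[has, ordered_ok := first_evidence >= onset]
  per[has, in_window := onset >= config$study_start &
        onset <= config$incidence_follow_up_end]
  per[has, qualifies := a10b_in_window | n_t2d_dates >= 2L]

  per[has, status := data.table::fcase(
    !ordered_ok, "possible_unclassified",
    !qualifies, "possible_unclassified",
    !in_window, "non_case",
    default = "incident_case")]
  per[has, index_date := onset]
  per[status == "incident_case", `:=`(
    qualifying_rule = ifelse(a10b_in_window, "one_dx_plus_A10B",
                             "two_occasions"),
    treatment_class = ifelse(a10_in_window, "pharmacological",
                             "non_pharmacological"))]

  # register provenance for incident cases
  per[status == "incident_case", `:=`(
    registers_involved = {
      regs <- Map(function(s, p, rxq) {
        r <- c(if (rxq) "prescription", if (s) "specialist",
               if (p) "primary_care")
        paste(r, collapse = ",")
      }, spec_t2d, prim_t2d, a10_in_window & treatment_class ==
        "pharmacological")
      unlist(regs)
    })]
  per[, n_registers := ifelse(is.na(registers_involved), NA_integer_,
                              lengths(strsplit(registers_involved, ",")))]
  per[status != "incident_case", onset_date :=
        data.table::as.IDate(NA_integer_)]
  per[status == "incident_case", onset_date := onset]

  regimen <- classify_regimen(per[status == "incident_case" &
                                    treatment_class == "pharmacological",
                                  .(person_id, onset_date)],
                              bundle$prescriptions, config)
  per <- regimen[per, on = "person_id"]

  out <- per[, .(person_id, status, onset_date, index_date, treatment_class,
                 qualifying_rule, registers_involved, n_registers,
                 initial_regimen)]
  data.table::setkey(out, person_id)
  out[]
}

phenotype_prevalence <- function(bundle, ev, config) {
  per <- ev[, {
    td <- sort(unique(date[t2d]))
    ab <- suppressWarnings(min(date[a10b]))
    first_t2d <- if (length(td)) td[1L] else NA_integer_
    second_t2d <- if (length(td) >= 2L) td[2L] else NA_integer_
    r1 <- if (length(td) && is.finite(ab)) max(td[1L], ab) else NA_integer_
    qd <- suppressWarnings(min(c(r1, second_t2d), na.rm = TRUE))
    .(onset_date = data.table::as.IDate(first_t2d),
      qualify_date = data.table::as.IDate(
        ifelse(is.finite(qd), qd, NA_integer_)))
  }, by = person_id]
  out <- data.table::data.table(person_id = bundle$persons$person_id)
  out <- per[out, on = "person_id"]
  out[, qualified := !is.na(qualify_date) &
        qualify_date <= config$prevalence_end]
  data.table::setkey(out, person_id)
  out[]
}

#' Initial-regimen classification for pharmacologically treated cases
#'
#' The initial regimen is read off the distinct ATC substances dispensed
#' within the first-month window after the first on-or-after-onset
#' dispensing: all substances insulins (A10A) gives `insulin_only`; two or
#' more distinct substances gives `multi_drug`; a single substance gives
#' `metformin_mono` (A10BA02), `sulfonylurea_mono` (A10BB*) or
#' `other_oral_mono`.
#'
#' @param cases `data.table` with `person_id` and `onset_date` of
#'   pharmacologically treated incident cases.
#' @param prescriptions Prescription event table.
#' @param config A [study_config()].
#' @return `data.table` with `person_id` and `initial_regimen`.
#' @export
classify_regimen <- function(cases, prescriptions,
                             config = study_config()) {
  if (nrow(cases) == 0L)
    return(data.table::data.table(person_id = character(),
                                  initial_regimen = character()))
  rx <- prescriptions[cases, on = "person_id", nomatch = NULL]
  rx <- rx[dispense_date >= onset_date]
  rx[, first_rx := min(dispense_date), by = person_id]
  rx <- rx[dispense_date <= first_rx + config$first_month_window_days]
  reg <- rx[, {
    subs <- unique(atc_code)
    cls <- if (all(startsWith(subs, "A10A"))) "insulin_only"
    else if (length(subs) >= 2L) "multi_drug"
    else if (subs == "A10BA02") "metformin_mono"
    else if (startsWith(subs, "A10BB")) "sulfonylurea_mono"
    else "other_oral_mono"
    .(initial_regimen = cls)
  }, by = person_id]
  reg[cases[, .(person_id)], on = "person_id"]
}

#' Yearly counts of possible-but-unclassified diabetes
#'
#' Sensitivity-analysis summary: per calendar year, the number of persons
#' first flagged `possible_unclassified` (anchored at their first
#' qualifying-adjacent registration) and `medication_without_diagnosis`
#' (anchored at their first glucose-lowering dispensing).
#'
#' @param cases Incidence-mode [phenotype_registry()] output.
#' @param config A [study_config()].
#' @param years Calendar years to tabulate (default: study years).
#' @return `data.table` with columns `calendar_year`,
#'   `possible_unclassified`, `medication_without_diagnosis`.
#' @export
unclassified_summary <- function(cases, config = study_config(),
                                 years = NULL) {
  if (is.null(years))
    years <- seq(iyear(config$study_start),
                 iyear(config$incidence_follow_up_end))
  u <- cases[status == "possible_unclassified" & !is.na(index_date),
             .N, by = .(calendar_year = iyear(index_date))]
  m <- cases[status == "medication_without_diagnosis" & !is.na(index_date),
             .N, by = .(calendar_year = iyear(index_date))]
  out <- data.table::data.table(calendar_year = as.integer(years))
  out[, possible_unclassified := u$N[match(calendar_year, u$calendar_year)]]
  out[, medication_without_diagnosis :=
        m$N[match(calendar_year, m$calendar_year)]]
  for (col in c("possible_unclassified", "medication_without_diagnosis"))
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  out[]
}

#' Register-overlap distribution among incident cases
#'
#' Proportion of incident cases ascertained from one, two or all three of
#' the contributing registers (prescriptions, specialist care, primary
#' care).
#'
#' @param cases Incidence-mode [phenotype_registry()] output.
#' @return `data.table` with `n_registers`, `n` and `proportion`
#'   (proportions sum to 1); zero rows for empty input.
#' @export
register_overlap_summary <- function(cases) {
  inc <- cases[status == "incident_case"]
  if (nrow(inc) == 0L)
    return(data.table::data.table(n_registers = integer(), n = integer(),
                                  proportion = numeric()))
  tab <- inc[, .N, by = n_registers][order(n_registers)]
  data.table::setnames(tab, "N", "n")
  tab[, proportion := n / sum(n)]
  tab[]
}

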