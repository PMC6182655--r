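#' Study configuration
#'
#' Bundles the fixed design constants of the open-cohort analysis: the study
#' window, age range, the one-year immigration lag before cohort entry, the
#' treatment-ascertainment window after first diagnosis, the first-month
#' window used for initial-regimen classification, the interruption date for
#' the segmented trend model, and the rate scale.
#'
#' Incident onsets are counted up to `incidence_follow_up_end`, six months
#' before the end of data availability (`prevalence_end`), so that every
#' onset has a full treatment-ascertainment window; confirmatory second
#' registrations may fall anywhere up to `prevalence_end`.
#'
#' @param study_start First day of follow-up (default 2009-01-01).
#' @param incidence_follow_up_end Last day an incident onset may occur
#'   (default 2014-06-30).
#' @param prevalence_end End of data availability and of the prevalence
#'   series (default 2014-12-31).
#' @param min_age_years,max_age_years Age range; follow-up runs from the
#'   `min_age_years`th birthday to the day before the `max_age_years`th
#'   (default 30 and 90; the upper bound is exclusive).
#' @param immigration_lag_days Days of residence required after immigration
#'   before cohort entry (default 365).
#' @param treatment_window_days Window after first type 2 diabetes
#'   registration within which a non-insulin glucose-lowering dispensing
#'   classifies the case as pharmacologically treated (default 183, i.e.
#'   six months).
#' @param first_month_window_days Window after the first dispensing within
#'   which dispensed substances define the initial regimen (default 30).
#' @param its_break_date Interruption date for the segmented trend model
#'   (default 2012-09-01, when HbA1c was recommended for diagnosing
#'   diabetes in Norway).
#' @param ci_z Normal quantile for confidence intervals (default 1.96).
#' @param rate_scale Person-time scale for rates (default 1e5, i.e. rates
#'   per 100,000 person-years).
#' @param prescription_start,primary_care_start,specialist_start First day
#'   of data availability per source (defaults 2004-01-01, 2006-01-01,
#'   2008-01-01).
#' @return An object of class `study_config` (a named list).
#' @export
#' @examples
#' cfg <- study_config()
#' cfg$treatment_window_days
study_config <- function(study_start = "2009-01-01",
                         incidence_follow_up_end = "2014-06-30",
                         prevalence_end = "2014-12-31",
                         min_age_years = 30L,
                         max_age_years = 90L,
                         immigration_lag_days = 365L,
                         treatment_window_days = 183L,
                         first_month_window_days = 30L,
                         its_break_date = "2012-09-01",
                         ci_z = 1.96,
                         rate_scale = 1e5,
                         prescription_start = "2004-01-01",
                         primary_care_start = "2006-01-01",
                         specialist_start = "2008-01-01") {
  cfg <- list(
    study_start = data.table::as.IDate(study_start),
    incidence_follow_up_end = data.table::as.IDate(incidence_follow_up_end),
    prevalence_end = data.table::as.IDate(prevalence_end),
    min_age_years = as.integer(min_age_years),
    max_age_years = as.integer(max_age_years),
    immigration_lag_days = as.integer(immigration_lag_days),
    treatment_window_days = as.integer(treatment_window_days),
    first_month_window_days = as.integer(first_month_window_days),
    its_break_date = data.table::as.IDate(its_break_date),
    ci_z = as.numeric(ci_z),
    rate_scale = as.numeric(rate_scale),
    prescription_start = data.table::as.IDate(prescription_start),
    primary_care_start = data.table::as.IDate(primary_care_start),
    specialist_start = data.table::as.IDate(specialist_start)
  )
  if (!(cfg$study_start < cfg$incidence_follow_up_end))
    stop("study_start must precede incidence_follow_up_end")
  if (!(cfg$incidence_follow_up_end <= cfg$prevalence_end))
    stop("incidence_follow_up_end must not exceed prevalence_end")
  if (cfg$min_age_years >= cfg$max_age_years)
    stop("min_age_years must be below max_age_years")
  win <- c(cfg$immigration_lag_days, cfg$treatment_window_days,
           cfg$first_month_window_days)
  if (any(win <= 0L)) stop("all windows must be positive")
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  follow-up:        %s to %s (incidence), data to %s\n",
              x$study_start, x$incidence_follow_up_end, x$prevalence_end))
  cat(sprintf("  age range:        %d to <%d years\n",
              x$min_age_years, x$max_age_years))
  cat(sprintf("  immigration lag:  %d days\n", x$immigration_lag_days))
  cat(sprintf("  treatment window: %d days; first-month window: %d days\n",
              x$treatment_window_days, x$first_month_window_days))
  cat(sprintf("  trend break:      %s\n", x$its_break_date))
  invisible(x)
}

#' Read/write a study configuration as a flat key-value file
#'
#' @param path File path; tab-separated `key<TAB>value` lines.
#' @return `read_study_config()` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  vals <- as.list(kv$V2)
  names(vals) <- kv$V1
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(study_config, vals)
}

#' @rdname read_study_config
#' @param config A `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  keys <- names(config)
  vals <- vapply(config, function(v) as.character(v), character(1))
  utils::write.table(data.frame(keys, vals), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- internal date helpers --------------------------------------------------

# k-th anniversary of a date, vectorised; Feb 29 maps to Mar 1 off leap years
anniversary <- function(date, k) {
  lt <- as.POSIXlt(as.Date(date))
  lt$year <- lt$year + as.integer(k)
  data.table::as.IDate(as.Date(lt))
}

# fractional calendar years between dates (365.25-day convention)
years_between <- function(from, to) {
  as.numeric(to - from) / 365.25
}

# Jan 1 of a calendar year, as IDate
jan1 <- function(year) {
  if (length(year) == 0L) return(data.table::as.IDate(integer()))
  data.table::as.IDate(paste0(year, "-01-01"))
}

iyear <- function(date) data.table::year(date)
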