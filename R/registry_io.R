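#' Registry bundle: the four linked tables
#'
#' A `registry_bundle` holds the four tables of a linked national-registry
#' extract: one row per person (demographics and residency history), and
#' three longitudinal event tables — pharmacy dispensings of glucose-lowering
#' drugs (ATC `A10*`), specialist-care diabetes diagnoses (ICD-10 `E10`-`E14`)
#' and primary-care diabetes diagnoses (ICPC-2 `T89`/`T90`).
#'
#' @param persons data.frame with columns `person_id`, `sex`
#'   (`male`/`female`), `birth_date`, `death_date`, `immigration_date`,
#'   `emigration_date` (ISO dates, `NA` when absent), `education_level`
#'   (`low`/`medium`/`high`/`missing`) and `place_of_birth` (one of
#'   [pob_levels()]).
#' @param prescriptions data.frame with `person_id`, `dispense_date`,
#'   `atc_code`.
#' @param specialist_dx data.frame with `person_id`, `event_date`, `code`
#'   (ICD-10).
#' @param primary_dx data.frame with `person_id`, `event_date`, `code`
#'   (ICPC-2).
#' @param config A [study_config()]; supplies the source availability
#'   windows used in validation.
#' @param validate Validate invariants (default `TRUE`).
#' @return An object of class `registry_bundle`: a list of four
#'   `data.table`s, each sorted by (`person_id`, date).
#' @export
registry_bundle <- function(persons, prescriptions, specialist_dx,
                            primary_dx, config = study_config(),
                            validate = TRUE) {
  b <- structure(list(
    persons = normalise_persons(persons),
    prescriptions = normalise_events(prescriptions, "dispense_date",
                                     "atc_code"),
    specialist_dx = normalise_events(specialist_dx, "event_date", "code"),
    primary_dx = normalise_events(primary_dx, "event_date", "code")
  ), class = "registry_bundle")
  if (validate) validate_registry(b, config)
  b
}

#' Category levels used in the person table
#'
#' @return Character vector of levels.
#' @export
pob_levels <- function() {
  c("Norway", "Europe-excl-Norway", "Africa", "Asia",
    "North-Central-America", "South-America", "Oceania")
}

#' @rdname pob_levels
#' @export
education_levels <- function() c("low", "medium", "high", "missing")

person_cols <- c("person_id", "sex", "birth_date", "death_date",
                 "immigration_date", "emigration_date", "education_level",
                 "place_of_birth")

normalise_persons <- function(p) {
  p <- data.table::as.data.table(p)
  missing_cols <- setdiff(person_cols, names(p))
  if (length(missing_cols))
    stop("persons table lacks columns: ", paste(missing_cols, collapse = ", "))
  p <- p[, person_cols, with = FALSE]
  p[, person_id := as.character(person_id)]
  for (col in c("birth_date", "death_date", "immigration_date",
                "emigration_date"))
    data.table::set(p, j = col, value = parse_idate(p[[col]], col))
  data.table::setkey(p, person_id)
  p
}

normalise_events <- function(e, date_col, code_col) {
  e <- data.table::as.data.table(e)
  need <- c("person_id", date_col, code_col)
  missing_cols <- setdiff(need, names(e))
  if (length(missing_cols))
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "))
  e <- e[, need, with = FALSE]
  e[, person_id := as.character(person_id)]
  data.table::set(e, j = date_col, value = parse_idate(e[[date_col]], date_col))
  data.table::set(e, j = code_col, value = as.character(e[[code_col]]))
  data.table::setkeyv(e, c("person_id", date_col))
  e
}

parse_idate <- function(x, what) {
  if (inherits(x, "Date")) return(data.table::as.IDate(x))
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  bad <- !is.na(x) & !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(bad))
    stop(sprintf("malformed date in '%s' at row(s) %s: %s", what,
                 paste(utils::head(which(bad), 5L), collapse = ", "),
                 paste(utils::head(x[bad], 5L), collapse = ", ")))
  out <- data.table::as.IDate(x)
  failed <- !is.na(x) & is.na(out)
  if (any(failed))
    stop(sprintf("invalid calendar date in '%s' at row(s) %s", what,
                 paste(utils::head(which(failed), 5L), collapse = ", ")))
  out
}

#' Validate a registry bundle
#'
#' Checks the documented invariants: linkage (every event's `person_id`
#' resolves to a person), code families per source (`A10*` for
#' prescriptions, `E10`-`E14` for specialist care, `T89`/`T90` for primary
#' care; prefix match on the three-character stem, uppercase), source
#' availability windows, demographic category levels, and date ordering
#' (birth before death, immigration before emigration).
#'
#' @param bundle A `registry_bundle`.
#' @param config A [study_config()].
#' @return The bundle, invisibly; stops with a descriptive error otherwise.
#' @export
validate_registry <- function(bundle, config = study_config()) {
  p <- bundle$persons
  if (anyDuplicated(p$person_id))
    stop("duplicate person_id in persons table")
  if (any(!p$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(!p$education_level %in% education_levels()))
    stop("invalid education_level; expected one of ",
         paste(education_levels(), collapse = ", "))
  if (any(!p$place_of_birth %in% pob_levels()))
    stop("invalid place_of_birth")
  if (anyNA(p$birth_date)) stop("birth_date is required for every person")
  bad <- !is.na(p$death_date) & !(p$birth_date < p$death_date)
  if (any(bad))
    stop("birth_date must precede death_date: person(s) ",
         paste(utils::head(p$person_id[bad], 5L), collapse = ", "))
  bad <- !is.na(p$immigration_date) & !is.na(p$emigration_date) &
    !(p$immigration_date < p$emigration_date)
  if (any(bad))
    stop("immigration_date must precede emigration_date: person(s) ",
         paste(utils::head(p$person_id[bad], 5L), collapse = ", "))

  check_linkage <- function(e, nm) {
    orphan <- !(e$person_id %in% p$person_id)
    if (any(orphan))
      stop(sprintf("linkage error in %s: unknown person_id at row(s) %s (%s)",
                   nm, paste(utils::head(which(orphan), 5L), collapse = ", "),
                   paste(utils::head(unique(e$person_id[orphan]), 5L),
                         collapse = ", ")))
  }
  check_linkage(bundle$prescriptions, "prescriptions")
  check_linkage(bundle$specialist_dx, "specialist_dx")
  check_linkage(bundle$primary_dx, "primary_dx")

  rx <- bundle$prescriptions
  if (nrow(rx)) {
    bad <- !startsWith(rx$atc_code, "A10")
    if (any(bad))
      stop("validation error: non-A10 ATC code in prescriptions at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    if (any(rx$dispense_date < config$prescription_start))
      stop("prescription dispensings precede data availability (",
           config$prescription_start, ")")
  }
  sp <- bundle$specialist_dx
  if (nrow(sp)) {
    bad <- !grepl("^E1[0-4]", sp$code)
    if (any(bad))
      stop("validation error: specialist_dx codes must be ICD-10 E10-E14; ",
           "offending row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    if (any(sp$event_date < config$specialist_start))
      stop("specialist diagnoses precede data availability (",
           config$specialist_start, ")")
  }
  pc <- bundle$primary_dx
  if (nrow(pc)) {
    bad <- !grepl("^T(89|90)", pc$code)
    if (any(bad))
      stop("validation error: primary_dx codes must be ICPC-2 T89/T90; ",
           "offending row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    if (any(pc$event_date < config$primary_care_start))
      stop("primary-care diagnoses precede data availability (",
           config$primary_care_start, ")")
  }
  invisible(bundle)
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("Registry bundle\n")
  cat(sprintf("  persons:        %d\n", nrow(x$persons)))
  cat(sprintf("  prescriptions:  %d\n", nrow(x$prescriptions)))
  cat(sprintf("  specialist dx:  %d\n", nrow(x$specialist_dx)))
  cat(sprintf("  primary-care dx:%d\n", nrow(x$primary_dx)))
  invisible(x)
}

bundle_files <- c(persons = "persons.tsv", prescriptions = "prescriptions.tsv",
                  specialist_dx = "specialist_dx.tsv",
                  primary_dx = "primary_dx.tsv")

#' Read the four registry tables from delimited files
#'
#' Files are tab-delimited UTF-8 with a header row, ISO-8601 dates and the
#' empty string for absent dates (the format written by [write_registry()]).
#'
#' @param dir Directory containing `persons.tsv`, `prescriptions.tsv`,
#'   `specialist_dx.tsv` and `primary_dx.tsv`; alternatively pass the four
#'   paths explicitly.
#' @param paths Optional named character vector overriding the default
#'   file names (names: `persons`, `prescriptions`, `specialist_dx`,
#'   `primary_dx`).
#' @param config A [study_config()] used for validation.
#' @return A validated `registry_bundle`.
#' @export
read_registry <- function(dir = NULL, paths = NULL, config = study_config()) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- file.path(dir, bundle_files)
    names(paths) <- names(bundle_files)
  }
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("registry file(s) not found: ", paste(missing_files, collapse = ", "))
  rd <- function(f) data.table::fread(f, sep = "\t", header = TRUE,
                                      colClasses = "character",
                                      na.strings = NULL)
  registry_bundle(rd(paths[["persons"]]), rd(paths[["prescriptions"]]),
                  rd(paths[["specialist_dx"]]), rd(paths[["primary_dx"]]),
                  config = config)
}

#' Write a registry bundle to four delimited files
#'
#' Output is deterministic: fixed column order, rows sorted by
#' (`person_id`, date), ISO-8601 dates, empty string for absent dates.
#' Writing the same bundle twice produces byte-identical files.
#'
#' @param bundle A `registry_bundle`.
#' @param dir Output directory (created if needed).
#' @param config A [study_config()] used to re-validate before writing.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_registry <- function(bundle, dir, config = study_config()) {
  validate_registry(bundle, config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  wr <- function(dt, path) {
    out <- data.table::copy(dt)
    for (col in names(out))
      if (inherits(out[[col]], "IDate"))
        data.table::set(out, j = col,
                        value = ifelse(is.na(out[[col]]),
                                       "", format(out[[col]])))
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "",
                       eol = "\n")
  }
  wr(bundle$persons, paths[["persons"]])
  wr(bundle$prescriptions, paths[["prescriptions"]])
  wr(bundle$specialist_dx, paths[["specialist_dx"]])
  wr(bundle$primary_dx, paths[["primary_dx"]])
  invisible(paths)
}
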