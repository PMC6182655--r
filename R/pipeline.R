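#' Run the full registry analysis pipeline
#'
#' Orchestrates a deterministic end-to-end run: simulate (or read) the
#' registry, classify cases (incidence and prevalence modes), build
#' follow-up windows and Lexis segments, aggregate person-time, and fit
#' the trend and association models. All stage outputs are written as
#' tab-delimited files plus a JSON run manifest with a config hash, the
#' seed, stage timings and output checksums. Identical configuration and
#' seed give identical checksums; re-running restores any deleted output
#' byte-identically.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()] to simulate from, or `NULL` to read an
#'   existing registry from `registry_dir`.
#' @param registry_dir Directory with the four registry files (used when
#'   `sim` is `NULL`).
#' @param study A [study_config()].
#' @param strata_by Grouping keys for the stratified rate table.
#' @param verbose Emit per-stage log messages with rule counts.
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), registry_dir = NULL,
                         study = study_config(),
                         strata_by = c("calendar_year", "age_band", "sex"),
                         verbose = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  t0 <- proc.time()[["elapsed"]]
  if (!is.null(sim)) {
    s <- simulate_registry(sim, study)
    bundle <- s$bundle; truth <- s$truth
    reg_dir <- file.path(out_dir, "registry")
    write_registry(bundle, reg_dir, study)
    data.table::fwrite(format_dates(truth), file.path(reg_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, na = "", eol = "\n")
    log_msg("simulate: %d persons, %d true cases",
            nrow(bundle$persons), sum(!is.na(truth$onset_date)))
  } else {
    if (is.null(registry_dir)) stop("need either sim or registry_dir")
    bundle <- read_registry(registry_dir, config = study)
    truth <- NULL
    log_msg("read registry: %d persons", nrow(bundle$persons))
  }
  tick("registry", t0)

  t0 <- proc.time()[["elapsed"]]
  cases <- phenotype_registry(bundle, study, mode = "incidence")
  prev <- phenotype_registry(bundle, study, mode = "prevalence")
  counts <- cases[, .N, by = status]
  log_msg("phenotype: %s",
          paste(sprintf("%s=%d", counts$status, counts$N), collapse = ", "))
  write_tsv(cases, file.path(out_dir, "cases.tsv"))
  tick("phenotype", t0)

  t0 <- proc.time()[["elapsed"]]
  windows <- eligibility_windows(bundle$persons, cases, study)
  dropped <- attr(windows, "dropped")
  log_msg("persontime: %d windows (%d dropped: %s)", nrow(windows),
          nrow(dropped),
          paste(sprintf("%s=%d", names(table(dropped$drop_reason)),
                        table(dropped$drop_reason)), collapse = ", "))
  segments <- lexis_split(windows, bundle$persons, study)
  strata <- aggregate_strata(segments, cases, by = strata_by)
  yearly <- aggregate_strata(segments, cases, by = "calendar_year")
  write_tsv(format_dates(windows), file.path(out_dir, "windows.tsv"))
  write_tsv(add_rates(strata, study), file.path(out_dir, "strata.tsv"))
  tick("persontime", t0)

  t0 <- proc.time()[["elapsed"]]
  rates_year <- add_rates(yearly, study)
  prevalence <- period_prevalence(bundle$persons, prev, config = study)
  apc <- poisson_apc(yearly$calendar_year, yearly$cases,
                     yearly$person_years, study)
  monthly <- monthly_series(windows, cases, study)
  its <- its_fit(monthly$time, monthly$cases, monthly$person_years,
                 study$its_break_date, config = study)
  cox <- cox_fit(windows, cases, bundle$persons, config = study)
  unclassified <- unclassified_summary(cases, study)
  overlap <- register_overlap_summary(cases)
  log_msg("estimate: APC %.1f%%; ITS %.1f%% / %.1f%% (p=%.3g)",
          apc$apc, its$pre_slope_apc, its$post_slope_apc,
          its$slope_change_p)
  write_tsv(rates_year, file.path(out_dir, "rates_yearly.tsv"))
  write_tsv(prevalence, file.path(out_dir, "prevalence.tsv"))
  write_tsv(cox$table, file.path(out_dir, "hazard_ratios.tsv"))
  write_tsv(unclassified, file.path(out_dir, "unclassified.tsv"))
  write_tsv(overlap, file.path(out_dir, "register_overlap.tsv"))
  trend <- data.table::data.table(
    quantity = c("apc", "apc_ci_low", "apc_ci_high", "its_pre_apc",
                 "its_post_apc", "its_slope_change_p"),
    value = c(apc$apc, apc$ci_low, apc$ci_high, its$pre_slope_apc,
              its$post_slope_apc, its$slope_change_p))
  write_tsv(trend, file.path(out_dir, "trend.tsv"))
  tick("estimate", t0)

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  checksums <- tools::md5sum(sort(outputs))
  names(checksums) <- sub(paste0("^", out_dir, "/?"), "",
                          names(checksums))
  manifest <- list(
    config_hash = config_hash(list(sim = unclass_config(sim),
                                   study = unclass_config(study),
                                   strata_by = strata_by)),
    seed = if (!is.null(sim)) sim$seed else NA_integer_,
    timings_sec = as.list(timings),
    checksums = as.list(checksums),
    elapsed_sec = round(proc.time()[["elapsed"]] - t_start, 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bundle = bundle, truth = truth, cases = cases,
                 prevalence_cases = prev, windows = windows,
                 segments = segments, strata = strata,
                 rates_yearly = rates_year, prevalence = prevalence,
                 apc = apc, its = its, cox = cox,
                 unclassified = unclassified, overlap = overlap,
                 manifest = manifest))
}

write_tsv <- function(dt, path) {
  data.table::fwrite(format_dates(dt), path, sep = "\t", quote = FALSE,
                     na = "", eol = "\n")
  invisible(path)
}

format_dates <- function(dt) {
  out <- data.table::as.data.table(dt)
  for (col in names(out))
    if (inherits(out[[col]], "Date") || inherits(out[[col]], "IDate"))
      data.table::set(out, j = col, value = ifelse(is.na(out[[col]]), "",
                                                   format(out[[col]])))
  out
}

unclass_config <- function(x) {
  if (is.null(x)) return(NULL)
  rapply(unclass(x), as.character, how = "replace")
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a simulation configuration from a YAML file
#'
#' The file may contain top-level `n_persons` and `seed` plus optional
#' `demography`, `disease_model` and `care_model` mappings overriding
#' individual defaults of [sim_config()].
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (sec in c("demography", "disease_model", "care_model"))
    if (!is.null(y[[sec]]))
      y[[sec]] <- lapply(y[[sec]], function(v)
        if (is.list(v)) unlist(v) else v)
  sim_config(n_persons = y$n_persons %||% 10000L,
             seed = y$seed %||% 1L,
             demography = y$demography %||% list(),
             disease_model = y$disease_model %||% list(),
             care_model = y$care_model %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
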