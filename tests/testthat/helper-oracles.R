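# Independent brute-force oracles. These re-derive the expected behaviour
# from the stated rules with plain loops and day-by-day counting, sharing
# no code with the package implementation.

# rule-checking oracle for one person's event stream
# kinds: code strings; E*/T* diagnoses, A10* dispensings
oracle_classify <- function(kinds, dates, cfg = study_config()) {
  kinds <- as.character(kinds)
  dates <- as.Date(as.character(dates))
  is_dx <- grepl("^[ET]", kinds)
  is_rx <- startsWith(kinds, "A10")
  dx_dates <- dates[is_dx]
  rx_dates <- dates[is_rx]
  if (any(dates < as.Date(cfg$study_start)))
    return(list(status = "excluded_washout"))
  t2d_dates <- sort(unique(dates[grepl("^E11", kinds) |
                                   grepl("^T90", kinds)]))
  if (length(t2d_dates) == 0L) {
    if (length(rx_dates) > 0L && length(dx_dates) == 0L)
      return(list(status = "medication_without_diagnosis"))
    if (length(dx_dates) > 0L)
      return(list(status = "possible_unclassified"))
    return(list(status = "non_case"))
  }
  onset <- t2d_dates[1L]
  if (min(dates) < onset)
    return(list(status = "possible_unclassified"))
  wend <- onset + cfg$treatment_window_days
  a10b_win <- any(is_rx & startsWith(kinds, "A10B") &
                    dates >= onset & dates <= wend)
  a10_win <- any(is_rx & dates >= onset & dates <= wend)
  if (!(a10b_win || length(t2d_dates) >= 2L))
    return(list(status = "possible_unclassified"))
  if (onset > as.Date(cfg$incidence_follow_up_end))
    return(list(status = "non_case"))
  list(status = "incident_case",
       onset = onset,
       rule = if (a10b_win) "one_dx_plus_A10B" else "two_occasions",
       class = if (a10_win) "pharmacological" else "non_pharmacological")
}

# day-by-day person-time counter: assigns every followed day to a
# (calendar year, age band) cell
oracle_day_count <- function(entry, exit, birth) {
  entry <- as.Date(entry); exit <- as.Date(exit); birth <- as.Date(birth)
  if (entry >= exit) return(data.table(calendar_year = integer(),
                                       age_band = character(),
                                       days = integer()))
  bday <- function(years) {
    b <- as.POSIXlt(birth)
    b$year <- b$year + years
    as.Date(b)
  }
  b50 <- bday(50L); b70 <- bday(70L)
  days <- seq(entry, exit - 1, by = "day")
  band <- ifelse(days >= b70, "70-89", ifelse(days >= b50, "50-69",
                                              "30-49"))
  dt <- data.table(calendar_year = as.integer(format(days, "%Y")),
                   age_band = band)
  dt[, .(days = .N), by = .(calendar_year, age_band)]
}

# Breslow partial log-likelihood for one numeric covariate (no ties)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x,
                            grid = seq(-3, 3, by = 0.001)) {
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time,
               event = event, x = x)
  grid[which.max(ll)]
}
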