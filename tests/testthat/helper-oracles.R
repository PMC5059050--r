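# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive — day-by-day simulation, token lookup, 1-D grid search —
# and share no code with the package implementations they check.

# ---- day-granularity consumption simulator -------------------------------
#
# fills: data.frame(day, tablets, dose) with integer doses; same-day fills
# must share one dose. Walks calendar days keeping a tablet stock: a fill on
# a covered day adds its tablets to the remaining stock (carry-over, consumed
# at the incoming fill's dose); on an uncovered day it replaces the stock.
# Returns the covered-day runs as intervals [start, end).
oracle_runs <- function(fills, horizon = 2000) {
  fills <- fills[order(fills$day), , drop = FALSE]
  stock <- 0
  dose <- 1
  runs <- list()
  run_start <- NA
  for (d in fills$day[1]:horizon) {
    todays <- fills[fills$day == d, , drop = FALSE]
    if (nrow(todays) > 0) {
      if (stock <= 0) stock <- 0
      stock <- stock + sum(todays$tablets)
      dose <- todays$dose[1]
    }
    covered <- stock > 0
    if (covered && is.na(run_start)) run_start <- d
    if (!covered && !is.na(run_start)) {
      runs[[length(runs) + 1]] <- c(run_start, d)
      run_start <- NA
    }
    if (covered) stock <- stock - dose
    if (!covered && d > max(fills$day)) break
  }
  if (!is.na(run_start)) runs[[length(runs) + 1]] <- c(run_start, horizon + 1)
  do.call(rbind, runs)
}

# grace-rule episode classification on top of oracle_runs; other_days are
# fill days of different antihypertensive classes
oracle_outcome <- function(fills, other_days = numeric(0),
                           grace = 30, followup = 730) {
  # coverage cannot outlast last fill day + total tablets (doses are >= 1)
  runs <- oracle_runs(fills, horizon = max(fills$day) + sum(fills$tablets) + grace + 10)
  E <- runs[1, 2]
  if (nrow(runs) > 1) {
    for (j in 2:nrow(runs)) {
      if (runs[j, 1] <= E + grace) E <- max(E, runs[j, 2]) else break
    }
  }
  index <- fills$day[1]
  if (E + grace >= index + followup) {
    return(list(status = "persistent", event_time = followup, supply_end = E - index))
  }
  in_grace <- other_days[other_days > E & other_days <= E + grace]
  status <- if (length(in_grace) > 0) "switched" else "discontinued"
  list(status = status, event_time = E - index, supply_end = E - index)
}

# random single-patient fill history (integer doses; same-day fills share a
# dose so the day-level oracle is exact)
random_history <- function() {
  n <- sample(1:6, 1)
  gaps <- sample(0:130, n, replace = TRUE)
  gaps[1] <- 0
  days <- cumsum(gaps)
  dose_of_day <- sapply(unique(days), function(d) sample(1:3, 1))
  names(dose_of_day) <- as.character(unique(days))
  data.frame(
    day = days,
    tablets = sample(5:120, n, replace = TRUE),
    dose = dose_of_day[as.character(days)]
  )
}

# a fills data.frame -> the package's input tibble (absolute dates), with a
# dosage text that parses to the given integer dose
fills_to_tibble <- function(fills, origin = as.Date("2006-01-01")) {
  txt <- c("1 tablet daily", "2 tablets daily", "3 tablets daily")
  tibble::tibble(
    patient_id = "X",
    fill_date = origin + fills$day,
    atc_code = "C09AA02",
    tablets = fills$tablets,
    dosage_text = txt[fills$dose]
  )
}

# ---- 1-D Cox partial-likelihood oracle (no ties) -------------------------
cox_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

cox_oracle_1d <- function(time, event, x) {
  stats::optimize(function(b) cox_loglik_1d(b, time, event, x),
                  interval = c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# ---- regex-free reference dosage parser ----------------------------------
# token-based lookup over the grammar vocabulary; returns tablets/day or NA
ref_parse_dosage <- function(text) {
  freq_mult <- c(
    "daily" = 1, "every day" = 1, "once daily" = 1, "once a day" = 1,
    "every other day" = 0.5,
    "twice daily" = 2, "twice a day" = 2, "two times daily" = 2,
    "three times daily" = 3, "three times a day" = 3, "3 times daily" = 3,
    "in the morning" = 1, "in the evening" = 1, "at night" = 1, "at bedtime" = 1
  )
  total <- 0
  for (clause in strsplit(tolower(text), " and ", fixed = TRUE)[[1]]) {
    tokens <- strsplit(trimws(clause), " ", fixed = TRUE)[[1]]
    tokens <- tokens[tokens != ""]
    if (length(tokens) < 2 || !(tokens[2] %in% c("tablet", "tablets"))) return(NA)
    q <- tokens[1]
    qty <- if (grepl("/", q, fixed = TRUE)) {
      parts <- as.numeric(strsplit(q, "/", fixed = TRUE)[[1]])
      parts[1] / parts[2]
    } else {
      suppressWarnings(as.numeric(q))
    }
    if (is.na(qty) || qty <= 0) return(NA)
    freq <- paste(tokens[-(1:2)], collapse = " ")
    mult <- if (freq == "") 1 else if (freq %in% names(freq_mult)) freq_mult[[freq]] else return(NA)
    total <- total + qty * mult
  }
  if (total <= 0) NA else total
}
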