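#' Classify a persistence episode from a supply schedule
#'
#' Applies the refill-gap (grace period) rule to a patient's index-class
#' supply schedule. Walking the coverage intervals in order, each successive
#' index-class fill starting no later than `current supply end + grace_days`
#' extends the episode; the first fill beyond that bound ends it (a later
#' index-class fill cannot rescue an expired episode). Let `E` be the
#' episode's final supply end, rounded up to a whole day. Then:
#'
#' * `E + grace_days` reaching the follow-up horizon means the patient is
#'   **persistent**, with `event_time_days = followup_days`;
#' * otherwise, a fill of a *different* antihypertensive class dated in the
#'   half-open window `(E, E + grace_days]` makes the patient a **switcher**,
#'   with the event at the end of supply and the switch date/class recorded;
#' * otherwise the patient **discontinued** at the end of supply.
#'
#' Different-class fills dated during supply (on or before `E`) never produce
#' a switch — they are add-ons, reported via the `addon` flag.
#'
#' By default the event is dated at the end of supply (`event_at =
#' "supply_end"`), so uncovered grace days are not credited as exposure;
#' `"supply_end_plus_grace"` dates it at the end of the grace window instead.
#'
#' @param schedule a [build_supply_schedule()] result for the index class.
#' @param other_fills tibble of the patient's antihypertensive fills of other
#'   classes: columns `fill_date`, `atc_code` (may be empty / `NULL`).
#' @param grace_days maximum days without supply before discontinuation
#'   (default 30).
#' @param followup_days follow-up horizon in days since index (default 730).
#' @param event_at `"supply_end"` (default) or `"supply_end_plus_grace"`.
#' @return One-row tibble: `patient_id`, `status` (persistent / discontinued
#'   / switched), `event_time_days`, `censor_reason` (`"none"`; see
#'   [apply_censoring()]), `switch_date`, `switch_to_class`, `addon`,
#'   `supply_end_day`.
#' @export
determine_outcome <- function(schedule, other_fills = NULL,
                              grace_days = 30, followup_days = 730,
                              event_at = c("supply_end", "supply_end_plus_grace")) {
  event_at <- match.arg(event_at)
  if (grace_days < 0) abort("grace_days must be >= 0")
  if (followup_days <= 0) abort("followup_days must be > 0")
  iv <- schedule$intervals
  index_day <- schedule$index_day

  # chain intervals under the grace rule; E = running supply end (whole days)
  E <- rat_ceil(rat(iv$end_num[1], iv$end_den[1]))
  i <- 2L
  while (i <= nrow(iv)) {
    start_i <- iv$start_num[i] / iv$start_den[i]
    if (start_i > E + grace_days) break
    end_i <- rat_ceil(rat(iv$end_num[i], iv$end_den[i]))
    if (end_i > E) E <- end_i
    i <- i + 1L
  }

  horizon <- index_day + followup_days
  status <- NULL
  switch_date <- as.Date(NA)
  switch_class <- NA_character_

  if (E + grace_days >= horizon) {
    status <- "persistent"
    event_day <- horizon
  } else {
    event_day <- if (event_at == "supply_end") E else E + grace_days
    status <- "discontinued"
    if (!is.null(other_fills) && nrow(other_fills) > 0) {
      od <- as.numeric(other_fills$fill_date)
      in_grace <- od > E & od <= E + grace_days
      if (any(in_grace)) {
        first <- which(in_grace)[which.min(od[in_grace])]
        status <- "switched"
        switch_date <- as.Date(other_fills$fill_date[first])
        switch_class <- as.character(classify_atc(other_fills$atc_code[first]))
      }
    }
  }

  addon <- FALSE
  if (!is.null(other_fills) && nrow(other_fills) > 0) {
    od <- as.numeric(other_fills$fill_date)
    addon <- any(od >= index_day & od <= E)
  }

  tibble(
    patient_id = schedule$patient_id,
    status = status,
    event_time_days = min(event_day - index_day, followup_days),
    censor_reason = "none",
    switch_date = switch_date,
    switch_to_class = switch_class,
    addon = addon,
    supply_end_day = E - index_day
  )
}

#' Censor an episode outcome
#'
#' Candidate censoring times are: the death date; the admission date of the
#' first hospitalization lasting more than 21 days (exposure observation
#' stops at admission); the first unit-bag (multi-dose) dispensing date,
#' floored at day 1 so survival times stay positive; and the end of follow-up
#' (the earlier of the patient's `followup_end` and the analysis horizon).
#' If the earliest candidate precedes the event time, the episode becomes
#' censored at that time with the corresponding reason; ties are broken by
#' the precedence death > hospitalization > unit bags > end of follow-up. A
#' persistent episode has no event, so it is always censored — at the
#' follow-up horizon when nothing cuts in earlier.
#'
#' @param outcome one-row tibble from [determine_outcome()].
#' @param index_date the patient's index (first fill) date.
#' @param death_date optional death date.
#' @param hospitalizations optional tibble with `admit_date`, `discharge_date`.
#' @param unit_bag_date optional date of first unit-bag dispensing.
#' @param followup_end end of the patient's follow-up (Date); defaults to the
#'   analysis horizon.
#' @param followup_days analysis horizon in days since index (default 730).
#' @return The outcome row, censored where applicable: `status`,
#'   `event_time_days` and `censor_reason` updated.
#' @export
apply_censoring <- function(outcome, index_date,
                            death_date = NULL, hospitalizations = NULL,
                            unit_bag_date = NULL, followup_end = NULL,
                            followup_days = 730) {
  index_day <- as.numeric(as.Date(index_date))
  cand_time <- c(death = Inf, hospitalization_gt21d = Inf,
                 unit_bags = Inf, end_of_followup = Inf)

  if (!is.null(death_date) && !is.na(death_date)) {
    cand_time["death"] <- as.numeric(as.Date(death_date)) - index_day
  }
  if (!is.null(hospitalizations) && nrow(hospitalizations) > 0) {
    adm <- as.numeric(as.Date(hospitalizations$admit_date))
    dis <- as.numeric(as.Date(hospitalizations$discharge_date))
    if (any(dis < adm)) abort("hospitalization discharge before admission")
    long <- (dis - adm) > 21
    if (any(long)) {
      cand_time["hospitalization_gt21d"] <- min(adm[long]) - index_day
    }
  }
  if (!is.null(unit_bag_date) && !is.na(unit_bag_date)) {
    cand_time["unit_bags"] <- max(as.numeric(as.Date(unit_bag_date)) - index_day, 1)
  }
  eof <- followup_days
  if (!is.null(followup_end) && !is.na(followup_end)) {
    eof <- min(as.numeric(as.Date(followup_end)) - index_day, followup_days)
  }
  cand_time["end_of_followup"] <- eof

  best <- which.min(cand_time)  # which.min honours the precedence order on ties
  t_cens <- cand_time[best]

  is_event <- outcome$status %in% c("discontinued", "switched")
  if ((is_event && t_cens < outcome$event_time_days) ||
      (!is_event && t_cens <= outcome$event_time_days)) {
    outcome$status <- "censored"
    outcome$event_time_days <- unname(t_cens)
    outcome$censor_reason <- names(cand_time)[best]
    outcome$switch_date <- as.Date(NA)
    outcome$switch_to_class <- NA_character_
  }
  outcome
}

#' Build censored persistence episodes for a whole cohort
#'
#' Per-patient orchestration of [build_supply_schedule()],
#' [determine_outcome()] and [apply_censoring()]: for each eligible patient,
#' the index-class fills form the supply schedule, the remaining
#' antihypertensive fills drive switch/add-on classification, and the
#' censoring processes (death, >21-day hospitalization, unit-bag dispensing,
#' end of follow-up) are applied.
#'
#' @param eligible eligible cohort from [apply_eligibility()] (needs
#'   `patient_id`, `index_date`, `index_class`, and optionally `death_date`,
#'   `followup_end`).
#' @param dispensings full dispensing table (all classes; needs `patient_id`,
#'   `fill_date`, `atc_code`, `tablets`, `dosage_text`, `unit_bag`).
#' @param hospitalizations tibble `patient_id`, `admit_date`,
#'   `discharge_date`, or `NULL`.
#' @param grace_days,followup_days,event_at passed to [determine_outcome()].
#' @return A list: `outcomes` (one row per patient) and `qc` (counts of
#'   defaulted dosage parses, same-day anomalies, add-on flags).
#' @export
build_episodes <- function(eligible, dispensings, hospitalizations = NULL,
                           grace_days = 30, followup_days = 730,
                           event_at = "supply_end") {
  cls <- classify_atc(dispensings$atc_code)
  parses <- parse_dosage_batch(dispensings$dosage_text, quiet = TRUE)
  disp <- dispensings
  disp$.class <- as.character(cls)
  disp$.row <- seq_len(nrow(disp))

  disp_split <- split(disp, disp$patient_id)
  hosp_split <- if (!is.null(hospitalizations) && nrow(hospitalizations) > 0) {
    split(hospitalizations, hospitalizations$patient_id)
  } else list()

  out <- vector("list", nrow(eligible))
  n_defaulted <- 0L
  n_anomaly <- 0L
  for (i in seq_len(nrow(eligible))) {
    pid <- eligible$patient_id[i]
    pd <- disp_split[[as.character(pid)]]
    idx_class <- as.character(eligible$index_class[i])
    idx_fills <- pd[pd$.class == idx_class, , drop = FALSE]
    other <- pd[pd$.class != idx_class & pd$.class != "OTHER", , drop = FALSE]

    sch <- build_supply_schedule(idx_fills, parses[idx_fills$.row, , drop = FALSE])
    n_defaulted <- n_defaulted + sch$n_defaulted_parses
    n_anomaly <- n_anomaly + sch$same_day_anomaly

    oc <- determine_outcome(sch, other, grace_days = grace_days,
                            followup_days = followup_days, event_at = event_at)

    ub <- pd$fill_date[!is.na(pd$unit_bag) & pd$unit_bag == 1]
    oc <- apply_censoring(
      oc,
      index_date = eligible$index_date[i],
      death_date = if ("death_date" %in% names(eligible)) eligible$death_date[i] else NULL,
      hospitalizations = hosp_split[[as.character(pid)]],
      unit_bag_date = if (length(ub) > 0) min(ub) else NULL,
      followup_end = if ("followup_end" %in% names(eligible)) eligible$followup_end[i] else NULL,
      followup_days = followup_days
    )
    out[[i]] <- oc
  }
  outcomes <- dplyr::bind_rows(out)
  list(
    outcomes = outcomes,
    qc = tibble(
      n_patients = nrow(eligible),
      n_defaulted_parses = n_defaulted,
      n_same_day_anomalies = n_anomaly,
      n_addon_flags = sum(outcomes$addon),
      censor_death = sum(outcomes$censor_reason == "death"),
      censor_hospitalization = sum(outcomes$censor_reason == "hospitalization_gt21d"),
      censor_unit_bags = sum(outcomes$censor_reason == "unit_bags"),
      censor_end_of_followup = sum(outcomes$censor_reason == "end_of_followup")
    )
  )
}
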