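#' Assemble the covariate table the Cox models expect
#'
#' Joins demographics with derived covariates: comorbidity flags from the
#' diagnoses on or before the index date ([map_comorbidity()] prefixes), the
#' index blood pressure (the last measurement strictly before the first
#' fill), the count of other drugs (distinct non-antihypertensive ATC codes
#' filled in the 365 days before the index date), and the age group with
#' 65-79 years as the reference level.
#'
#' @param eligible eligible cohort from [apply_eligibility()].
#' @param diagnoses tibble `patient_id`, `icd10_code`, `dx_date`.
#' @param dispensings full dispensing table.
#' @param bp_measurements tibble `patient_id`, `measure_date`, `sbp`, `dbp`.
#' @param other_drug_window_days look-back window for the other-drug count
#'   (default 365).
#' @param age_breaks age-group cut points (default 30/50/65/80).
#' @return A tibble, one row per eligible patient, with the covariates coded
#'   as the adjusted model expects (`index_sbp`/`index_dbp` are `NA` when no
#'   blood pressure was recorded before the first fill).
#' @export
build_cohort_table <- function(eligible, diagnoses, dispensings, bp_measurements,
                               other_drug_window_days = 365,
                               age_breaks = c(30, 50, 65, 80, Inf)) {
  cohort <- eligible
  idx <- cohort[c("patient_id", "index_date")]

  cm <- comorbidity_table(diagnoses, idx)
  cohort <- dplyr::left_join(cohort, cm, by = "patient_id")

  # last BP strictly before the first fill
  bp <- dplyr::inner_join(bp_measurements, idx, by = "patient_id")
  bp <- bp[as.Date(bp$measure_date) < as.Date(bp$index_date), , drop = FALSE]
  bp_last <- bp |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$measure_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", index_sbp = "sbp", index_dbp = "dbp")
  cohort <- dplyr::left_join(cohort, bp_last, by = "patient_id")

  # distinct non-antihypertensive substances in the year before index
  other <- dplyr::inner_join(dispensings, idx, by = "patient_id")
  other <- other[!is_antihypertensive(other$atc_code), , drop = FALSE]
  od <- as.Date(other$fill_date)
  oi <- as.Date(other$index_date)
  other <- other[od < oi & od >= oi - other_drug_window_days, , drop = FALSE]
  other_n <- other |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_other_drugs = dplyr::n_distinct(.data$atc_code), .groups = "drop")
  cohort <- dplyr::left_join(cohort, other_n, by = "patient_id")
  cohort$n_other_drugs[is.na(cohort$n_other_drugs)] <- 0L

  labs <- paste(head(age_breaks, -1),
                c(head(age_breaks, -1)[-1] - 1, ""), sep = "-")
  labs[length(labs)] <- paste0(age_breaks[length(age_breaks) - 1], "+")
  cohort$age_group <- cut(cohort$age_at_index, breaks = age_breaks,
                          right = FALSE, labels = labs)
  ref <- "65-79"
  if (ref %in% levels(cohort$age_group)) {
    cohort$age_group <- stats::relevel(cohort$age_group, ref = ref)
  }
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  cohort$education <- factor(cohort$education,
                             levels = c("primary", "lower_secondary", "upper_secondary"))
  cohort$income_group <- factor(cohort$income_group,
                                levels = c("below_median", "at_or_above_median"))
  cohort$country_of_birth <- factor(cohort$country_of_birth,
                                    levels = c("sweden", "other_nordic",
                                               "europe_non_nordic", "other"))
  cohort$drug_class <- stats::relevel(factor(as.character(cohort$index_class),
                                             levels = atc_class_levels[atc_class_levels != "OTHER"]),
                                      ref = "DIURETIC")
  as_tibble(cohort)
}

# covariate terms entering the crude / adjusted hazard-ratio table
.hr_terms <- function(cohort) {
  terms <- list(
    age_group = ~age_group,
    sex = ~sex,
    sbp = ~I(index_sbp / 10),
    dbp = ~I(index_dbp / 10),
    diabetes = ~diabetes,
    no_cv_comorbidity = ~no_cv_comorbidity,
    n_other_drugs = ~n_other_drugs,
    education = ~education,
    income = ~income_group,
    country_of_birth = ~country_of_birth,
    drug_class = ~drug_class
  )
  # drop degenerate terms (a single observed level carries no contrast)
  keep <- vapply(names(terms), function(nm) {
    v <- switch(nm,
                sbp = cohort$index_sbp, dbp = cohort$index_dbp,
                income = cohort$income_group, cohort[[nm]])
    if (is.factor(v)) length(unique(v[!is.na(v)])) > 1 else length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  terms[keep]
}

.design_for <- function(formulas, data) {
  f <- stats::as.formula(paste("~", paste(vapply(formulas, function(x)
    as.character(x)[2], character(1)), collapse = " + ")))
  mm <- stats::model.matrix(f, data = droplevels(as.data.frame(data)))
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Crude and adjusted hazard-ratio table for discontinuation
#'
#' Crude hazard ratios come from one single-covariate Cox fit per term;
#' adjusted hazard ratios from one joint fit of all terms. Continuous blood
#' pressures enter per 10 mm Hg; categorical covariates are coded as dummies
#' against their reference level (females, age 65-79, primary education,
#' below-median income, born in Sweden, diuretics). Rows with missing
#' covariates are dropped (complete-case), with the count reported.
#'
#' @param samples tibble with `time`, `event` and the cohort covariates.
#' @param ties_method passed to [cox_fit()].
#' @return A list: `table` (term, level, crude/adjusted HR + CI + p),
#'   `adjusted_fit` (the joint `cox_fit`), `n_used`, `n_dropped`.
#' @export
hazard_ratio_table <- function(samples, ties_method = "efron") {
  terms <- .hr_terms(samples)
  if (length(terms) == 0) abort("no usable covariates for the hazard-ratio table")

  need <- unique(unlist(lapply(terms, all.vars)))
  cc <- stats::complete.cases(samples[need])
  data <- samples[cc, , drop = FALSE]
  rows <- list()
  for (nm in names(terms)) {
    mm <- .design_for(terms[nm], data)
    fit <- cox_fit(data$time, data$event, mm, ties = ties_method)
    rows[[nm]] <- summary(fit) |>
      dplyr::mutate(term = nm, level = colnames(mm)) |>
      dplyr::select("term", "level", crude_hr = "hr",
                    crude_ci_lower = "ci_lower", crude_ci_upper = "ci_upper",
                    crude_p = "p_value")
  }
  crude <- dplyr::bind_rows(rows)

  mm_all <- .design_for(terms, data)
  adj_fit <- cox_fit(data$time, data$event, mm_all, ties = ties_method)
  adj <- summary(adj_fit) |>
    dplyr::select(level = "term", adj_hr = "hr",
                  adj_ci_lower = "ci_lower", adj_ci_upper = "ci_upper",
                  adj_p = "p_value")

  list(
    table = dplyr::left_join(crude, adj, by = "level"),
    adjusted_fit = adj_fit,
    n_used = nrow(data),
    n_dropped = sum(!cc)
  )
}

#' Persistence, switching and hazard-ratio report
#'
#' Aggregates censored episode outcomes into the study's headline tables:
#' Kaplan-Meier persistence at 365 and 730 days overall, by sex and by
#' initiated drug class; the proportion of switchers by class; the crude and
#' adjusted hazard-ratio table; and the blood-pressure-before-switch audit
#' (how many switchers had a blood pressure recorded within 26 weeks before
#' the switch, and how many of those were still at or above 140/90 mm Hg).
#'
#' Switchers count as discontinuation events of the index class by default
#' (`switch_handling = "event"`: they are, by definition, no longer on the
#' initial class); `"censor"` treats them as censored instead.
#'
#' @param outcomes censored outcomes from [build_episodes()].
#' @param cohort covariate table from [build_cohort_table()].
#' @param bp_measurements optional BP table for the pre-switch audit.
#' @param switch_handling `"event"` (default) or `"censor"`.
#' @param ties_method passed to [cox_fit()].
#' @param readout_days persistence readout times (default 365 and 730 days).
#' @return Object of class `persistence_report`: list with `persistence`,
#'   `switching`, `hazard_ratios`, `bp_audit`, `km_curves`, `n_dropped_nonpositive`.
#' @export
persistence_report <- function(outcomes, cohort, bp_measurements = NULL,
                               switch_handling = c("event", "censor"),
                               ties_method = "efron",
                               readout_days = c(365, 730)) {
  switch_handling <- match.arg(switch_handling)
  samples <- dplyr::inner_join(outcomes, cohort, by = "patient_id")
  samples$time <- samples$event_time_days
  samples$event <- samples$status == "discontinued" |
    (samples$status == "switched" & switch_handling == "event")

  n_bad <- sum(samples$time <= 0)
  if (n_bad > 0) {
    warn(sprintf("%d episode(s) with non-positive time dropped from survival analyses", n_bad))
    samples <- samples[samples$time > 0, , drop = FALSE]
  }

  strata <- list(
    overall = list(type = "overall", split = list(all = samples)),
    sex = list(type = "sex", split = split(samples, samples$sex, drop = TRUE)),
    drug_class = list(type = "drug_class",
                      split = split(samples, samples$drug_class, drop = TRUE))
  )
  pers_rows <- list()
  km_rows <- list()
  for (s in strata) {
    for (nm in names(s$split)) {
      d <- s$split[[nm]]
      if (nrow(d) == 0) {
        warn(sprintf("stratum %s/%s has no patients; row omitted", s$type, nm))
        next
      }
      km <- km_estimate(d$time, d$event)
      pers_rows[[paste(s$type, nm)]] <- tibble(
        stratum_type = s$type, stratum = nm, n = nrow(d),
        n_events = sum(d$event),
        persistence_365 = km_survival_at(km, readout_days[1]),
        persistence_730 = km_survival_at(km, readout_days[2])
      )
      km_rows[[paste(s$type, nm)]] <- km_tidy(km, label = paste(s$type, nm, sep = ":"))
    }
  }
  persistence <- dplyr::bind_rows(pers_rows)
  km_curves <- dplyr::bind_rows(km_rows)

  switching <- samples |>
    dplyr::group_by(drug_class = .data$drug_class) |>
    dplyr::summarise(
      n_initiated = dplyr::n(),
      n_switched = sum(.data$status == "switched"),
      pct_switched = 100 * .data$n_switched / .data$n_initiated,
      .groups = "drop"
    )

  hr <- hazard_ratio_table(samples, ties_method = ties_method)

  bp_audit <- NULL
  switchers <- samples[samples$status == "switched", , drop = FALSE]
  if (!is.null(bp_measurements) && nrow(switchers) > 0) {
    bp_split <- split(bp_measurements, bp_measurements$patient_id)
    res <- lapply(seq_len(nrow(switchers)), function(i) {
      bp_before_switch(switchers$switch_date[i],
                       bp_split[[as.character(switchers$patient_id[i])]])
    })
    recorded <- vapply(res, `[[`, logical(1), "recorded")
    unctrl <- vapply(res, function(r) isTRUE(r$uncontrolled), logical(1))
    bp_audit <- tibble(
      n_switchers = nrow(switchers),
      n_bp_recorded = sum(recorded),
      pct_recorded = 100 * mean(recorded),
      n_uncontrolled = sum(unctrl),
      pct_uncontrolled = if (sum(recorded) > 0) 100 * sum(unctrl) / sum(recorded) else NA_real_
    )
  }

  structure(
    list(
      persistence = persistence,
      switching = switching,
      hazard_ratios = hr$table,
      adjusted_fit = hr$adjusted_fit,
      hr_n_used = hr$n_used,
      hr_n_dropped = hr$n_dropped,
      bp_audit = bp_audit,
      km_curves = km_curves,
      n_dropped_nonpositive = n_bad,
      switch_handling = switch_handling
    ),
    class = "persistence_report"
  )
}

#' @export
print.persistence_report <- function(x, ...) {
  cat("<persistence_report>\n\nPersistence (Kaplan-Meier):\n")
  print(x$persistence)
  cat("\nSwitching by initiated class:\n")
  print(x$switching)
  if (!is.null(x$bp_audit)) {
    cat("\nBP recorded within 26 weeks before switch:\n")
    print(x$bp_audit)
  }
  cat("\nHazard ratios (crude and adjusted):\n")
  print(x$hazard_ratios, n = 30)
  invisible(x)
}
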