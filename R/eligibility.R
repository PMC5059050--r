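#' Apply cohort eligibility rules
#'
#' Retains patients who (i) are at least 30 years old on the index date (the
#' first antihypertensive fill), (ii) carry a hypertension diagnosis (ICD-10
#' I10) recorded strictly before that first fill, (iii) have at least one
#' filled antihypertensive prescription, (iv) have their index fill inside the
#' enrollment window, and (v) initiate exactly one antihypertensive product on
#' the index date — a single fixed-combination product counts as one product;
#' two or more distinct antihypertensive products on the index day is a
#' multi-product initiation and is excluded.
#'
#' Every excluded patient is logged with exactly one reason, assigned in the
#' precedence order `age` > `missing_dx`/`dx_after_index` > `no_fill` >
#' `index_outside_window` > `multi_product_initiation`, so the exclusion
#' tallies always reconcile: `nrow(patients) == nrow(eligible) +
#' nrow(exclusions)`.
#'
#' @param patients tibble with at least `patient_id`, `birth_date`.
#' @param dispensings tibble with `patient_id`, `fill_date`, `atc_code`.
#' @param diagnoses tibble with `patient_id`, `icd10_code`, `dx_date`
#'   (hypertension rows are those with codes starting `I10`).
#' @param enrollment_start,enrollment_end the enrollment window (Dates); index
#'   fills outside it are excluded.
#' @param map ATC class map, see [atc_class_map()].
#' @return A list with `eligible` (patients joined with `index_date`,
#'   `index_class`, `age_at_index`) and `exclusions` (tibble `patient_id`,
#'   `reason`).
#' @export
apply_eligibility <- function(patients, dispensings, diagnoses,
                              enrollment_start, enrollment_end,
                              map = atc_class_map()) {
  if (is.null(diagnoses)) abort("a diagnoses table is required for eligibility")
  enrollment_start <- as.Date(enrollment_start)
  enrollment_end <- as.Date(enrollment_end)

  aht <- dispensings[is_antihypertensive(dispensings$atc_code, map), , drop = FALSE]
  idx <- aht |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(index_date = min(.data$fill_date), .groups = "drop")

  # distinct antihypertensive products (ATC codes) filled on the index day
  n_idx_products <- aht |>
    dplyr::inner_join(idx, by = "patient_id") |>
    dplyr::filter(.data$fill_date == .data$index_date) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_products = dplyr::n_distinct(.data$atc_code),
      index_class = as.character(classify_atc(.data$atc_code[1], map)),
      .groups = "drop"
    )

  ht_dx <- diagnoses[startsWith(diagnoses$icd10_code, "I10"), , drop = FALSE] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_ht_dx = min(.data$dx_date), .groups = "drop")

  tab <- patients |>
    dplyr::left_join(idx, by = "patient_id") |>
    dplyr::left_join(n_idx_products, by = "patient_id") |>
    dplyr::left_join(ht_dx, by = "patient_id")
  tab$age_at_index <- floor(
    as.numeric(tab$index_date - as.Date(tab$birth_date)) / 365.25
  )

  reason <- rep(NA_character_, nrow(tab))
  has_fill <- !is.na(tab$index_date)
  # precedence: age -> missing dx / dx after index -> no fill -> window -> multi-product
  too_young <- has_fill & tab$age_at_index < 30
  reason[is.na(reason) & too_young] <- "age"
  reason[is.na(reason) & is.na(tab$first_ht_dx)] <- "missing_dx"
  dx_late <- has_fill & !is.na(tab$first_ht_dx) & tab$first_ht_dx >= tab$index_date
  reason[is.na(reason) & dx_late] <- "dx_after_index"
  reason[is.na(reason) & !has_fill] <- "no_fill"
  outside <- has_fill &
    (tab$index_date < enrollment_start | tab$index_date > enrollment_end)
  reason[is.na(reason) & outside] <- "index_outside_window"
  multi <- has_fill & !is.na(tab$n_products) & tab$n_products > 1
  reason[is.na(reason) & multi] <- "multi_product_initiation"

  eligible <- tab[is.na(reason), , drop = FALSE]
  eligible$n_products <- NULL
  eligible$index_class <- factor(eligible$index_class, levels = atc_class_levels)
  exclusions <- tibble(
    patient_id = tab$patient_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  list(eligible = as_tibble(eligible), exclusions = exclusions)
}
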