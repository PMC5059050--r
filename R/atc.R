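#' Antihypertensive drug classes
#'
#' Factor levels used throughout the package. `DIURETIC` is the reference
#' class in hazard-ratio tables; `OTHER` marks non-antihypertensive ATC codes.
#'
#' @export
atc_class_levels <- c(
  "ACE_INHIBITOR", "ARB", "BETA_BLOCKER", "CCB",
  "DIURETIC", "FIXED_COMBINATION", "OTHER"
)

#' ATC prefix to drug-class mapping
#'
#' The antihypertensive class map: ACE inhibitors (C09A), angiotensin receptor
#' blockers (C09C), beta blockers (C07), calcium channel blockers (C08),
#' diuretics (C03A/C03B/C03D/C03E — thiazides, low-ceiling and potassium-
#' sparing agents including mineralocorticoid receptor antagonists and
#' amiloride), and fixed-dose combinations (C07FB02, C09BA, C09D). Matching is
#' longest-prefix, so the fixed-combination prefixes take precedence over any
#' overlapping single-class prefix. Shipped as an editable table
#' (`inst/extdata/atc_classes.csv`) so deployments can extend it.
#'
#' @return A tibble with columns `prefix` and `class`.
#' @export
atc_class_map <- function() {
  path <- system.file("extdata", "atc_classes.csv", package = "rxpersist")
  readr::read_csv(path, col_types = readr::cols(
    prefix = readr::col_character(),
    class = readr::col_character()
  ))
}

#' Classify ATC codes into antihypertensive drug classes
#'
#' Longest-prefix match of each code against [atc_class_map()]; codes that
#' match no antihypertensive prefix are `OTHER`.
#'
#' @param atc_code character vector of ATC codes (4-7 characters typical).
#' @param map mapping table, by default [atc_class_map()].
#' @return Factor with levels [atc_class_levels], same length as `atc_code`.
#' @export
#' @examples
#' classify_atc(c("C03AA03", "C09BA02", "C07AB02", "N02BE01"))
classify_atc <- function(atc_code, map = atc_class_map()) {
  atc_code <- as.character(atc_code)
  if (length(atc_code) == 0 || anyNA(atc_code) || any(!nzchar(atc_code))) {
    abort("atc_code must be non-empty strings")
  }
  prefixes <- map$prefix
  ord <- order(nchar(prefixes), decreasing = TRUE)  # longest prefix wins
  prefixes <- prefixes[ord]
  classes <- map$class[ord]
  out <- rep("OTHER", length(atc_code))
  undecided <- rep(TRUE, length(atc_code))
  for (i in seq_along(prefixes)) {
    hit <- undecided & startsWith(atc_code, prefixes[i])
    out[hit] <- classes[i]
    undecided[hit] <- FALSE
  }
  factor(out, levels = atc_class_levels)
}

#' @rdname classify_atc
#' @export
is_antihypertensive <- function(atc_code, map = atc_class_map()) {
  classify_atc(atc_code, map) != "OTHER"
}

# ICD-10 prefixes per cardiovascular-comorbidity flag; diabetes included in
# the "no cardiovascular comorbidity" negation on purpose (the adjusted model
# carries diabetes separately AND inside the no-comorbidity indicator).
.comorbidity_prefixes <- list(
  atrial_fibrillation = c("I48"),
  heart_failure = c("I50"),
  ischemic_heart_disease = paste0("I2", 0:5),
  stroke_tia = c(paste0("I6", 0:9), "G45"),
  diabetes = c("E10", "E11")
)

#' Map ICD-10 codes to comorbidity flags
#'
#' Prefix matching of ICD-10 codes against the study comorbidities: atrial
#' fibrillation/flutter (I48), heart failure (I50), ischemic heart disease
#' (I20-I25), previous stroke/TIA (I60-I69, G45) and diabetes mellitus
#' (E10-E11). Unknown codes are ignored. Also derives `no_cv_comorbidity`,
#' the negation of the union of all five flags, as the adjusted model expects.
#'
#' @param icd10_codes character vector of ICD-10 codes (possibly empty).
#' @return Named logical vector: the five flags plus `no_cv_comorbidity`.
#' @export
#' @examples
#' map_comorbidity(c("I21", "E11"))
map_comorbidity <- function(icd10_codes) {
  codes <- as.character(icd10_codes)
  codes <- codes[!is.na(codes)]
  flags <- vapply(.comorbidity_prefixes, function(pref) {
    any(vapply(pref, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  c(flags, no_cv_comorbidity = !any(flags))
}

# per-patient comorbidity flags from a diagnoses table, restricted to codes
# recorded on or before each patient's index date
comorbidity_table <- function(diagnoses, index_dates) {
  stopifnot(all(c("patient_id", "icd10_code", "dx_date") %in% names(diagnoses)))
  flag_names <- names(.comorbidity_prefixes)
  dx <- dplyr::inner_join(diagnoses, index_dates, by = "patient_id")
  dx <- dx[dx$dx_date <= dx$index_date, , drop = FALSE]
  for (nm in flag_names) {
    pref <- .comorbidity_prefixes[[nm]]
    dx[[nm]] <- Reduce(`|`, lapply(pref, function(p) startsWith(dx$icd10_code, p)))
  }
  agg <- dx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(flag_names), any), .groups = "drop")
  out <- dplyr::left_join(index_dates["patient_id"], agg, by = "patient_id")
  for (nm in flag_names) out[[nm]][is.na(out[[nm]])] <- FALSE
  out$no_cv_comorbidity <- !Reduce(`|`, out[flag_names])
  as_tibble(out)
}
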