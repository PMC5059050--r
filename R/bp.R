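#' Blood pressure recorded before a switch
#'
#' Looks for the latest blood-pressure measurement in the half-open window
#' `[switch_date - window_days, switch_date)` — 26 weeks (182 days) by
#' default, excluding the switch day itself — and, when one exists, judges
#' control against the 140/90 mm Hg threshold: `uncontrolled` is true when
#' systolic >= 140 **or** diastolic >= 90.
#'
#' @param switch_date the switch date (Date).
#' @param bp_history tibble with `measure_date`, `sbp`, `dbp` for one patient.
#' @param window_days look-back window (default 182 = 26 weeks).
#' @return A list: `recorded` (logical), `last_bp` (one-row tibble or `NULL`),
#'   `uncontrolled` (logical or `NA` when nothing was recorded).
#' @export
#' @examples
#' bp <- tibble::tibble(
#'   measure_date = as.Date("2006-05-01"), sbp = 142, dbp = 85
#' )
#' bp_before_switch(as.Date("2006-07-01"), bp)$uncontrolled  # TRUE
bp_before_switch <- function(switch_date, bp_history, window_days = 182) {
  if (window_days <= 0) abort("window_days must be > 0")
  switch_date <- as.Date(switch_date)
  if (is.null(bp_history) || nrow(bp_history) == 0) {
    return(list(recorded = FALSE, last_bp = NULL, uncontrolled = NA))
  }
  d <- as.Date(bp_history$measure_date)
  in_window <- d >= switch_date - window_days & d < switch_date
  if (!any(in_window)) {
    return(list(recorded = FALSE, last_bp = NULL, uncontrolled = NA))
  }
  last <- which(in_window)[which.max(d[in_window])]
  row <- bp_history[last, , drop = FALSE]
  list(
    recorded = TRUE,
    last_bp = as_tibble(row),
    uncontrolled = row$sbp >= 140 || row$dbp >= 90
  )
}
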