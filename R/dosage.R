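#' Dosage-instruction grammar rules
#'
#' The frequency vocabulary recognised by [parse_dosage()]. Each row maps a
#' frequency phrase to a multiplier applied to the clause quantity, expressed
#' as an exact fraction (`mult_num / mult_den`): "twice daily" doubles the
#' per-intake quantity, "every other day" halves it, and time-of-day phrases
#' ("in the morning", "at night") describe a single daily intake. Clauses
#' joined by "and" are summed, so "1 tablet in the morning and 0.5 tablet in
#' the evening" yields 1.5 tablets/day.
#'
#' The table is data-driven so a deployment facing a different prescription
#' dialect can extend it: `extra` may be a data frame, or the path of a CSV
#' file, with columns `pattern`, `mult_num`, `mult_den`. Extension rows are
#' matched before the built-ins.
#'
#' @param extra optional extension rules: a data frame or CSV path with
#'   columns `pattern`, `mult_num`, `mult_den`.
#' @return A tibble with columns `pattern`, `mult_num`, `mult_den`.
#' @export
#' @examples
#' dosage_rules()
dosage_rules <- function(extra = NULL) {
  base <- tibble(
    pattern = c(
      "daily", "every day", "once daily", "once a day",
      "every other day",
      "twice daily", "twice a day", "two times daily",
      "three times daily", "three times a day", "3 times daily",
      "in the morning", "in the evening", "at night", "at bedtime"
    ),
    mult_num = c(1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 1, 1, 1, 1),
    mult_den = c(1, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  )
  if (is.null(extra)) return(base)
  if (is.character(extra)) {
    extra <- readr::read_csv(extra, col_types = readr::cols(
      pattern = readr::col_character(),
      mult_num = readr::col_double(),
      mult_den = readr::col_double()
    ))
  }
  extra <- as_tibble(extra)
  need <- c("pattern", "mult_num", "mult_den")
  if (!all(need %in% names(extra))) {
    abort("dosage rule extension must have columns pattern, mult_num, mult_den")
  }
  dplyr::bind_rows(extra[need], base)
}

# "1", "0.5", "1/2" -> reduced rational c(num, den); NULL when not a quantity
.parse_quantity <- function(s) {
  s <- trimws(s)
  if (grepl("^[0-9]+\\s*/\\s*[0-9]+$", s)) {
    parts <- as.numeric(strsplit(s, "/")[[1]])
    if (parts[2] == 0) return(NULL)
    return(rat(parts[1], parts[2]))
  }
  if (grepl("^[0-9]+$", s)) return(rat(as.numeric(s), 1))
  if (grepl("^[0-9]*\\.[0-9]+$", s)) {
    dec <- sub("^[0-9]*\\.", "", s)
    den <- 10^nchar(dec)
    return(rat(round(as.numeric(s) * den), den))
  }
  NULL
}

# one clause: "<quantity> tablet[s] [<frequency>]" -> rational dose or NULL
.parse_clause <- function(clause, rules) {
  clause <- tolower(trimws(gsub("\\s+", " ", clause)))
  m <- regmatches(
    clause,
    regexec("^([0-9]+\\s*/\\s*[0-9]+|[0-9]*\\.?[0-9]+)\\s*tablets?\\s*(.*)$", clause)
  )[[1]]
  if (length(m) == 0) return(NULL)
  qty <- .parse_quantity(m[2])
  if (is.null(qty) || qty[1] == 0) return(NULL)
  freq_text <- trimws(m[3])
  if (freq_text == "") return(qty)
  hit <- match(freq_text, rules$pattern)
  if (is.na(hit)) return(NULL)
  rat_mul(qty, rat(rules$mult_num[hit], rules$mult_den[hit]))
}

#' Parse a free-text dosage instruction into tablets per day
#'
#' Converts the dosage text on a prescription into a daily tablet consumption
#' rate. The recognised grammar is `<quantity> tablet[s] [<frequency>]`, where
#' the quantity is a decimal or a plain fraction ("1/2") and the frequency
#' vocabulary comes from [dosage_rules()]; clauses joined by "and" are summed.
#'
#' The function is total: a blank instruction defaults to 1 tablet/day with
#' `source = "defaulted_missing"`, and any non-empty text outside the grammar
#' (including pro-re-nata phrasing such as "as needed", which implies no fixed
#' rate) defaults to 1 tablet/day with `source = "defaulted_unparseable"` and
#' a warning. Defaulted parses are what downstream QC counts surface, so
#' nothing is silently dropped.
#'
#' @param text a dosage instruction (single string; `NA` treated as missing).
#' @param rules grammar table from [dosage_rules()].
#' @param quiet suppress the unparseable-text warning.
#' @return A list of class `dosage_parse` with elements `daily_dose` (numeric,
#'   always > 0), `dose_num`/`dose_den` (the exact fraction), `source` (one of
#'   `"parsed"`, `"defaulted_missing"`, `"defaulted_unparseable"`) and
#'   `raw_text`.
#' @export
#' @examples
#' parse_dosage("2 tablets twice daily")$daily_dose              # 4
#' parse_dosage("1 tablet in the morning and 0.5 tablet in the evening")$daily_dose
#' parse_dosage("")$source                                       # defaulted_missing
parse_dosage <- function(text, rules = dosage_rules(), quiet = FALSE) {
  raw <- if (is.null(text) || length(text) == 0) NA_character_ else as.character(text)[1]
  if (is.na(raw) || trimws(raw) == "") {
    return(.dosage_parse(rat(1, 1), "defaulted_missing", ifelse(is.na(raw), "", raw)))
  }
  clean <- tolower(raw)
  if (grepl("\\b(as needed|when needed|if needed|prn|pro re nata)\\b", clean) ||
      grepl("[0-9]\\s*(-|–)\\s*[0-9]", clean)) {
    # no fixed daily rate exists for as-needed or range ("1-2 tablets") texts
    if (!quiet) {
      warn(paste0("unparseable dosage text, defaulting to 1 tablet/day: ", sQuote(raw)),
           class = "rxpersist_dosage_default")
    }
    return(.dosage_parse(rat(1, 1), "defaulted_unparseable", raw))
  }
  clauses <- strsplit(clean, "\\band\\b")[[1]]
  clauses <- clauses[trimws(clauses) != ""]
  if (length(clauses) == 0) clauses <- clean
  total <- rat(0, 1)
  ok <- TRUE
  for (cl in clauses) {
    d <- .parse_clause(cl, rules)
    if (is.null(d)) {
      ok <- FALSE
      break
    }
    total <- rat_add(total, d)
  }
  if (!ok || total[1] == 0) {
    if (!quiet) {
      warn(paste0("unparseable dosage text, defaulting to 1 tablet/day: ", sQuote(raw)),
           class = "rxpersist_dosage_default")
    }
    return(.dosage_parse(rat(1, 1), "defaulted_unparseable", raw))
  }
  .dosage_parse(total, "parsed", raw)
}

.dosage_parse <- function(dose, source, raw) {
  structure(
    list(
      daily_dose = rat_num(dose),
      dose_num = dose[1],
      dose_den = dose[2],
      source = source,
      raw_text = raw
    ),
    class = "dosage_parse"
  )
}

#' @export
print.dosage_parse <- function(x, ...) {
  cat(sprintf("<dosage_parse> %.4g tablets/day [%s] %s\n",
              x$daily_dose, x$source,
              if (nzchar(x$raw_text)) sQuote(x$raw_text) else "<blank>"))
  invisible(x)
}

#' Parse a vector of dosage texts
#'
#' Vectorised form of [parse_dosage()] for the `dosage_text` column of a
#' dispensing table. Unparseable texts are collected into one summary warning
#' rather than one warning per row.
#'
#' @param texts character vector (NAs treated as missing).
#' @inheritParams parse_dosage
#' @return A tibble with one row per input: `raw_text`, `daily_dose`,
#'   `dose_num`, `dose_den`, `source`.
#' @export
parse_dosage_batch <- function(texts, rules = dosage_rules(), quiet = FALSE) {
  texts <- as.character(texts)
  res <- lapply(texts, parse_dosage, rules = rules, quiet = TRUE)
  out <- tibble(
    raw_text = vapply(res, function(x) x$raw_text, character(1)),
    daily_dose = vapply(res, function(x) x$daily_dose, numeric(1)),
    dose_num = vapply(res, function(x) x$dose_num, numeric(1)),
    dose_den = vapply(res, function(x) x$dose_den, numeric(1)),
    source = vapply(res, function(x) x$source, character(1))
  )
  n_bad <- sum(out$source == "defaulted_unparseable")
  if (n_bad > 0 && !quiet) {
    warn(sprintf("%d dosage text(s) could not be parsed; defaulted to 1 tablet/day", n_bad),
         class = "rxpersist_dosage_default")
  }
  out
}
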