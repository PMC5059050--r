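# column schemas for the four input CSVs (name = readr collector)
.schemas <- list(
  dispensings = list(patient_id = "c", fill_date = "D", atc_code = "c",
                     tablets = "d", strength_mg = "d", dosage_text = "c",
                     unit_bag = "d"),
  patients = list(patient_id = "c", sex = "c", birth_date = "D",
                  education = "c", income_group = "c", country_of_birth = "c",
                  death_date = "D", followup_end = "D"),
  hospitalizations = list(patient_id = "c", admit_date = "D",
                          discharge_date = "D"),
  diagnoses = list(patient_id = "c", icd10_code = "c", dx_date = "D"),
  bp_measurements = list(patient_id = "c", measure_date = "D",
                         sbp = "d", dbp = "d")
)

#' Read and validate a study input CSV
#'
#' Reads one of the five input tables (`dispensings`, `patients`,
#' `hospitalizations`, `diagnoses`, `bp_measurements`) with its documented
#' column schema. A missing column, or a value that fails to parse as its
#' declared type (for example a corrupt date), is an error naming the file,
#' row and column — malformed inputs never propagate silently.
#'
#' @param path CSV file path.
#' @param what which schema to apply (defaults to the file's base name).
#' @return A tibble.
#' @export
read_study_csv <- function(path, what = sub("[.]csv$", "", basename(path))) {
  if (!what %in% names(.schemas)) {
    abort(paste0("unknown input table: ", what))
  }
  schema <- .schemas[[what]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  out <- raw
  for (col in names(schema)) {
    type <- schema[[col]]
    v <- raw[[col]]
    if (type == "D") {
      parsed <- as.Date(v, format = "%Y-%m-%d")
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad) > 0) {
        abort(sprintf("%s: row %d, column '%s': cannot parse date %s",
                      path, bad[1], col, sQuote(v[bad[1]])))
      }
      out[[col]] <- parsed
    } else if (type == "d") {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad) > 0) {
        abort(sprintf("%s: row %d, column '%s': cannot parse number %s",
                      path, bad[1], col, sQuote(v[bad[1]])))
      }
      out[[col]] <- parsed
    } else {
      out[[col]] <- ifelse(is.na(v), NA_character_, v)
    }
  }
  out
}

#' Write a generated cohort to CSV files
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param ground_truth also write the `ground_truth.csv` sidecar (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, ground_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("patients", "diagnoses", "dispensings", "hospitalizations",
              "bp_measurements", if (ground_truth) "ground_truth")
  for (nm in tables) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")), progress = FALSE)
  }
  invisible(dir)
}

#' Read a study input directory
#'
#' @param dir directory containing the five input CSVs.
#' @return A named list of validated tibbles.
#' @export
read_cohort_csv <- function(dir) {
  out <- list()
  for (nm in names(.schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) abort(paste0("missing input file: ", path))
    out[[nm]] <- read_study_csv(path, nm)
  }
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) {
    out$ground_truth <- readr::read_csv(gt, show_col_types = FALSE, progress = FALSE)
  }
  out
}

.analysis_defaults <- function() {
  list(grace_days = 30, followup_days = 730,
       event_at = "supply_end", switch_handling = "event",
       ties_method = "efron",
       enrollment_start = as.Date("2006-01-01"),
       enrollment_end = as.Date("2007-12-31"))
}

#' Run the full persistence study
#'
#' Orchestrates the pipeline: (optionally) simulate a synthetic registry,
#' apply eligibility, build the covariate table, construct and censor supply
#' episodes, estimate persistence / switching / hazard-ratio tables, and
#' write every output together with a run manifest whose stage counts
#' reconcile (patients in = retained + excluded at each stage).
#'
#' Outputs written to `out_dir`: `persistence.csv`, `hazard_ratios.csv`,
#' `switching.csv`, `km_curves.csv`, `bp_audit.csv`, `exclusions.csv`,
#' `manifest.json` and `run.log`. Warnings (defaulted dosage texts, omitted
#' strata) are logged and never abort; validation errors always abort.
#'
#' @param out_dir output directory.
#' @param input_dir directory of input CSVs; `NULL` means simulate.
#' @param sim a [sim_config()] for simulation (ignored when `input_dir`
#'   given); defaults to `sim_config(seed = seed)`.
#' @param seed master seed used when simulating.
#' @param config named list of analysis settings overriding the defaults
#'   (`grace_days`, `followup_days`, `event_at`, `switch_handling`,
#'   `ties_method`, `enrollment_start`, `enrollment_end`); unknown keys are
#'   an error. May also be the path of a YAML file with an `analysis` block
#'   (and optionally a `sim` block of [sim_config()] overrides).
#' @param write_inputs when simulating, also write the generated input CSVs
#'   under `out_dir/inputs` (default TRUE).
#' @return Invisibly, a list with the `report`, `manifest`, `outcomes`,
#'   `cohort` and (when simulated) `ground_truth`.
#' @export
run_study <- function(out_dir, input_dir = NULL, sim = NULL, seed = 1,
                      config = list(), write_inputs = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    inform(line)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), line))
  }

  acfg <- .analysis_defaults()
  sim_overrides <- list()
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    unknown_blocks <- setdiff(names(y), c("analysis", "sim"))
    if (length(unknown_blocks) > 0) {
      abort(paste0("unknown config block(s): ", paste(unknown_blocks, collapse = ", ")))
    }
    sim_overrides <- y$sim %||% list()
    config <- y$analysis %||% list()
  }
  unknown <- setdiff(names(config), names(acfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown analysis config key(s): ", paste(unknown, collapse = ", ")))
  }
  acfg[names(config)] <- config

  checksums <- list()
  ground_truth <- NULL
  if (is.null(input_dir)) {
    if (is.null(sim)) {
      sim <- do.call(sim_config, c(list(seed = seed), sim_overrides))
    }
    say("simulating synthetic cohort: n = %d, seed = %d", sim$n_patients, sim$seed)
    cohort_in <- generate_cohort(sim)
    ground_truth <- cohort_in$ground_truth
    if (write_inputs) {
      input_dir_w <- file.path(out_dir, "inputs")
      write_cohort_csv(cohort_in, input_dir_w)
      files <- list.files(input_dir_w, full.names = TRUE)
      checksums <- as.list(tools::md5sum(files))
      names(checksums) <- basename(files)
    }
  } else {
    say("reading inputs from %s", input_dir)
    cohort_in <- read_cohort_csv(input_dir)
    ground_truth <- cohort_in$ground_truth
    files <- file.path(input_dir, paste0(names(.schemas), ".csv"))
    checksums <- as.list(tools::md5sum(files))
    names(checksums) <- basename(files)
  }

  n_in <- nrow(cohort_in$patients)
  say("eligibility: %d patients in", n_in)
  elig <- apply_eligibility(cohort_in$patients, cohort_in$dispensings,
                            cohort_in$diagnoses,
                            acfg$enrollment_start, acfg$enrollment_end)
  excl_tally <- table(elig$exclusions$reason)
  say("eligible: %d; excluded: %d (%s)", nrow(elig$eligible), nrow(elig$exclusions),
      paste(names(excl_tally), excl_tally, sep = "=", collapse = ", "))

  cohort <- build_cohort_table(elig$eligible, cohort_in$diagnoses,
                               cohort_in$dispensings, cohort_in$bp_measurements)

  say("building episodes (grace %d d, follow-up %d d)", acfg$grace_days, acfg$followup_days)
  ep <- build_episodes(elig$eligible, cohort_in$dispensings,
                       cohort_in$hospitalizations,
                       grace_days = acfg$grace_days,
                       followup_days = acfg$followup_days,
                       event_at = acfg$event_at)
  if (ep$qc$n_defaulted_parses > 0) {
    say("QC: %d dispensing(s) with defaulted dosage parse", ep$qc$n_defaulted_parses)
  }

  say("estimating persistence, switching and hazard ratios")
  report <- withCallingHandlers(
    persistence_report(ep$outcomes, cohort, cohort_in$bp_measurements,
                       switch_handling = acfg$switch_handling,
                       ties_method = acfg$ties_method),
    warning = function(w) {
      log_lines <<- c(log_lines, paste0("warning: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )

  readr::write_csv(report$persistence, file.path(out_dir, "persistence.csv"), progress = FALSE)
  readr::write_csv(report$hazard_ratios, file.path(out_dir, "hazard_ratios.csv"), progress = FALSE)
  readr::write_csv(report$switching, file.path(out_dir, "switching.csv"), progress = FALSE)
  readr::write_csv(report$km_curves, file.path(out_dir, "km_curves.csv"), progress = FALSE)
  if (!is.null(report$bp_audit)) {
    readr::write_csv(report$bp_audit, file.path(out_dir, "bp_audit.csv"), progress = FALSE)
  }
  readr::write_csv(elig$exclusions, file.path(out_dir, "exclusions.csv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rxpersist")),
    seed = seed,
    analysis_config = lapply(acfg, as.character),
    input_checksums = checksums,
    counts = list(
      patients_in = n_in,
      eligible = nrow(elig$eligible),
      excluded = nrow(elig$exclusions),
      exclusion_reasons = as.list(excl_tally),
      episodes = nrow(ep$outcomes),
      censor_reasons = as.list(table(ep$outcomes$censor_reason)),
      status = as.list(table(ep$outcomes$status)),
      qc = as.list(ep$qc)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  say("done: outputs in %s", out_dir)

  invisible(list(report = report, manifest = manifest, outcomes = ep$outcomes,
                 qc = ep$qc, cohort = cohort, eligible = elig$eligible,
                 exclusions = elig$exclusions, ground_truth = ground_truth,
                 sim = if (is.null(input_dir)) sim else NULL))
}
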