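# tiny hand-built cohort: one clean patient and one violator of each rule
make_mini_cohort <- function() {
  d0 <- as.Date("2006-06-01")
  patients <- tibble::tibble(
    patient_id = c("ok", "young", "late_dx", "no_dx", "no_fill", "multi"),
    birth_date = c(d0 - round(50.5 * 365.25), d0 - 29 * 365, d0 - 60 * 365,
                   d0 - 45 * 365, d0 - 70 * 365, d0 - 55 * 365)
  )
  dispensings <- tibble::tibble(
    patient_id = c("ok", "young", "late_dx", "no_dx", "multi", "multi"),
    fill_date = rep(d0, 6),
    atc_code = c("C09AA02", "C07AB02", "C03AA03", "C08CA01", "C09AA02", "C03AA03"),
    tablets = 100, dosage_text = "1 tablet daily", unit_bag = 0
  )
  diagnoses <- tibble::tibble(
    patient_id = c("ok", "young", "late_dx", "no_fill", "multi"),
    icd10_code = "I10",
    dx_date = c(d0 - 100, d0 - 100, d0 + 30, d0 - 100, d0 - 100)
  )
  list(patients = patients, dispensings = dispensings, diagnoses = diagnoses)
}

test_that("each eligibility rule excludes its violator with the right reason", {
  mc <- make_mini_cohort()
  res <- apply_eligibility(mc$patients, mc$dispensings, mc$diagnoses,
                           "2006-01-01", "2007-12-31")
  expect_equal(res$eligible$patient_id, "ok")
  expect_equal(res$eligible$index_date, as.Date("2006-06-01"))
  expect_equal(as.character(res$eligible$index_class), "ACE_INHIBITOR")
  expect_equal(res$eligible$age_at_index, 50)
  reasons <- setNames(res$exclusions$reason, res$exclusions$patient_id)
  expect_equal(reasons[["young"]], "age")
  expect_equal(reasons[["late_dx"]], "dx_after_index")
  expect_equal(reasons[["no_dx"]], "missing_dx")
  expect_equal(reasons[["no_fill"]], "no_fill")
  expect_equal(reasons[["multi"]], "multi_product_initiation")
})

test_that("exclusions reconcile: input = eligible + excluded, one reason each", {
  mc <- make_mini_cohort()
  res <- apply_eligibility(mc$patients, mc$dispensings, mc$diagnoses,
                           "2006-01-01", "2007-12-31")
  expect_equal(nrow(mc$patients), nrow(res$eligible) + nrow(res$exclusions))
  expect_equal(anyDuplicated(res$exclusions$patient_id), 0L)
})

test_that("a single fixed-combination product on the index day is eligible", {
  d0 <- as.Date("2006-06-01")
  res <- apply_eligibility(
    tibble::tibble(patient_id = "fc", birth_date = d0 - 40 * 365),
    tibble::tibble(patient_id = "fc", fill_date = d0, atc_code = "C09BA02",
                   tablets = 100, dosage_text = "1 tablet daily", unit_bag = 0),
    tibble::tibble(patient_id = "fc", icd10_code = "I10", dx_date = d0 - 10),
    "2006-01-01", "2007-12-31"
  )
  expect_equal(res$eligible$patient_id, "fc")
  expect_equal(as.character(res$eligible$index_class), "FIXED_COMBINATION")
})

test_that("index fills outside the enrollment window are excluded", {
  d0 <- as.Date("2009-06-01")
  res <- apply_eligibility(
    tibble::tibble(patient_id = "late", birth_date = d0 - 40 * 365),
    tibble::tibble(patient_id = "late", fill_date = d0, atc_code = "C09AA02",
                   tablets = 100, dosage_text = "1 tablet daily", unit_bag = 0),
    tibble::tibble(patient_id = "late", icd10_code = "I10", dx_date = d0 - 10),
    "2006-01-01", "2007-12-31"
  )
  expect_equal(res$exclusions$reason, "index_outside_window")
  expect_error(
    apply_eligibility(tibble::tibble(patient_id = "x", birth_date = d0),
                      tibble::tibble(patient_id = "x", fill_date = d0,
                                     atc_code = "C09AA02", tablets = 1,
                                     dosage_text = "", unit_bag = 0),
                      NULL, "2006-01-01", "2007-12-31"),
    "diagnoses"
  )
})
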