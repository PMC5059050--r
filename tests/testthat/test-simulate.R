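test_that("configuration validates fields and rejects unknown keys", {
  expect_s3_class(sim_config(n_patients = 10), "sim_config")
  expect_error(sim_config(not_a_field = 1), "unknown sim_config field")
  expect_error(sim_config(switch_prob = 1.4), "switch_prob")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(baseline = list(rates = c(-1, 1), breaks = 365)),
               "baseline")
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_patients = 120, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_cohort_csv(a, dir_a)
  write_cohort_csv(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(unname(tools::md5sum(file.path(dir_a, f))),
                     unname(tools::md5sum(file.path(dir_b, f))), info = f)
  }
})

test_that("extending the cohort leaves earlier patients untouched", {
  small <- generate_cohort(sim_config(n_patients = 40, seed = 5))
  large <- generate_cohort(sim_config(n_patients = 80, seed = 5))
  first40 <- large$ground_truth[large$ground_truth$patient_id %in%
                                  small$ground_truth$patient_id, ]
  expect_identical(small$ground_truth, first40)
})

test_that("planted violators are excluded for the planted reason", {
  cfg <- sim_config(n_patients = 400, seed = 17,
                    violators = list(p_under30 = 0.05, p_dx_after = 0.05,
                                     p_no_fill = 0.05, p_multi_product = 0.05))
  co <- generate_cohort(cfg)
  elig <- apply_eligibility(co$patients, co$dispensings, co$diagnoses,
                            cfg$enrollment_start, cfg$enrollment_end)
  gt <- co$ground_truth
  planted <- gt[!gt$eligible, c("patient_id", "violation")]
  expect_gt(nrow(planted), 0)
  m <- dplyr::inner_join(planted, elig$exclusions, by = "patient_id")
  expect_equal(nrow(m), nrow(planted))
  expect_equal(m$reason, m$violation)
  # and every emitted eligible patient passes
  expect_setequal(elig$eligible$patient_id, gt$patient_id[gt$eligible])
})

test_that("degenerate configuration yields only discontinuations", {
  cfg <- sim_config(n_patients = 150, seed = 23, switch_prob = 0, addon_prob = 0,
                    death_prob = 0, hosp_rate_per_year = 0, unit_bag_prob = 0,
                    missing_text_prob = 0, unparseable_text_prob = 0,
                    violators = list(p_under30 = 0, p_dx_after = 0,
                                     p_no_fill = 0, p_multi_product = 0))
  co <- generate_cohort(cfg)
  elig <- apply_eligibility(co$patients, co$dispensings, co$diagnoses,
                            cfg$enrollment_start, cfg$enrollment_end)
  ep <- build_episodes(elig$eligible, co$dispensings, co$hospitalizations)
  non_pers <- ep$outcomes[ep$outcomes$censor_reason != "end_of_followup", ]
  expect_true(all(non_pers$status == "discontinued"))
  expect_false(any(ep$outcomes$addon))
})

test_that("pipeline reproduces planted event times exactly when rules align", {
  cfg <- sim_config(n_patients = 300, seed = 29, missing_text_prob = 0,
                    unparseable_text_prob = 0, unit_bag_prob = 0,
                    death_prob = 0, hosp_rate_per_year = 0)
  co <- generate_cohort(cfg)
  elig <- apply_eligibility(co$patients, co$dispensings, co$diagnoses,
                            cfg$enrollment_start, cfg$enrollment_end)
  ep <- build_episodes(elig$eligible, co$dispensings, co$hospitalizations)
  rc <- recovery_check(co$ground_truth, ep$outcomes, cfg, fit_cox = FALSE)
  expect_equal(rc$event_time_match, 1)
  expect_equal(rc$status_match, 1)
  # planted switchers are recovered as switchers
  gt <- co$ground_truth
  sw <- gt$patient_id[gt$eligible & !is.na(gt$true_status) &
                        gt$true_status == "switched"]
  oc <- ep$outcomes[ep$outcomes$patient_id %in% sw, ]
  expect_true(all(oc$status == "switched"))
})

test_that("missing-dosage fraction tracks its configured probability", {
  cfg <- sim_config(n_patients = 400, seed = 37, missing_text_prob = 0.05,
                    switch_prob = 0, addon_prob = 0,
                    covariates = utils::modifyList(
                      sim_config(n_patients = 1)$covariates,
                      list(other_drugs_lambda = 0)),
                    violators = list(p_under30 = 0, p_dx_after = 0,
                                     p_no_fill = 0, p_multi_product = 0))
  co <- generate_cohort(cfg)
  frac <- mean(co$dispensings$dosage_text == "")
  n <- nrow(co$dispensings)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("ground-truth sidecar is internally consistent", {
  cfg <- sim_config(n_patients = 200, seed = 41)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth[co$ground_truth$eligible, ]
  expect_true(all(gt$true_status %in% c("persistent", "discontinued", "switched")))
  expect_true(all(gt$true_event_days[gt$true_status == "persistent"] == cfg$followup_days))
  expect_true(all(is.na(gt$switch_day) | gt$switch_day - gt$true_event_days <= cfg$grace_days))
  expect_true(all(gt$age >= 30))
  expect_true(all(gt$sbp > gt$dbp))
})
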