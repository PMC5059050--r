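test_that("worked dosage examples parse to the expected daily rates", {
  expect_equal(parse_dosage("1 tablet daily")$daily_dose, 1)
  expect_equal(parse_dosage("1 tablet daily")$source, "parsed")
  expect_equal(parse_dosage("2 tablets twice daily")$daily_dose, 4)
  p <- parse_dosage("1 tablet in the morning and 0.5 tablet in the evening")
  expect_equal(p$daily_dose, 1.5)
  expect_equal(p$source, "parsed")
  expect_equal(parse_dosage("1/2 tablet daily")$daily_dose, 0.5)
  expect_equal(parse_dosage("1 tablet every other day")$daily_dose, 0.5)
})

test_that("missing text defaults to one tablet per day, flagged as missing", {
  for (txt in list("", "   ", NA_character_)) {
    p <- parse_dosage(txt)
    expect_equal(p$daily_dose, 1)
    expect_equal(p$source, "defaulted_missing")
  }
})

test_that("unparseable text defaults with a warning and a distinct flag", {
  expect_warning(p <- parse_dosage("take as directed"), class = "rxpersist_dosage_default")
  expect_equal(p$daily_dose, 1)
  expect_equal(p$source, "defaulted_unparseable")
  # pro-re-nata and dose-range texts carry no fixed daily rate
  for (txt in c("1 tablet as needed", "1-2 tablets daily", "0 tablets daily")) {
    expect_equal(suppressWarnings(parse_dosage(txt))$source, "defaulted_unparseable")
  }
})

test_that("parser agrees with the token-based reference grammar", {
  quantities <- c("1", "2", "0.5", "1/2", "3", "1.5")
  freqs <- c("", "daily", "every other day", "twice daily", "three times daily",
             "in the morning", "at night")
  for (q in quantities) {
    for (f in freqs) {
      txt <- trimws(paste(q, if (q %in% c("1", "0.5", "1/2")) "tablet" else "tablets", f))
      expect_equal(parse_dosage(txt)$daily_dose, ref_parse_dosage(txt),
                   info = txt)
    }
  }
})

test_that("clauses joined by 'and' add their rates", {
  clauses <- c("1 tablet daily", "2 tablets twice daily", "1/2 tablet at night",
               "1 tablet every other day")
  for (a in clauses) {
    for (b in clauses) {
      combined <- paste(a, "and", b)
      expect_equal(parse_dosage(combined)$daily_dose,
                   parse_dosage(a)$daily_dose + parse_dosage(b)$daily_dose,
                   info = combined)
    }
  }
})

test_that("parse_dosage is total over arbitrary byte strings", {
  set.seed(20)
  for (i in 1:200) {
    txt <- rawToChar(as.raw(sample(c(32:126), sample(0:30, 1), replace = TRUE)))
    expect_no_error(suppressWarnings(p <- parse_dosage(txt)))
    expect_gt(p$daily_dose, 0)
  }
})

test_that("every generator regimen text round-trips exactly", {
  cfg <- sim_config(n_patients = 1)
  for (reg in cfg$regimens) {
    for (txt in reg$texts) {
      p <- parse_dosage(txt)
      expect_equal(p$source, "parsed", info = txt)
      expect_equal(p$daily_dose, reg$dose, info = txt)
    }
  }
})

test_that("grammar rule table can be extended", {
  extra <- tibble::tibble(pattern = "at supper", mult_num = 1, mult_den = 1)
  rules <- dosage_rules(extra)
  expect_equal(parse_dosage("2 tablets at supper", rules = rules)$daily_dose, 2)
  expect_equal(suppressWarnings(parse_dosage("2 tablets at supper"))$source,
               "defaulted_unparseable")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(extra, path)
  expect_equal(parse_dosage("2 tablets at supper", rules = dosage_rules(path))$daily_dose, 2)
  expect_error(dosage_rules(tibble::tibble(pattern = "x")), "mult_num")
})

test_that("batch parsing aggregates defaulted counts into one warning", {
  texts <- c("1 tablet daily", "", "gibberish", "2 tablets daily", "nonsense")
  expect_warning(out <- parse_dosage_batch(texts), "2 dosage text")
  expect_equal(out$source,
               c("parsed", "defaulted_missing", "defaulted_unparseable",
                 "parsed", "defaulted_unparseable"))
  expect_equal(out$daily_dose, c(1, 1, 1, 2, 1))
})
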