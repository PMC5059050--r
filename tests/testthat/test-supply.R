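d0 <- as.Date("2006-01-01")

mk_fills <- function(days, tablets, texts) {
  tibble::tibble(patient_id = "X", fill_date = d0 + days, atc_code = "C09AA02",
                 tablets = tablets, dosage_text = texts)
}

end_day_rel <- function(sch) supply_end_day(sch) - as.numeric(d0)

test_that("single fill at one tablet per day lasts exactly its tablet count", {
  sch <- build_supply_schedule(mk_fills(0, 100, "1 tablet daily"))
  expect_equal(end_day_rel(sch), 100)
  expect_equal(nrow(sch$intervals), 1)
})

test_that("early refill carries leftover tablets forward", {
  sch <- build_supply_schedule(mk_fills(c(0, 90), c(100, 100), "1 tablet daily"))
  expect_equal(end_day_rel(sch), 200)  # 10 leftover tablets at day 90
})

test_that("same-day fills are consumed successively", {
  sch <- build_supply_schedule(mk_fills(c(0, 0), c(100, 100), "1 tablet daily"))
  expect_equal(end_day_rel(sch), 200)
  # different dose on the same day: each lot at its own rate, 10/1 then 10/2
  sch2 <- build_supply_schedule(
    mk_fills(c(0, 0), c(10, 10), c("1 tablet daily", "1 tablet twice daily"))
  )
  expect_equal(end_day_rel(sch2), 15)
  expect_equal(sch2$intervals$start - as.numeric(d0), c(0, 10))
})

test_that("carry-over tablets are consumed at the incoming fill's dose", {
  sch <- build_supply_schedule(
    mk_fills(c(0, 60), c(90, 90), c("1 tablet daily", "1 tablet twice daily"))
  )
  expect_equal(end_day_rel(sch), 120)  # 60 + (30 + 90)/2
})

test_that("fractional doses keep exact rational supply ends", {
  # 31 tablets at 1/2 tablet/day: 62 days exactly
  sch <- build_supply_schedule(mk_fills(0, 31, "1/2 tablet daily"))
  expect_equal(end_day_rel(sch), 62)
  # 10 tablets at 3/day: 10/3 days, covering day 3 partially
  sch2 <- build_supply_schedule(mk_fills(0, 10, "3 tablets daily"))
  expect_equal(end_day_rel(sch2), 4)
  expect_equal(sch2$intervals$end_num, 10 + 3 * as.numeric(d0))
  expect_equal(sch2$intervals$end_den, 3)
})

test_that("tablet conservation holds after every carry-over", {
  set.seed(31)
  for (i in 1:50) {
    h <- random_history()
    sch <- build_supply_schedule(fills_to_tibble(h))
    expect_true(tablets_conserved(sch))
    expect_true(all(diff(sch$intervals$start) >= 0))
    expect_true(all(sch$intervals$end > sch$intervals$start))
  }
})

test_that("interval arithmetic matches the day-level consumption oracle", {
  set.seed(32)
  for (i in 1:100) {
    h <- random_history()
    sch <- build_supply_schedule(fills_to_tibble(h))
    runs <- oracle_runs(h, horizon = max(h$day) + sum(h$tablets) + 50)
    expect_equal(supply_end_day(sch) - as.numeric(d0), unname(runs[nrow(runs), 2]),
                 info = paste(capture.output(print(h)), collapse = "\n"))
  }
})

test_that("contract violations are rejected", {
  expect_error(build_supply_schedule(mk_fills(integer(0), numeric(0), character(0))),
               class = "rxpersist_no_fills")
  expect_error(build_supply_schedule(mk_fills(0, 0, "1 tablet daily")), "tablets")
  mixed <- tibble::tibble(patient_id = "X", fill_date = d0 + c(0, 10),
                          atc_code = c("C09AA02", "C07AB02"), tablets = 10,
                          dosage_text = "1 tablet daily")
  expect_error(build_supply_schedule(mixed), "one drug class")
})
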