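test_that("daily dose converts daily and depot schedules", {
  expect_equal(daily_dose(25, interval_days = 28), 25 / 28)
  expect_equal(round_half_away(daily_dose(25, interval_days = 28), 2), 0.89)
  expect_equal(round_half_away(daily_dose(100, interval_days = 28), 2), 3.57)
  expect_equal(daily_dose(7, interval_days = 1), 7) # identity interval
  expect_equal(daily_dose(5, times_per_day = 2), 10)
  expect_error(daily_dose(-5, times_per_day = 1), "positive")
  expect_error(daily_dose(5, interval_days = 0), "positive integer")
  expect_error(daily_dose(5), "exactly one")
  expect_error(daily_dose(5, times_per_day = 1, interval_days = 28), "exactly one")
})

test_that("depot conversion equals the mean of the injection-day ledger", {
  # place the full dose at injection, spread nothing: mean over the interval
  # equals the uniform-spread daily dose
  for (case in list(c(25, 28), c(100, 28), c(50, 2), c(200, 14))) {
    ledger <- c(case[1], rep(0, case[2] - 1))
    expect_equal(mean(ledger), daily_dose(case[1], interval_days = case[2]))
  }
})

test_that("PDD averages the day ledger over exposed days", {
  # constant dose for the whole stay
  rx <- resolve_test(rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-14"))
  expect_equal(patient_pdd(rx)$pdd_mg_per_day, 10)
  expect_equal(patient_pdd(rx)$exposed_days, 14L)

  # titration modelled as two consecutive orders: (4*10 + 4*20)/8 = 15
  rx <- resolve_test(dplyr::bind_rows(
    rx_raw("P1", "Olanzapine", 5, "2014-06-01", "2014-06-04", times_per_day = 2),
    rx_raw("P1", "Olanzapine", 10, "2014-06-05", "2014-06-08", times_per_day = 2)
  ))
  expect_equal(patient_pdd(rx)$pdd_mg_per_day, 15)
  expect_equal(patient_pdd(rx)$pdd_mg_per_day, ledger_pdd_oracle(rx))

  # two concurrent orders of the same drug sum day by day
  rx <- resolve_test(dplyr::bind_rows(
    rx_raw("P1", "Olanzapine", 5, "2014-06-01", "2014-06-10"),
    rx_raw("P1", "Olanzapine", 5, "2014-06-01", "2014-06-10")
  ))
  expect_equal(patient_pdd(rx)$pdd_mg_per_day, 10)
  expect_equal(patient_pdd(rx)$pdd_mg_per_day, ledger_pdd_oracle(rx))
})

test_that("an empty prescription list yields a flagged no-exposure result", {
  rx <- resolve_test(rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-14"))[0, ]
  out <- patient_pdd(rx)
  expect_true(out$no_exposure)
  expect_equal(out$pdd_mg_per_day, 0)
  expect_equal(out$exposed_days, 0L)
})

test_that("date ranges are inclusive: a one-day order has one exposed day", {
  rx <- resolve_test(rx_raw("P1", "Haloperidol", 5, "2014-06-03", "2014-06-03"))
  out <- patient_pdd(rx)
  expect_equal(out$exposed_days, 1L)
  expect_equal(out$pdd_mg_per_day, 5)
})

test_that("PDD scales linearly in dose and is invariant to order splitting", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(1:4, 1)
      starts <- as.Date("2014-06-01") + sample(0:10, n, replace = TRUE)
      lens <- sample(1:10, n, replace = TRUE)
      doses <- stats::runif(n, 1, 30)
      rx <- resolve_test(purrr::list_rbind(purrr::map(seq_len(n), function(i) {
        rx_raw("P1", "Olanzapine", doses[i], starts[i], starts[i] + lens[i] - 1)
      })))
      base <- patient_pdd(rx)$pdd_mg_per_day
      # scaling
      k <- stats::runif(1, 0.5, 3)
      rx_k <- dplyr::mutate(rx,
        dose_mg = dose_mg * k, daily_dose_mg = daily_dose_mg * k
      )
      expect_equal(patient_pdd(rx_k)$pdd_mg_per_day, k * base)
      # splitting the first order into two abutting ranges
      first <- rx[1, ]
      if (first$end_date > first$start_date) {
        cut <- first$start_date + sample.int(as.integer(first$end_date - first$start_date), 1) - 1
        split_rx <- dplyr::bind_rows(
          dplyr::mutate(first, end_date = cut),
          dplyr::mutate(first, start_date = cut + 1),
          rx[-1, ]
        )
        expect_equal(patient_pdd(split_rx)$pdd_mg_per_day, base)
      }
    }
  })
})

test_that("prescription validation catches schedule and date errors", {
  reg <- default_registry()
  bad_dates <- rx_raw("P1", "Olanzapine", 10, "2014-06-10", "2014-06-01")
  expect_error(resolve_prescriptions(bad_dates, reg), "start_date after end_date")
  depot_on_oral <- rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-10",
    interval_days = 28L
  )
  expect_error(resolve_prescriptions(depot_on_oral, reg), "non-long_acting")
  unknown_ap <- rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-10",
    atc = "N05AH09"
  )
  expect_error(resolve_prescriptions(unknown_ap, reg), "row 1.*not in registry")
})
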