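test_that("sequential switching is not concurrency; overlap is", {
  # disjoint date ranges: monotherapy with a switch
  rx <- dplyr::bind_rows(
    rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-10"),
    rx_raw("P1", "Risperidone", 6, "2014-06-11", "2014-06-20")
  ) |> resolve_test()
  expect_equal(max_concurrency(rx), 1L)

  # clozapine days 1-20 plus amisulpride days 5-20: augmentation, concurrent
  rx <- dplyr::bind_rows(
    rx_raw("P1", "Clozapine", 300, "2014-06-01", "2014-06-20"),
    rx_raw("P1", "Amisulpride", 400, "2014-06-05", "2014-06-20")
  ) |> resolve_test()
  expect_equal(max_concurrency(rx), 2L)
})

test_that("two presentations of one chemical count as one agent", {
  rx <- dplyr::bind_rows(
    rx_raw("P1", "Risperidone", 6, "2014-06-01", "2014-06-20"),
    rx_raw("P1", "Long-acting risperidone", 100, "2014-06-01", "2014-06-20",
      interval_days = 28L
    )
  ) |> resolve_test()
  expect_equal(max_concurrency(rx), 1L)
  expect_equal(classify_regimen(rx)$regimen, "monotherapy")
})

test_that("min_overlap_days tolerates short cross-taper overlaps", {
  rx <- dplyr::bind_rows(
    rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-12"),
    rx_raw("P1", "Risperidone", 6, "2014-06-10", "2014-06-20") # 3-day overlap
  ) |> resolve_test()
  expect_equal(max_concurrency(rx, min_overlap_days = 1), 2L)
  expect_equal(max_concurrency(rx, min_overlap_days = 3), 2L)
  expect_equal(max_concurrency(rx, min_overlap_days = 4), 1L)
  expect_error(max_concurrency(rx, min_overlap_days = 0), ">= 1")
})

test_that("concurrency matches the brute-force day sweep on random instances", {
  chems <- c("N05AH03", "N05AX08", "N05AH02", "N05AL05", "N06AB06", "N05AN01")
  withr::with_seed(42, {
    for (i in 1:500) {
      rx <- random_rx_instance(sample(1:6, 1), chems)
      expect_equal(max_concurrency(rx), day_sweep_oracle(rx))
    }
  })
})

test_that("classification is invariant to prescription order", {
  chems <- c("N05AH03", "N05AX08", "N05AH02", "N05AL05")
  withr::with_seed(7, {
    for (i in 1:50) {
      rx <- random_rx_instance(sample(2:6, 1), chems)
      shuffled <- rx[sample(nrow(rx)), ]
      expect_identical(
        classify_regimen(rx)[-1], # patient_id row order irrelevant
        classify_regimen(shuffled)[-1]
      )
    }
  })
})

test_that("regimen classification distinguishes none/mono/poly and pure regimens", {
  # one antipsychotic plus one antidepressant: monotherapy, not pure
  rx <- dplyr::bind_rows(
    rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-14"),
    rx_raw("P1", "Sertraline", 100, "2014-06-01", "2014-06-14", atc = "N06AB06")
  ) |> resolve_test()
  out <- classify_regimen(rx)
  expect_equal(out$regimen, "monotherapy")
  expect_false(out$antipsychotic_only)

  # antipsychotics only
  rx <- resolve_test(rx_raw("P1", "Olanzapine", 10, "2014-06-01", "2014-06-14"))
  expect_true(classify_regimen(rx)$antipsychotic_only)

  # zero prescriptions
  out <- classify_regimen(rx[0, ])
  expect_equal(out$regimen, "none")
  expect_equal(out$n_antipsychotics_total, 0L)
  expect_false(out$antipsychotic_only)

  # lithium alone is not an antipsychotic regimen
  rx <- resolve_test(
    rx_raw("P1", "Lithium", 800, "2014-06-01", "2014-06-14", atc = "N05AN01")
  )
  expect_equal(classify_regimen(rx)$regimen, "none")
})

test_that("cohort classification matches per-patient classification", {
  co <- generate_cohort(cohort_spec(n_patients = 120, seed = 5))
  rx <- resolve_prescriptions(co$prescriptions, default_registry())
  regs <- classify_cohort(rx, co$patients)
  expect_equal(nrow(regs), 120)
  expect_setequal(regs$patient_id, co$patients$patient_id)
  for (pid in sample(co$patients$patient_id, 25)) {
    single <- classify_regimen(rx[rx$patient_id == pid, , drop = FALSE])
    row <- regs[regs$patient_id == pid, ]
    expect_equal(row$regimen, single$regimen)
    expect_equal(
      row$n_antipsychotics_concurrent_max,
      single$n_antipsychotics_concurrent_max
    )
  }
  # polypharmacy iff >= 2 concurrent; none iff no antipsychotics
  expect_identical(
    regs$regimen == "polypharmacy",
    regs$n_antipsychotics_concurrent_max >= 2L
  )
  expect_identical(regs$regimen == "none", regs$n_antipsychotics_total == 0L)
})

test_that("per-drug APP share counts users in polypharmacy", {
  rx <- dplyr::bind_rows(
    # P1: clozapine + amisulpride concurrently -> polypharmacy
    rx_raw("P1", "Clozapine", 300, "2014-06-01", "2014-06-20"),
    rx_raw("P1", "Amisulpride", 800, "2014-06-01", "2014-06-20"),
    # P2, P3: clozapine monotherapy
    rx_raw("P2", "Clozapine", 350, "2014-06-01", "2014-06-20"),
    rx_raw("P3", "Clozapine", 400, "2014-06-01", "2014-06-20")
  ) |> resolve_test()
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"), age = 40L, sex = "F",
    admission_date = as.Date("2014-06-01"), discharge_date = as.Date("2014-06-20")
  )
  regs <- classify_cohort(rx, patients)
  shares <- app_share_by_drug(compute_exposures(rx), regs)
  cloz <- shares[shares$drug == "Clozapine", ]
  expect_equal(cloz$n_users, 3L)
  expect_equal(cloz$n_in_polypharmacy, 1L)
  expect_equal(cloz$percent, 33.3)
  ami <- shares[shares$drug == "Amisulpride", ]
  expect_equal(ami$percent, 100)
})
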