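test_that("VO2 equation reproduces hand-evaluated and degenerate cases", {
  # hand-evaluated oracle value, frozen before the build
  expect_equal(
    vo2_rate(30000, 0.2095, 0.2000, 0.0004, 0.0100, 0.1),
    2842.5,
    tolerance = 1e-12
  )
  # identical incurrent/excurrent composition -> no gas exchange
  expect_equal(vo2_rate(30000, 0.21, 0.21, 0.0004, 0.0004, 0.1), 0)
  expect_equal(vco2_rate(30000, 0.21, 0.21, 0.0004, 0.0004, 0.1), 0)
  # zero flow -> zero rate
  expect_equal(vo2_rate(0, 0.2095, 0.2, 0.0004, 0.01, 0.1), 0)
  # mass-specific scaling: halving mass doubles both rates
  expect_equal(
    vco2_rate(30000, 0.2095, 0.2, 0.0004, 0.01, 0.05),
    2 * vco2_rate(30000, 0.2095, 0.2, 0.0004, 0.01, 0.1)
  )
  # CO2 production by the animal comes out positive
  expect_gt(vco2_rate(30000, 0.2095, 0.2, 0.0004, 0.01, 0.1), 0)
})

test_that("equations agree with independent brute-force evaluation", {
  set.seed(42)
  n <- 500
  fr <- runif(n, 1000, 60000)
  fio <- runif(n, 0.19, 0.21)
  feo <- fio - runif(n, 0, 0.02)
  fic <- runif(n, 2e-4, 1e-3)
  fec <- fic + runif(n, 0, 0.02)
  m <- runif(n, 0.05, 0.15)
  expect_equal(
    vo2_rate(fr, fio, feo, fic, fec, m),
    oracle_vo2(fr, fio, feo, fic, fec, m),
    tolerance = 1e-12
  )
  expect_equal(
    vco2_rate(fr, fio, feo, fic, fec, m),
    oracle_vco2(fr, fio, feo, fic, fec, m),
    tolerance = 1e-12
  )
})

test_that("CO2-fraction shifts cancel in VO2 but not in VCO2", {
  # VO2 depends on the CO2 fractions only through their difference, so a
  # common additive shift cancels; VCO2 carries fe_co2 on its own (in the
  # interference term and the denominator) and is genuinely sensitive
  base <- vo2_rate(30000, 0.2095, 0.2, 0.0004, 0.01, 0.1)
  shifted <- vo2_rate(30000, 0.2095, 0.2, 0.0004 + 0.005, 0.01 + 0.005, 0.1)
  expect_equal(shifted, base, tolerance = 1e-12)
  base_c <- vco2_rate(30000, 0.2095, 0.2, 0.0004, 0.01, 0.1)
  shifted_c <- vco2_rate(30000, 0.2095, 0.2, 0.0004 + 0.005, 0.01 + 0.005, 0.1)
  expect_false(isTRUE(all.equal(base_c, shifted_c)))
})

test_that("RER is the flagged element-wise ratio with explicit undefined marks", {
  r <- compute_rer(c(1000, 700, 1100, 500), c(1000, 1000, 1000, 0))
  expect_equal(r$rer[1:3], c(1.0, 0.7, 1.1))
  expect_true(is.na(r$rer[4]))
  expect_false(r$rer_defined[4])
  expect_equal(r$rer_flagged[1:3], c(FALSE, FALSE, TRUE))
  expect_error(compute_rer(1:3, 1:2), "aligned")
})

test_that("EE formula matches its oxycaloric form and unit contract", {
  # unit inputs: (3.815 + 1.232) * 1 * 1
  expect_equal(compute_ee(1.0, 1000, 1), 5.047)
  # group-level magnitudes: product of published female night means
  expect_equal(compute_ee(0.99, 2147, 0.0997), 1.0777, tolerance = 1e-4)
  # zero VO2 -> zero EE even with RER defined
  expect_equal(compute_ee(0.7, 0, 0.1), 0)
  # monotone in RER and VO2
  expect_gt(compute_ee(0.9, 2000, 0.1), compute_ee(0.8, 2000, 0.1))
  expect_gt(compute_ee(0.9, 2500, 0.1), compute_ee(0.9, 2000, 0.1))
  # unit-mismatch guard for a 100 g animal
  expect_warning(compute_ee(0.9, 2e6, 0.1), "unit")
})

test_that("phase labelling follows the photoperiod schedule", {
  sch <- photoperiod("17:00", "03:00")
  expect_equal(sch$day_length_h, 14)
  expect_equal(assign_phase(parse_hhmm("12:00"), sch), "day")
  expect_equal(assign_phase(parse_hhmm("17:00"), sch), "night")
  expect_equal(assign_phase(parse_hhmm("02:59"), sch), "night")
  expect_equal(assign_phase(parse_hhmm("03:00"), sch), "day")
  expect_error(photoperiod("12:00", "12:00"), "differ")
})

test_that("phase aggregation averages correctly and conserves the global mean", {
  sch <- photoperiod()
  # square wave: 1000 by day, 2000 by night
  n <- 144
  mins <- (sch$lights_off + 10 * (seq_len(n) - 1)) %% 1440
  phase <- assign_phase(mins, sch)
  vals <- ifelse(phase == "night", 2000, 1000)
  ser <- tibble::tibble(
    animal_id = "A1", phase = phase, vo2 = vals, vco2 = vals,
    rer = 0.9, ee_kcal_h = 1
  )
  agg <- aggregate_by_phase(ser)
  expect_equal(agg$vo2[agg$phase == "day"], 1000)
  expect_equal(agg$vo2[agg$phase == "night"], 2000)
  # constant series: both phases equal the constant
  agg2 <- aggregate_by_phase(dplyr::mutate(ser, vo2 = 42))
  expect_equal(agg2$vo2, c(42, 42))
  # weighted recombination of phase means equals the global mean
  w <- agg$n / sum(agg$n)
  expect_equal(sum(w * agg$vo2), mean(vals), tolerance = 1e-9)
  # empty phase -> explicit NA row with n = 0
  agg3 <- aggregate_by_phase(dplyr::filter(ser, phase == "night"))
  day_row <- dplyr::filter(agg3, phase == "day")
  expect_equal(day_row$n, 0L)
  expect_true(is.na(day_row$vo2))
})

test_that("full derivation round-trips a constructed trace", {
  tr <- make_trace(vo2 = rep(2000, 20), rer = rep(0.9, 20))
  ser <- derive_metabolic_series(tr)
  expect_equal(ser$vo2, rep(2000, 20), tolerance = 1e-9)
  expect_equal(ser$rer, rep(0.9, 20), tolerance = 1e-9)
  expect_equal(
    ser$ee_kcal_h,
    rep((3.815 + 1.232 * 0.9) * 2 * 0.1, 20),
    tolerance = 1e-8
  )
  expect_true(all(ser$phase %in% c("day", "night")))
})

test_that("gas-trace validation rejects malformed inputs by name", {
  tr <- make_trace(vo2 = rep(2000, 5), rer = rep(0.9, 5))
  bad <- dplyr::mutate(tr, fe_o2 = dplyr::if_else(
    dplyr::row_number() == 3, 1.0, fe_o2
  ))
  expect_error(compute_vo2(bad), "fe_o2")
  bad2 <- tr
  bad2$time[2] <- bad2$time[1]
  expect_error(compute_vo2(bad2), "increasing")
  expect_error(compute_vo2(dplyr::mutate(tr, fr_i = -1)), "fr_i")
  expect_error(compute_vo2(dplyr::mutate(tr, body_mass_kg = 0)), "body_mass")
  expect_error(compute_vo2(dplyr::mutate(tr, fi_o2 = NA_real_)), "non-finite")
})

test_that("CSV reader converts units and drops excurrent-flow columns", {
  tr <- make_trace(vo2 = rep(2000, 5), rer = rep(0.9, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- tr |>
    dplyr::mutate(
      datetime = format(time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      body_mass_g = body_mass_kg * 1000,
      fr_i_ml_per_h = fr_i,
      fr_e_ml_per_h = fr_i * 0.99
    ) |>
    dplyr::select(
      animal_id, datetime, fi_o2, fe_o2, fi_co2, fe_co2,
      fr_i_ml_per_h, fr_e_ml_per_h, body_mass_g
    )
  readr::write_csv(out, path)
  expect_message(got <- read_gas_traces(path), "fr_i")
  expect_false(any(grepl("^fr_e", names(got))))
  expect_equal(got$body_mass_kg, tr$body_mass_kg)
  expect_equal(got$fe_o2, tr$fe_o2, tolerance = 1e-12)
})
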