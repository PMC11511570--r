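test_that("K2 from Henry's constant reproduces the air-water coefficients", {
  # 60 C and 10 C conditions for the derivatized analyte
  expect_equal(k2_from_henry(5.25e-4, 333.15), 1.92e-2, tolerance = 1e-2)
  expect_equal(k2_from_henry(5.58e-5, 283.15), 2.40e-3, tolerance = 1e-2)
  # identity: K_H = RT gives K2 = 1
  expect_equal(k2_from_henry(GAS_CONSTANT_ATM * 300, 300), 1.0)
  expect_error(k2_from_henry(-1, 300), "henry_constant")
  expect_error(k2_from_henry(1e-4, 0), "temperature")
})

test_that("Kow routes to the partition coefficients", {
  expect_equal(k_from_kow(2.88), 758.6, tolerance = 1e-3)
  expect_equal(k_from_kow(0), 1.0)
  expect_equal(k_from_kow(3.41), 2570.4, tolerance = 1e-3)
  k2 <- k2_from_henry(5.25e-4, 333.15)
  expect_equal(k1_from_kow_k2(2.88, k2), 3.95e4, tolerance = 1e-2)
  expect_equal(k1_from_kow_k2(0, 1), 1.0)
  # the 10 C Kow/K2 route differs from the LTPRI route by design
  expect_equal(k1_from_kow_k2(3.41, 2.40e-3), 1.07e6, tolerance = 1e-2)
  expect_error(k1_from_kow_k2(2.88, 0), "k2")
})

test_that("K = K1 * K2 consistency between the Kow routes", {
  for (lk in c(0.5, 2.88, 3.41)) {
    for (kh in c(5.58e-5, 5.25e-4)) {
      k2 <- k2_from_henry(kh, 300)
      expect_equal(k1_from_kow_k2(lk, k2) * k2, k_from_kow(lk))
    }
  }
})

test_that("LTPRI correlation maps retention index to K1", {
  expect_equal(k1_from_ltpri(1384), 4.215e5, tolerance = 1e-3)
  co <- ltpri_correlation()
  expect_equal(k1_from_ltpri(-co$intercept / co$slope), 1.0)
  expect_equal(k1_from_ltpri(1000), 10^4.012, tolerance = 1e-9)
  expect_error(ltpri_correlation(slope = 0), "nonzero")
})

test_that("van't Hoff form gives temperature-corrected K1", {
  expect_equal(k1_vant_hoff(vant_hoff_params(0, 2), 300), 100)
  expect_equal(k1_vant_hoff(vant_hoff_params(1000, 0), 500), 100)
  # exothermic absorption: cooling raises K1
  p <- vant_hoff_params(vant_hoff_slope(45000), -5)
  expect_gt(k1_vant_hoff(p, 283.15), k1_vant_hoff(p, 333.15))
  expect_error(k1_vant_hoff(p, -10), "temperature")
})

test_that("equilibrium uptake matches the three-phase mass-balance oracle", {
  cases <- expand.grid(
    v1 = c(2.6e-5, 1.32e-4, 6.12e-4),
    k1 = c(1e3, 3.95e4, 4.215e5),
    k2 = c(2.40e-3, 1.92e-2),
    c0 = c(0.05, 0.2708)
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    sys <- phase_system(cs$v1, 2.9, 17.1, 333.15)
    n <- equilibrium_uptake(sys, cs$c0, partition_set(cs$k1, cs$k2))
    oracle <- mass_balance_oracle(cs$v1, 2.9, 17.1, cs$k1, cs$k2, cs$c0)
    expect_equal(n, oracle$coating, tolerance = 1e-9)
    # mass conservation across the three phases
    expect_equal(oracle$coating + oracle$liquid + oracle$headspace,
                 cs$c0 * 2.9 * 1000, tolerance = 1e-9)
    # never exhaustive
    expect_lte(n, cs$c0 * 2.9 * 1000)
  }
})

test_that("uptake limits and monotonicity behave physically", {
  parts <- partition_set(3.95e4, 1.92e-2, "from_kow")
  sys0 <- phase_system(0, 2.9, 17.1, 333.15)
  expect_equal(equilibrium_uptake(sys0, 0.3, parts), 0)
  # exhaustive-extraction limit: K1 K2 -> infinity recovers all mass
  sys <- phase_system(1.32e-4, 2.9, 17.1, 333.15)
  n_inf <- equilibrium_uptake(sys, 0.3, partition_set(1e12, 1, "user"))
  expect_equal(n_inf, 0.3 * 2.9 * 1000, tolerance = 1e-4)
  # monotone non-decreasing in c0, v1 and k1
  n_base <- equilibrium_uptake(sys, 0.2, parts)
  expect_gte(equilibrium_uptake(sys, 0.4, parts), n_base)
  sys_big <- phase_system(6.12e-4, 2.9, 17.1, 333.15)
  expect_gte(equilibrium_uptake(sys_big, 0.2, parts), n_base)
  expect_gte(equilibrium_uptake(sys, 0.2, partition_set(8e4, 1.92e-2)),
             n_base)
  expect_error(
    equilibrium_uptake(phase_system(0, 0, 0, 300), 0.3, parts),
    "degenerate"
  )
})

test_that("uptake kinetics follow the 95%-equilibrium convention", {
  pred <- uptake_prediction(120, 38)
  expect_equal(uptake_at_time(pred, 0), 0)
  expect_equal(uptake_at_time(pred, 38), 0.95 * 120)
  expect_equal(uptake_at_time(pred, 1e6), 120)
  tt <- seq(0, 80, by = 0.5)
  masses <- uptake_at_time(pred, tt)
  expect_true(all(diff(masses) > 0))
  expect_true(all(masses <= 120))
  expect_error(uptake_at_time(pred, -1), "time")
})

test_that("prep-protocol bookkeeping gives the liquid and headspace volumes", {
  p <- default_prep_protocol()
  expect_equal(liquid_volume(p), 2.9)
  expect_equal(headspace_volume(p), 17.1)
  expect_error(
    prep_protocol(data.frame(volume = 25, role = "sample"), vial_volume = 20),
    "exceed"
  )
})

test_that("effective concentration accounts for dilution and derivatization", {
  p <- default_prep_protocol()
  expect_equal(effective_c0(p, 0.3, 136.194, 178.231), 0.2707563,
               tolerance = 1e-6)
  # identical molecular weights and a lone sample addition: unchanged
  solo <- prep_protocol(data.frame(volume = 2, role = "sample"))
  expect_equal(effective_c0(solo, 0.5, 100, 100), 0.5)
  # a 50% yield halves the effective concentration
  expect_equal(effective_c0(p, 0.3, 136.194, 178.231, yield = 0.5),
               0.2707563 / 2, tolerance = 1e-6)
})

test_that("molecular weights come from standard atomic weights", {
  expect_equal(formula_weight("C11H14O2"), 178.231, tolerance = 1e-6)
  expect_equal(formula_weight("C9H12O"), 136.194, tolerance = 1e-6)
  expect_equal(formula_weight("H2O"), 18.015, tolerance = 1e-6)
  expect_error(formula_weight("C2Xx4"), "unknown element|parse")
})

test_that("phase systems convert Celsius and validate inputs", {
  sys <- phase_system(1e-4, 2.9, 17.1, 60, unit = "C")
  expect_equal(sys$temperature, 333.15)
  expect_error(phase_system(-1, 2.9, 17.1, 300), "volumes")
  expect_error(phase_system(1e-4, 2.9, 17.1, 0), "temperature")
})

test_that("nominal PDMS coating volumes are shipped for all thicknesses", {
  expect_equal(pdms_coating_volume(30), 1.32e-4)
  expect_equal(pdms_coating_volume(7), 2.6e-5)
  expect_equal(pdms_coating_volume(100), 6.12e-4)
  expect_error(pdms_coating_volume(65), "thickness")
})

test_that("analyte property records load from the YAML config", {
  path <- system.file("extdata", "bmda.yaml", package = "hsspme")
  recs <- read_analyte_properties(path)
  expect_length(recs, 2)
  expect_equal(recs[["60"]]$log_kow, 2.88)
  expect_equal(recs[["60"]]$temperature, 333.15)
  expect_equal(recs[["10"]]$henry_constant, 5.58e-5)
  expect_equal(recs[["10"]]$molecular_weight, 178.231, tolerance = 1e-6)
})
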