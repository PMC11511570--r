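test_that("internal-standard correction is a simple ratio with guards", {
  expect_equal(is_ratio(100, 100), 1.0)
  expect_equal(is_ratio(210501, 100000), 2.10501)
  expect_error(is_ratio(100, 0), "degenerate")
})

test_that("calibration fitting recovers an exact line and matches the
           normal-equations oracle", {
  concs <- c(0.3, 0.5, 1, 5, 10)
  exact <- data.frame(concentration = concs,
                      response = 210501 * concs + 151459)
  curve <- fit_calibration(exact)
  expect_equal(curve$slope, 210501, tolerance = 1e-9)
  expect_equal(curve$intercept, 151459, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
  # noisy fit agrees with the closed-form least-squares oracle
  set.seed(5)
  noisy <- data.frame(concentration = concs,
                      response = 210501 * concs + 151459 +
                        rnorm(5, 0, 5e4))
  c2 <- fit_calibration(noisy)
  oracle <- ols_oracle(noisy$concentration, noisy$response)
  expect_equal(c2$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(c2$intercept, oracle$intercept, tolerance = 1e-9)
  expect_equal(c2$sd_intercept, oracle$sd_intercept, tolerance = 1e-9)
  expect_equal(c2$r_squared, oracle$r_squared, tolerance = 1e-9)
  # constant response: zero slope
  flat <- data.frame(concentration = concs, response = rep(3, 5))
  expect_equal(fit_calibration(flat)$slope, 0, tolerance = 1e-12)
  expect_error(
    fit_calibration(data.frame(concentration = c(1, 2),
                               response = c(1, 2))),
    "levels"
  )
})

test_that("calibration averages replicates per level by default", {
  concs <- rep(c(0.3, 0.5, 1, 5, 10), each = 3)
  set.seed(9)
  dat <- data.frame(concentration = concs,
                    analyte_area = (2000 * concs + 500 +
                                    rnorm(length(concs), 0, 30)) * 100,
                    is_area = 100)
  c_avg <- fit_calibration(dat)
  means <- aggregate(analyte_area / is_area ~ concentration, dat, mean)
  oracle <- ols_oracle(means$concentration, means[[2]])
  expect_equal(c_avg$slope, oracle$slope, tolerance = 1e-9)
  c_pool <- fit_calibration(dat, average_replicates = FALSE)
  expect_equal(c_pool$residual_df, length(concs) - 2)
})

test_that("LOD/LOQ follow the SD-of-intercept rule", {
  concs <- c(0.3, 0.5, 1, 5, 10)
  set.seed(3)
  dat <- data.frame(concentration = concs,
                    response = 210501 * concs + 151459 + rnorm(5, 0, 2e4))
  curve <- fit_calibration(dat)
  lims <- lod_loq(curve)
  expect_equal(unname(lims["lod"]), 3.3 * curve$sd_intercept / curve$slope)
  expect_equal(unname(lims["loq"] / lims["lod"]), 3)
  # doubling the intercept SD doubles both limits
  curve2 <- curve
  curve2$sd_intercept <- 2 * curve$sd_intercept
  expect_equal(unname(lod_loq(curve2)), unname(2 * lims))
  curve3 <- curve
  curve3$sd_intercept <- 0
  expect_equal(unname(lod_loq(curve3)), c(0, 0))
  curve4 <- curve
  curve4$slope <- -1
  expect_error(lod_loq(curve4), "slope")
})

test_that("precision, accuracy and recovery statistics", {
  expect_equal(rsd_percent(c(9, 10, 11)), 10.0)
  expect_equal(rsd_percent(c(5, 5, 5)), 0)
  expect_error(rsd_percent(c(-1, 1)), "mean")
  expect_equal(accuracy_percent(1, 1), 100)
  expect_equal(accuracy_percent(c(0.95, 0.96, 0.97), 1), 96.0)
  expect_error(accuracy_percent(1, 0), "nominal")
  # recovery through a liquid-injection reference curve
  masses <- c(5, 10, 50, 100, 200)
  ref <- fit_calibration(data.frame(concentration = masses,
                                    response = 2 * masses))
  rec <- recovery_percent(2 * 92.1, ref, 100)
  expect_equal(rec$percent, 92.1, tolerance = 1e-9)
  expect_false(rec$below_range)
  ref_pos <- fit_calibration(data.frame(concentration = masses,
                                        response = 2 * masses + 10))
  rec0 <- recovery_percent(0, ref_pos, 100)
  expect_true(rec0$below_range)
  expect_error(recovery_percent(10, ref, 0), "theoretical_mass")
})

test_that("slope recovery across seeded synthetic calibration sets", {
  ok <- 0L
  n_sets <- 500L
  for (s in seq_len(n_sets)) {
    camp <- gen_calibration_campaign(interday_days = 1, interday_sets = 1,
                                     intraday_sets = 1, seed = s)
    cal <- camp[camp$scope == "interday" & camp$role == "calibrant", ]
    curve <- fit_calibration(data.frame(concentration = cal$level_mg_L,
                                        analyte_area = cal$analyte_area,
                                        is_area = cal$is_area))
    if (abs(curve$slope - 210501) <= 3 * curve$sd_slope) ok <- ok + 1L
  }
  expect_gte(ok / n_sets, 0.95)
})

test_that("performance report aggregates daily, inter- and intra-day", {
  # the same day's data under both scopes: all summaries must agree
  one <- gen_calibration_campaign(interday_days = 1, interday_sets = 2,
                                  intraday_sets = 2, seed = 21)
  day1 <- one[one$scope == "interday", ]
  both <- rbind(day1, transform(day1, scope = "intraday"))
  rep1 <- assemble_report(both)
  expect_equal(rep1$interday$lod, rep1$intraday$lod)
  expect_equal(rep1$overall$lod, rep1$interday$lod)
  expect_equal(rep1$interday$accuracy_1, rep1$daily$accuracy_1[1])

  # six identical days: the inter-day mean equals any daily value
  six <- do.call(rbind, lapply(1:6, function(d) transform(day1, day = d)))
  rep6 <- assemble_report(six)
  expect_equal(rep6$interday$lod, rep6$daily$lod[1])
  expect_equal(rep6$interday$rsd_0.3, rep6$daily$rsd_0.3[1])

  # a full synthetic campaign populates every cell
  camp <- gen_calibration_campaign(seed = 4)
  full <- assemble_report(camp)
  expect_equal(sum(full$daily$scope == "interday"), 6)
  expect_equal(sum(full$daily$scope == "intraday"), 1)
  expect_true(all(is.finite(unlist(full$overall))))
  expect_true(all(c("rsd_0.3", "rsd_1", "accuracy_0.3", "accuracy_1")
                  %in% names(full$overall)))
  # display rounding: limits to 2 significant figures, percents to 0.1
  disp <- format_report(full)
  expect_equal(disp$lod, signif(full$overall$lod, 2))
  expect_equal(disp$accuracy_1, round(full$overall$accuracy_1, 1))
})

test_that("LOD scales linearly with the injected response noise", {
  sigmas <- c(2e4, 4e4, 6e4, 8e4, 1e5)
  mean_lod <- vapply(sigmas, function(sg) {
    lods <- vapply(1:40, function(s) {
      camp <- gen_calibration_campaign(interday_days = 1, interday_sets = 1,
                                       intraday_sets = 1, noise_sd = sg,
                                       seed = s)
      cal <- camp[camp$scope == "interday" & camp$role == "calibrant", ]
      curve <- fit_calibration(data.frame(
        concentration = cal$level_mg_L,
        analyte_area = cal$analyte_area, is_area = cal$is_area))
      unname(lod_loq(curve)["lod"])
    }, numeric(1))
    mean(lods)
  }, numeric(1))
  fit <- lm(mean_lod ~ 0 + sigmas)
  expect_gt(summary(fit)$r.squared, 0.99)
})
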