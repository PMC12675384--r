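test_that("foot mass scales with body mass by the anthropometric fraction", {
  expect_equal(foot_mass_from_body(80.42), 1.17, tolerance = 0.005)
  expect_equal(foot_mass_from_body(100), 1.45)
  expect_equal(foot_mass_from_body(70, fraction = 0), 0)
  expect_error(foot_mass_from_body(-1), "> 0")
})

test_that("composite specific heat is the mass-weighted mixture and convex", {
  expect_equal(composite_specific_heat(
    data.frame(name = "soft", fraction = 1, c = 1.96)), 1.96)
  expect_equal(composite_specific_heat(
    data.frame(name = c("bone", "blood"), fraction = c(0.5, 0.5),
               c = c(1.31, 3.62))), 2.465)
  expect_error(composite_specific_heat(
    data.frame(fraction = c(0.5, 0.4), c = c(1, 2))), "sum")
  # convexity: any composition of tissues stays inside [min c, max c]
  set.seed(9)
  for (i in 1:20) {
    f <- runif(4); f <- f / sum(f)
    cs <- runif(4, 1.31, 3.62)
    out <- composite_specific_heat(data.frame(fraction = f, c = cs))
    expect_gte(out, min(cs)); expect_lte(out, max(cs))
  }
})

test_that("per-stride temperature change has the right magnitude and sign", {
  p <- ref_thermo()
  expect_equal(stride_delta_T(p), 0.0034 / (1.17 * 1.96))
  expect_equal(stride_delta_T(p), 1.4827e-3, tolerance = 1e-4)
  p0 <- thermo_params(0, 1.17, 1.96, 1674, 30)
  expect_equal(stride_delta_T(p0), 0)
  # positive net work (net generation) cools in this convention
  pu <- thermo_params(0.00023, 1.17, 1.96, 1674, 30)
  expect_lt(stride_delta_T(pu), 0)
})

test_that("mechanical curve equals a stride-by-stride accumulation oracle", {
  p <- ref_thermo()
  sched <- stride_schedule(1674, 30, times = seq(0, 30, by = 5),
                           cumulative_strides = round(1674 * seq(0, 30, 5) / 30))
  mc <- mechanical_curve(p, sched)
  dTs <- stride_delta_T(p)
  for (k in seq_along(sched$times)) {
    acc <- 0
    for (s in seq_len(sched$cumulative_strides[k])) acc <- acc + dTs
    if (acc == 0) expect_equal(mc$dT[k], 0)
    else expect_equal(mc$dT[k], acc, tolerance = 1e-12)
  }
})

test_that("mechanical heating reaches ~2.5 degC over the walk and scales linearly", {
  p <- ref_thermo()
  mc <- mechanical_curve(p)
  final <- mc$dT[length(mc$dT)]
  expect_equal(final, 0.0034 * 1674 / (1.17 * 1.96), tolerance = 1e-12)
  expect_equal(final, 2.5, tolerance = 0.05)
  expect_equal(mc$dT[1], 0)
  # constant cadence: halfway in time is exactly half the heating
  expect_equal(mc$dT[mc$times == 15], final / 2)
  # zero strides
  expect_equal(mechanical_curve(thermo_params(-0.0034, 1.17, 1.96, 0, 30))$dT,
               rep(0, 7))
  # linear in |W| and inverse in m*c
  p2 <- thermo_params(-0.0068, 1.17, 1.96, 1674, 30)
  expect_equal(mechanical_curve(p2)$dT, 2 * mc$dT, tolerance = 1e-12)
  p3 <- thermo_params(-0.0034, 2 * 1.17, 1.96, 1674, 30)
  expect_equal(mechanical_curve(p3)$dT, mc$dT / 2, tolerance = 1e-12)
})

test_that("bound envelopes bracket the mean curve and hit the hand-computed extremes", {
  p <- ref_thermo()
  env <- mechanical_envelope(p)
  mc <- mechanical_curve(p)
  for (nm in c("work", "specific_heat")) {
    expect_true(all(env[[nm]]$lower$dT <= mc$dT + 1e-12))
    expect_true(all(env[[nm]]$upper$dT >= mc$dT - 1e-12))
  }
  # most negative work bound: 0.0071*1674/(1.17*1.96) ~ 5.18 degC
  expect_equal(env$work$upper$dT[7], 0.0071 * 1674 / (1.17 * 1.96))
  expect_equal(env$work$upper$dT[7], 5.18, tolerance = 0.01)
  # least negative (positive) bound cools slightly
  expect_lt(env$work$lower$dT[7], 0)
  # degenerate bounds collapse onto the mean curve
  pc <- thermo_params(-0.0034, 1.17, 1.96, 1674, 30,
                      W_bounds = c(-0.0034, -0.0034))
  envc <- mechanical_envelope(pc)
  expect_equal(envc$work$lower$dT, mc$dT)
  expect_equal(envc$work$upper$dT, mc$dT)
  expect_error(mechanical_envelope(thermo_params(-0.0034, 1.17, 1.96, 1674,
                                                 30)), "bounds")
})

test_that("decomposition conserves the experimental curve exactly", {
  set.seed(13)
  for (i in 1:10) {
    times <- seq(0, 30, by = 5)
    dT_exp <- c(0, cumsum(runif(6, 0, 1)))
    p <- thermo_params(-runif(1, 0.001, 0.01), 1.17, 1.96, 1674, 30)
    mech <- mechanical_curve(p, stride_schedule(1674, 30, times))
    dec <- decompose_series(data.frame(time_min = times, delta_C = dT_exp),
                            mech)
    expect_lt(max(abs(dec$table$dT_phys + dec$table$dT_mech -
                        dec$table$dT_exp)), 1e-12)
    expect_identical(dec$table$dT_exp[1], 0)
    expect_identical(dec$table$dT_mech[1], 0)
  }
})

test_that("decomposition handles identity, envelopes and grid mismatches", {
  times <- seq(0, 30, by = 5)
  p <- ref_thermo()
  mech <- mechanical_curve(p, stride_schedule(1674, 30, times))
  # mech == exp -> phys identically zero
  dec0 <- decompose_series(data.frame(time_min = times, delta_C = mech$dT),
                           mech)
  expect_equal(dec0$table$dT_phys, rep(0, 7))
  # envelope propagation: wider mechanical heating leaves less physiology
  env <- mechanical_envelope(p, stride_schedule(1674, 30, times))
  dec <- decompose_series(data.frame(time_min = times,
                                     delta_C = seq(0, 3.5, length.out = 7)),
                          mech, envelope = env)
  expect_true(all(dec$table$phys_low_work <= dec$table$dT_phys + 1e-12))
  expect_true(all(dec$table$phys_high_work >= dec$table$dT_phys - 1e-12))
  expect_true(all(c("phys_low_c", "phys_high_c") %in% names(dec$table)))
  # mismatched grids: error unless interpolation is requested
  mech2 <- mechanical_curve(p, stride_schedule(1674, 30, seq(0, 30, by = 10)))
  exp_df <- data.frame(time_min = times, delta_C = seq(0, 3.5, length.out = 7))
  expect_error(decompose_series(exp_df, mech2), "interpolate")
  dec2 <- decompose_series(exp_df, mech2, interpolate = TRUE)
  expect_equal(dec2$table$dT_mech, mech$dT, tolerance = 1e-12)  # linear curve
})

test_that("burn-time extrapolation covers thresholds, degenerate cases and both modes", {
  rate <- 2.4819 / 30
  bt <- burn_time(30, rate)
  expect_equal(bt$time_min, (43.3 - 30) / rate)
  expect_equal(bt$time_min, 160.8, tolerance = 0.5)
  expect_equal(burn_time(43.3, rate)$time_min, 0)
  expect_equal(burn_time(45, rate)$time_min, 0)
  expect_true(is.infinite(burn_time(30, 0)$time_min))
  expect_true(is.infinite(burn_time(30, -0.01)$time_min))
  # follow the measured curve first, then extrapolate mechanically
  curve <- data.frame(time_min = seq(0, 30, 5),
                      temp_C = 30 + seq(0, 3.5, length.out = 7))
  bt2 <- burn_time(30, rate, mode = "experimental_then_mechanical",
                   exp_curve = curve)
  expect_equal(bt2$time_min, 30 + (43.3 - 33.5) / rate)
  expect_error(burn_time(30, rate, mode = "experimental_then_mechanical"),
               "exp_curve")
})

test_that("burn time decreases in heating rate and in baseline", {
  rates <- seq(0.02, 0.2, by = 0.02)
  times <- vapply(rates, function(r) burn_time(30, r)$time_min, numeric(1))
  expect_true(all(diff(times) < 0))
  bases <- seq(28, 43, by = 1)
  times2 <- vapply(bases, function(b) burn_time(b, 0.08)$time_min, numeric(1))
  expect_true(all(diff(times2) < 0))
})

test_that("walking distance conversion is exact", {
  expect_equal(walk_distance_km(160), 12)
  expect_equal(walk_distance_km(77.5), 5.8125)
  expect_equal(walk_distance_km(60, speed_m_s = 1), 3.6)
  expect_error(walk_distance_km(10, speed_m_s = 0), "> 0")
})
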