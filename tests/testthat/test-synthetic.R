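test_that("oxygen generator follows the closed-form relaxation and is seeded", {
  g <- default_geometry()
  # alpha chosen as 0.01 min^-1 via the baseline channel only
  s <- gen_oxygen_experiment(0, true_D_B_cm3_min = 1, g,
                             schedule_min = c(0, 100), c_D = 8, c_R0 = 0,
                             noise_rel = 0, seed = 1)
  expect_equal(s$c_R[2], 8 * (1 - exp(-1)), tolerance = 1e-12)  # 5.0570

  # equilibrium: nothing moves when both transport paths are off
  eq <- gen_oxygen_experiment(0, 0, g, c_D = 8, c_R0 = 8, noise_rel = 0,
                              seed = 1)
  expect_true(all(eq$c_R == 8))

  a <- gen_oxygen_experiment(1e-6, 0.02, g, seed = 7)
  b <- gen_oxygen_experiment(1e-6, 0.02, g, seed = 7)
  expect_identical(a$c_R, b$c_R)
  expect_error(gen_oxygen_experiment(1e-6, 0.02, g, noise_rel = -1, seed = 1),
               ">= 0")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_oxygen_experiment(1e-6, 0.02, default_geometry(), seed = 5))
  invisible(gen_amide3_spectrum(beta_fraction = 0.4, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("stopper generator approaches c_D log-linearly at rate D_B/V_R", {
  g <- default_geometry()
  s <- gen_stopper_experiment(0.2, g, noise_rel = 0, seed = 3)
  # ln(c_D - c_R) linear with slope -D_B/V_R = -0.002
  slope <- coef(lm(log(s$c_D - s$c_R) ~ s$t_min))[[2]]
  expect_equal(slope, -0.002, tolerance = 1e-9)
  flat <- gen_stopper_experiment(0, g, noise_rel = 0, seed = 3)
  expect_true(all(flat$c_R == flat$c_R[1]))
})

test_that("cup generator gains weight linearly at wvtr * area", {
  cup <- gen_cup_series(0, seed = 1)
  expect_true(all(cup$weight_g == cup$weight_g[1]))
  # 0.001 g/h over a 14 mm opening corresponds to 1.804e-3 g m^-2 s^-1
  wvtr <- (0.001 / 3600) / 1.5394e-4
  cup <- gen_cup_series(wvtr, area_m2 = 1.5394e-4, schedule_h = 0:6,
                        seed = 1)
  expect_equal(diff(cup$weight_g), rep(0.001, 6), tolerance = 1e-9)
  expect_identical(gen_cup_series(wvtr, seed = 2)$weight_g,
                   gen_cup_series(wvtr, seed = 2)$weight_g)
})

test_that("amide spectrum generator records its ground-truth beta fraction", {
  # one beta band only
  areas <- c(1, rep(0, 11))
  s <- gen_amide3_spectrum(areas = areas, noise_sd = 0, seed = 1)
  expect_equal(attr(s, "true_beta_fraction"), 1)
  # 12 equal areas, 3 of them beta under the default layout
  s <- gen_amide3_spectrum(areas = rep(1, 12), noise_sd = 0, seed = 1)
  expect_equal(attr(s, "true_beta_fraction"), 3 / 12)
  s <- gen_amide3_spectrum(beta_fraction = 0.58, noise_sd = 0, seed = 1)
  expect_equal(attr(s, "true_beta_fraction"), 0.58, tolerance = 1e-12)
  expect_error(gen_amide3_spectrum(areas = rep(1, 12),
                                   centers = rep(1100, 12), seed = 1),
               "1200-1350")
})

test_that("dehydration generator approaches its equilibrium weight", {
  s <- gen_dehydration_series(w0_g = 20, k_per_day = 0, noise_sd_g = 0,
                              seed = 1)
  expect_true(all(s$w_g == 20))
  s <- gen_dehydration_series(w0_g = 20, k_per_day = 5, w_eq_fraction = 0.25,
                              noise_sd_g = 0, seed = 1)
  expect_equal(s$w_g[s$day == 14], 5, tolerance = 1e-6)
  expect_equal(weight_loss_fraction(s, 14), 0.75, tolerance = 1e-6)
})

test_that("headspace schedule follows the stated sampling cadence", {
  sch <- default_headspace_schedule()
  expect_equal(sch[1], 0)
  expect_equal(max(sch), 36)
  expect_true(all(diff(sch) > 0))
  # every 30 min over the first 5 h
  expect_equal(sch[sch > 0 & sch <= 5], seq(0.5, 5, by = 0.5))
  # 90-min cadence up to the 12th hour
  expect_equal(sch[sch > 5 & sch <= 12], c(6.5, 8, 9.5, 11, 12))
  # 180-min cadence for the remaining 24 h
  expect_equal(sch[sch > 12], seq(15, 36, by = 3))
  expect_length(sch, 24)
})

test_that("headspace generator accumulates CO2 linearly", {
  s <- gen_headspace_series(0, noise_sd_pct = 0, co2_0_pct = 0, seed = 1)
  expect_true(all(s$co2_pct == 0))
  s <- gen_headspace_series(18, mass_kg = 0.1, headspace_ml = 900,
                            schedule_h = c(0, 6), co2_0_pct = 0,
                            noise_sd_pct = 0, seed = 1)
  expect_equal(diff(s$co2_pct), 1.2)  # 100*18*0.1*6/900
})

test_that("puncture generator peaks where told and is reproducible", {
  p <- gen_puncture_curve(4.2, peak_depth_mm = 6, noise_sd_n = 0, seed = 1)
  expect_equal(max_penetration_force(p), 4.2, tolerance = 1e-9)
  expect_equal(p$displacement_mm[which.max(p$force_n)], 6)
  # peak beyond the probe travel: recorded maximum stays below it
  p2 <- gen_puncture_curve(4.2, peak_depth_mm = 12, length_mm = 8,
                           noise_sd_n = 0, seed = 1)
  expect_lt(max_penetration_force(p2), 4.2)
  expect_identical(gen_puncture_curve(3, noise_sd_n = 0.1, seed = 4)$force_n,
                   gen_puncture_curve(3, noise_sd_n = 0.1, seed = 4)$force_n)
})

test_that("noiseless generator outputs are recovered exactly by the estimators", {
  g <- default_geometry()
  fx <- oxygen_fixture(1e-6, noise_rel = 0, seed = 3)
  fit <- analyze_film(fx$reps, fx$stopper, g)
  expect_equal(fit$D_eM_cm2_s, 1e-6, tolerance = 1e-6)

  cup <- gen_cup_series(5e-3, seed = 2)
  expect_equal(fit_wvp(cup)$wvtr_g_m2_s, 5e-3, tolerance = 1e-6)

  hs <- gen_headspace_series(18, noise_sd_pct = 0, seed = 2)
  expect_equal(respiration_rate(hs), 18, tolerance = 1e-6)
})

test_that("scenario conditions map annealing to beta-sheet content with
           decreasing transport truths", {
  sc <- scenario_conditions()
  expect_equal(sc$annealing_h, c(0, 1, 6, 12))
  expect_equal(sc$beta_sheet_pct, c(23, 36, 48, 58))
  expect_true(all(diff(sc$true_D_eM_cm2_s) < 0))
  expect_true(all(diff(sc$true_wvp_g_m_s_pa) < 0))
  expect_equal(sc$true_D_eM_cm2_s[4] / sc$true_D_eM_cm2_s[1], 0.01,
               tolerance = 1e-12)
  expect_equal(sc$true_wvp_g_m_s_pa[2:4], unname(wvp_fixture),
               tolerance = 1e-12)
})
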