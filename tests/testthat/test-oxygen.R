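test_that("model_rhs reduces to the combined first-order law", {
  g <- default_geometry()
  expect_equal(model_rhs(8, 8, d_eM = 1e-3, d_B = 0.5, g), 0)  # equilibrium
  expect_equal(model_rhs(3, 8, d_eM = 0, d_B = 0, g), 0)
  # A_M * D_eM / (l * V_R) with unit deficit
  expect_equal(model_rhs(0, 1, d_eM = 2.727e-3, d_B = 0, g),
               2.75 * 2.727e-3 / (0.0075 * 100), tolerance = 1e-12)
  expect_equal(model_rhs(0, 1, d_eM = 2.727e-3, d_B = 0, g), 0.01,
               tolerance = 1e-3)
  expect_error(chamber_geometry(-1, 75, 100), "positive")
  expect_error(model_rhs(0, 1, d_eM = -1, d_B = 0, g), ">= 0")
})

test_that("closed form satisfies initial condition and flat limits", {
  expect_equal(solve_closed_form(0, c_R0 = 2, c_D = 8, alpha = 0.05), 2)
  expect_equal(solve_closed_form(c(10, 100), c_R0 = 2, c_D = 8, alpha = 0),
               c(2, 2))
  expect_equal(solve_closed_form(100, 0, 8, 0.01), 8 * (1 - exp(-1)),
               tolerance = 1e-12)
})

test_that("closed form is consistent with the ODE right-hand side", {
  # central-difference derivative of the closed form against model_rhs on a
  # 1000-point grid, and against an independent lsoda integration
  g <- default_geometry()
  d_eM <- 2e-3; d_B <- 0.2
  alpha <- g$k_M * d_eM + d_B / g$V_R
  tt <- seq(0, 360, length.out = 1000)
  h <- 1e-3
  num <- (solve_closed_form(tt + h, 0, 8, alpha) -
            solve_closed_form(tt - h, 0, 8, alpha)) / (2 * h)
  rhs <- model_rhs(solve_closed_form(tt, 0, 8, alpha), 8, d_eM, d_B, g)
  expect_lt(max(abs(num - rhs) / abs(rhs)), 1e-6)

  skip_if_not_installed("deSolve")
  sol <- deSolve::lsoda(
    y = c(c = 0), times = seq(0, 360, by = 30),
    func = function(t, y, p) list(model_rhs(y[["c"]], 8, d_eM, d_B, g)),
    rtol = 1e-10, atol = 1e-12)
  expect_equal(sol[, "c"], solve_closed_form(sol[, "time"], 0, 8, alpha),
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("diffusion-factor fit recovers alpha exactly from noiseless data", {
  tt <- seq(0, 360, by = 10)
  s <- oxygen_series(tt, solve_closed_form(tt, 0, 8, 0.02), c_D = 8)
  fit <- fit_diffusion_factor(s)
  expect_equal(fit$alpha, 0.02, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_excluded, 0)
})

test_that("degenerate concentration records are handled per policy", {
  # constant record below c_D: alpha = 0
  s <- oxygen_series(seq(0, 50, 10), rep(3, 6), c_D = 8)
  expect_equal(fit_diffusion_factor(s)$alpha, 0)
  # saturated record: no usable deficit
  sat <- oxygen_series(seq(0, 50, 10), rep(8, 6), c_D = 8)
  expect_error(fit_diffusion_factor(sat), "insufficient")
  # overshoot points are excluded and counted, not fatal
  c_R <- solve_closed_form(seq(0, 360, 10), 0, 8, 0.02)
  c_R[15] <- 8.2
  mixed <- oxygen_series(seq(0, 360, 10), c_R, c_D = 8)
  fit <- fit_diffusion_factor(mixed)
  expect_equal(fit$n_excluded, 1)
  expect_equal(fit$alpha, 0.02, tolerance = 1e-6)
})

test_that("baseline factor is the stopper rate scaled by chamber volume", {
  g <- default_geometry()
  tt <- seq(0, 360, by = 10)
  s <- oxygen_series(tt, solve_closed_form(tt, 0, 8, 0.002), c_D = 8,
                     replicate_id = "stopper")
  b <- baseline_factor(s, g)
  expect_equal(b$alpha_rs, 0.002, tolerance = 1e-10)
  expect_equal(b$D_B, 0.2, tolerance = 1e-9)
  flat <- oxygen_series(seq(0, 50, 10), rep(0, 6), c_D = 8)
  expect_equal(baseline_factor(flat, g)$D_B, 0)
})

test_that("baseline D_B recovers within 5% under 1% sensor noise", {
  g <- default_geometry()
  s <- gen_stopper_experiment(0.2, g, noise_rel = 0.01, seed = 11)
  expect_equal(baseline_factor(s, g)$D_B, 0.2, tolerance = 0.05)
})

test_that("effective diffusivity applies the cell constant and clips below baseline", {
  g <- default_geometry()
  r <- effective_diffusivity(0.012, 0.002, g)
  expect_equal(r$D_eM_cm2_min, (0.01 * 100 * 0.0075) / 2.75, tolerance = 1e-12)
  expect_equal(r$D_eM_cm2_s, 4.545e-5, tolerance = 1e-3)
  expect_false(r$below_baseline)
  z <- effective_diffusivity(0.002, 0.002, g)
  expect_equal(z$D_eM_cm2_s, 0)
  expect_true(z$below_baseline)
  neg <- effective_diffusivity(0.001, 0.002, g)
  expect_equal(neg$D_eM_cm2_s, 0)
  expect_true(neg$below_baseline)
})

test_that("analyze_film averages replicates and propagates unusable ones", {
  g <- default_geometry()
  tt <- seq(0, 360, by = 10)
  mk <- function(alpha, id) {
    oxygen_series(tt, solve_closed_form(tt, 0, 8, alpha), c_D = 8,
                  replicate_id = id)
  }
  stopper <- mk(0.002, "stopper")
  fit <- analyze_film(list(mk(0.010, "a"), mk(0.012, "b"), mk(0.014, "c")),
                      stopper, g)
  expect_equal(fit$alpha_mean, 0.012, tolerance = 1e-10)
  expect_equal(fit$n_replicates, 3)
  # identical replicates: zero spread
  same <- analyze_film(list(mk(0.012, "a"), mk(0.012, "b"), mk(0.012, "c")),
                       stopper, g)
  expect_equal(same$alpha_sd, 0, tolerance = 1e-12)
  # one saturated replicate is dropped with a warning, the rest are used
  bad <- oxygen_series(seq(0, 50, 10), rep(8, 6), c_D = 8)
  expect_warning(
    part <- analyze_film(list(mk(0.010, "a"), bad, mk(0.014, "c")),
                         stopper, g),
    "unusable")
  expect_equal(part$n_replicates, 2)
  expect_equal(part$alpha_mean, 0.012, tolerance = 1e-10)
})

test_that("oxygen_fit methods expose coefficients and predictions", {
  fx <- oxygen_fixture(1e-6, noise_rel = 0, seed = 5)
  fit <- analyze_film(fx$reps, fx$stopper, default_geometry())
  co <- coef(fit)
  expect_named(co, c("alpha_per_min", "alpha_rs_per_min", "D_B_cm3_per_min",
                     "D_eM_cm2_s"))
  expect_equal(predict(fit, 0), 0)
  expect_equal(predict(fit, 1e6), fit$c_D, tolerance = 1e-4)
  expect_output(print(summary(fit)), "Per-replicate")
})

test_that("recovered D_eM increases strictly with true D_eM over the scenario set", {
  g <- default_geometry()
  sc <- scenario_conditions()
  rec <- vapply(seq_len(nrow(sc)), function(i) {
    fx <- oxygen_fixture(sc$true_D_eM_cm2_s[i], D_B = sc$true_D_B_cm3_min[i],
                         noise_rel = 0.01, seed = 40 + i)
    analyze_film(fx$reps, fx$stopper, g)$D_eM_cm2_s
  }, 0)
  expect_true(all(diff(rec[order(sc$true_D_eM_cm2_s)]) > 0))
})
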