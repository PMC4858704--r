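# Seeded synthetic-instrument generators. Each generator is a pure function
# of its parameters and an explicit seed (scoped with withr, never touching
# the caller's RNG state) and, at zero noise, satisfies the corresponding
# estimator's model exactly, so every estimator is testable by parameter
# recovery with known ground truth.

with_seed_ <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) stop("a seed is required", call. = FALSE)
  withr::with_seed(as.integer(seed), expr)
}

check_noise <- function(noise) {
  if (noise < 0) stop("noise sd must be >= 0", call. = FALSE)
  noise
}

#' Simulate a two-chamber oxygen permeation run
#'
#' Receiving-chamber concentration following the closed-form first-order
#' relaxation for the given true film diffusivity and rig baseline, with
#' multiplicative Gaussian sensor noise (optical oxygen sensors have
#' reading-proportional error). Default schedule: 10-minute sampling over
#' 6 h.
#'
#' @param true_D_eM_cm2_s True effective membrane diffusivity, cm^2/s.
#' @param true_D_B_cm3_min True baseline volumetric diffusion factor,
#'   cm^3/min.
#' @param geometry A [chamber_geometry()].
#' @param schedule_min Sampling times, minutes.
#' @param c_D Donor concentration, mg/L (default 8, air-saturated water at
#'   22 C).
#' @param c_R0 Initial receiving concentration, mg/L.
#' @param noise_rel Relative (multiplicative) sensor noise sd (default 0.01).
#' @param seed RNG seed (required).
#' @param replicate_id Replicate label.
#' @return An [oxygen_series()] with attribute `true_alpha` (min^-1).
#' @export
#' @examples
#' g <- chamber_geometry()
#' s <- gen_oxygen_experiment(1e-6, 0.02, g, noise_rel = 0, seed = 1)
#' fit_diffusion_factor(s)$alpha - attr(s, "true_alpha")  # ~0
gen_oxygen_experiment <- function(true_D_eM_cm2_s, true_D_B_cm3_min, geometry,
                                  schedule_min = seq(0, 360, by = 10),
                                  c_D = 8, c_R0 = 0, noise_rel = 0.01,
                                  seed, replicate_id = NA_character_) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (true_D_eM_cm2_s < 0 || true_D_B_cm3_min < 0) {
    stop("true rates must be >= 0", call. = FALSE)
  }
  check_noise(noise_rel)
  if (length(schedule_min) < 2) stop("schedule must have >= 2 times", call. = FALSE)
  d_min <- convert_unit(true_D_eM_cm2_s, "cm2/s", "cm2/min")
  alpha <- geometry$k_M * d_min + true_D_B_cm3_min / geometry$V_R
  c_true <- solve_closed_form(schedule_min, c_R0 = c_R0, c_D = c_D,
                              alpha = alpha)
  c_obs <- with_seed_(seed, {
    c_true * (1 + stats::rnorm(length(c_true), sd = noise_rel))
  })
  out <- oxygen_series(schedule_min, pmax(c_obs, 0), c_D = c_D,
                       replicate_id = replicate_id)
  attr(out, "true_alpha") <- alpha
  out
}

#' Simulate a rubber-stopper baseline run
#'
#' Same rig and noise model as [gen_oxygen_experiment()] with the membrane
#' term forced to zero: only the rig's baseline leak (`D_B`) moves the
#' receiving chamber.
#'
#' @inheritParams gen_oxygen_experiment
#' @return An [oxygen_series()] with attribute `true_alpha` (= D_B / V_R).
#' @export
gen_stopper_experiment <- function(true_D_B_cm3_min, geometry,
                                   schedule_min = seq(0, 360, by = 10),
                                   c_D = 8, c_R0 = 0, noise_rel = 0.01,
                                   seed, replicate_id = "stopper") {
  gen_oxygen_experiment(0, true_D_B_cm3_min, geometry,
                        schedule_min = schedule_min, c_D = c_D, c_R0 = c_R0,
                        noise_rel = noise_rel, seed = seed,
                        replicate_id = replicate_id)
}

#' Simulate a desiccant-cup weighing series
#'
#' Cup weight grows linearly at `true_wvtr * area`; additive Gaussian
#' balance noise. The default noise is expressed per weighing as an absolute
#' sd in grams.
#'
#' @param true_wvtr_g_m2_s True water vapour transmission rate, g m^-2 s^-1.
#' @param area_m2 Opening area, m^2 (default Ø 14 mm).
#' @param schedule_h Weighing times, hours (default every 12 h to 72 h).
#' @param w0_g Initial cup weight, g.
#' @param noise_sd_g Balance noise sd, g (default 0: exact).
#' @param thickness_m,rh_out,rh_in,s_pa Film/boundary metadata passed to
#'   [cup_experiment()].
#' @param seed RNG seed (required).
#' @param replicate_id Replicate label.
#' @return A [cup_experiment()] with attribute `true_wvtr_g_m2_s`.
#' @export
gen_cup_series <- function(true_wvtr_g_m2_s, area_m2 = 1.5394e-4,
                           schedule_h = seq(0, 72, by = 12), w0_g = 20,
                           noise_sd_g = 0, thickness_m = 75e-6,
                           rh_out = 75, rh_in = 0, s_pa = 2645,
                           seed, replicate_id = NA_character_) {
  if (true_wvtr_g_m2_s < 0) stop("true_wvtr must be >= 0", call. = FALSE)
  check_noise(noise_sd_g)
  gain_g_h <- convert_unit(true_wvtr_g_m2_s, "g/m2/s", "g/m2/h") * area_m2
  w <- w0_g + gain_g_h * schedule_h
  w <- with_seed_(seed, w + stats::rnorm(length(w), sd = noise_sd_g))
  out <- cup_experiment(schedule_h, w, area_m2 = area_m2,
                        thickness_m = thickness_m, rh_out = rh_out,
                        rh_in = rh_in, s_pa = s_pa,
                        replicate_id = replicate_id)
  attr(out, "true_wvtr_g_m2_s") <- true_wvtr_g_m2_s
  out
}

#' Default Amide III band layout for synthetic spectra
#'
#' Twelve band centers: three beta-sheet bands well inside the 1216-1250
#' cm^-1 assignment window and nine bands spread over the rest of the Amide
#' III region, all far enough from the 1200/1350 cm^-1 edges that the
#' endpoint-anchored baseline sees near-zero absorbance there.
#'
#' @return List with `centers` (cm^-1), `sigmas` (cm^-1) and logical
#'   `is_beta`.
#' @export
amide3_band_layout <- function() {
  centers <- c(1225, 1235, 1245,
               1258, 1267, 1276, 1285, 1294, 1303, 1312, 1321, 1330)
  list(centers = centers,
       sigmas = rep(5, 12),
       is_beta = c(rep(TRUE, 3), rep(FALSE, 9)))
}

#' Simulate an Amide III spectrum with known beta-sheet fraction
#'
#' Sum of 12 Gaussian bands on a wavenumber grid, plus an optional linear
#' baseline and additive Gaussian noise. Either pass explicit band
#' parameters or just `beta_fraction`, in which case the default
#' [amide3_band_layout()] is used with the beta-band areas summing to
#' `beta_fraction` (equal split within each group). Ground truth is recorded
#' as attribute `true_beta_fraction`.
#'
#' @param beta_fraction Target beta-sheet area fraction in [0, 1]
#'   (used when `areas` is NULL).
#' @param centers,sigmas,areas Optional explicit 12-band parameters
#'   (centers within 1200-1350 cm^-1, areas >= 0).
#' @param is_beta Logical length-12 assignment (which bands count as beta).
#' @param grid Wavenumber grid, cm^-1.
#' @param baseline Length-2 `c(intercept, slope)` of an additive linear
#'   baseline (absorbance units; slope per cm^-1).
#' @param noise_sd Additive noise sd as a fraction of the peak absorbance
#'   (default 0).
#' @param seed RNG seed (required).
#' @return An [ftir_spectrum()] with attributes `true_beta_fraction` and
#'   `true_bands`.
#' @export
#' @examples
#' s <- gen_amide3_spectrum(beta_fraction = 0.58, noise_sd = 0.01, seed = 7)
#' attr(s, "true_beta_fraction")
gen_amide3_spectrum <- function(beta_fraction = NULL, centers = NULL,
                                sigmas = NULL, areas = NULL, is_beta = NULL,
                                grid = seq(1200, 1350, by = 0.5),
                                baseline = c(0, 0), noise_sd = 0, seed) {
  check_noise(noise_sd)
  lay <- amide3_band_layout()
  if (is.null(centers)) centers <- lay$centers
  if (is.null(sigmas)) sigmas <- lay$sigmas
  if (is.null(is_beta)) is_beta <- lay$is_beta
  if (is.null(areas)) {
    if (is.null(beta_fraction)) {
      stop("give either areas or beta_fraction", call. = FALSE)
    }
    if (beta_fraction < 0 || beta_fraction > 1) {
      stop("beta_fraction must lie in [0, 1]", call. = FALSE)
    }
    areas <- numeric(12)
    areas[is_beta] <- beta_fraction / sum(is_beta)
    areas[!is_beta] <- (1 - beta_fraction) / sum(!is_beta)
  }
  if (length(centers) != 12 || length(sigmas) != 12 || length(areas) != 12 ||
      length(is_beta) != 12) {
    stop("band parameters must have length 12", call. = FALSE)
  }
  if (any(centers < 1200 | centers > 1350)) {
    stop("band centers must lie inside 1200-1350 cm^-1", call. = FALSE)
  }
  if (any(areas < 0)) stop("areas must be >= 0", call. = FALSE)
  amps <- areas / (sigmas * sqrt(2 * pi))
  y <- gaussian_mix(grid, centers, sigmas, amps) +
    baseline[1] + baseline[2] * (grid - grid[1])
  peak <- max(abs(y))
  y <- with_seed_(seed, y + stats::rnorm(length(y), sd = noise_sd * peak))
  out <- ftir_spectrum(grid, y)
  total <- sum(areas)
  attr(out, "true_beta_fraction") <-
    if (total > 0) sum(areas[is_beta]) / total else NA_real_
  attr(out, "true_bands") <- data.frame(center = centers, sigma = sigmas,
                                        area = areas, is_beta = is_beta)
  out
}

#' Simulate a gravimetric dehydration series
#'
#' First-order approach of berry weight to an equilibrium value:
#' `w(t) = w_eq + (w0 - w_eq) * exp(-k t)` with `w_eq = w_eq_fraction * w0`
#' (the paper reports only empirical curves; the exponential form is this
#' generator's modelling choice). Additive balance noise.
#'
#' @param w0_g Initial berry weight, g.
#' @param k_per_day First-order dehydration rate, day^-1.
#' @param w_eq_fraction Equilibrium weight as a fraction of `w0_g`
#'   (default 0.25).
#' @param days Sampling days (default `c(0, 1, 3, 5, 7, 14)`).
#' @param noise_sd_g Balance noise sd, g.
#' @param seed RNG seed (required).
#' @param replicate_id Replicate label.
#' @return A `weight_series` (see [weight_series()]) with attribute
#'   `true_k_per_day`.
#' @export
gen_dehydration_series <- function(w0_g = 20, k_per_day,
                                   w_eq_fraction = 0.25,
                                   days = c(0, 1, 3, 5, 7, 14),
                                   noise_sd_g = 0, seed,
                                   replicate_id = NA_character_) {
  if (w0_g <= 0) stop("w0_g must be positive", call. = FALSE)
  if (k_per_day < 0) stop("k_per_day must be >= 0", call. = FALSE)
  check_noise(noise_sd_g)
  w_eq <- w_eq_fraction * w0_g
  w <- w_eq + (w0_g - w_eq) * exp(-k_per_day * days)
  w <- with_seed_(seed, w + stats::rnorm(length(w), sd = noise_sd_g))
  out <- weight_series(days, pmax(w, 0), w0_g = w0_g,
                       replicate_id = replicate_id)
  attr(out, "true_k_per_day") <- k_per_day
  out
}

#' Default headspace sampling schedule
#'
#' Gas sampling every 30 min for the first 5 h, every 90 min till the 12th
#' hour (including the hour-12 boundary sample), and every 180 min for the
#' remaining 24 h of a 36-h run, plus the t = 0 reading.
#'
#' @return Sampling times in hours.
#' @export
default_headspace_schedule <- function() {
  c(0, seq(0.5, 5, by = 0.5), seq(6.5, 11, by = 1.5), 12, seq(15, 36, by = 3))
}

#' Simulate a closed-jar headspace CO2 series
#'
#' CO2 accumulates linearly in a hermetic jar from fruit respiration:
#' `CO2%(t) = co2_0 + 100 * rate * m * t / V`. Additive Gaussian analyser
#' noise.
#'
#' @param rate_ml_kg_h True respiration rate, ml CO2 kg^-1 h^-1.
#' @param mass_kg Fruit mass, kg (default 0.1).
#' @param headspace_ml Jar free volume, ml (default 900: 1 L jar with
#'   ~100 g fruit).
#' @param schedule_h Sampling times, hours (default
#'   [default_headspace_schedule()]).
#' @param co2_0_pct Initial CO2 concentration, percent (default 0.04,
#'   ambient).
#' @param noise_sd_pct Analyser noise sd, percent CO2 absolute.
#' @param seed RNG seed (required).
#' @return A [headspace_series()] with attribute `true_rate_ml_kg_h`.
#' @export
gen_headspace_series <- function(rate_ml_kg_h, mass_kg = 0.1,
                                 headspace_ml = 900,
                                 schedule_h = default_headspace_schedule(),
                                 co2_0_pct = 0.04, noise_sd_pct = 0, seed) {
  if (rate_ml_kg_h < 0) stop("rate must be >= 0", call. = FALSE)
  check_noise(noise_sd_pct)
  co2 <- co2_0_pct + 100 * rate_ml_kg_h * mass_kg * schedule_h / headspace_ml
  co2 <- with_seed_(seed, co2 + stats::rnorm(length(co2), sd = noise_sd_pct))
  out <- headspace_series(schedule_h, pmax(co2, 0), mass_kg = mass_kg,
                          headspace_ml = headspace_ml)
  attr(out, "true_rate_ml_kg_h") <- rate_ml_kg_h
  out
}

#' Simulate a puncture force-displacement curve
#'
#' Smooth unimodal curve `F(d) = peak_force * (d/peak_depth) *
#' exp(1 - d/peak_depth)`, which rises to exactly `peak_force` at
#' `peak_depth` and softens beyond it (tissue rupture), sampled on a regular
#' displacement grid with additive load-cell noise.
#'
#' @param peak_force_n Peak force, N.
#' @param peak_depth_mm Displacement of the force peak, mm (default 6).
#' @param length_mm Total recorded displacement, mm (default 8, the probe
#'   travel).
#' @param step_mm Displacement resolution, mm (default 0.05; 1 mm/s
#'   cross-head at 20 Hz).
#' @param noise_sd_n Load-cell noise sd, N.
#' @param seed RNG seed (required).
#' @return A [puncture_curve()] with attribute `true_peak_force_n`.
#' @export
gen_puncture_curve <- function(peak_force_n, peak_depth_mm = 6,
                               length_mm = 8, step_mm = 0.05,
                               noise_sd_n = 0, seed) {
  if (peak_force_n < 0) stop("peak_force must be >= 0", call. = FALSE)
  if (peak_depth_mm <= 0 || length_mm <= 0) {
    stop("depths must be positive", call. = FALSE)
  }
  check_noise(noise_sd_n)
  d <- seq(0, length_mm, by = step_mm)
  f <- peak_force_n * (d / peak_depth_mm) * exp(1 - d / peak_depth_mm)
  f <- with_seed_(seed, f + stats::rnorm(length(f), sd = noise_sd_n))
  out <- puncture_curve(d, pmax(f, 0))
  attr(out, "true_peak_force_n") <- peak_force_n
  out
}

#' Ground-truth scenario table for the four annealing conditions
#'
#' One row per water-annealing condition (0, 1, 6, 12 h) mapping to relative
#' beta-sheet contents 23, 36, 48 and 58%. Film oxygen diffusivity and WVP
#' decrease strictly with beta-sheet content: D_eM spans the stated
#' two-orders-of-magnitude decrease (ratio `d_ratio`, default 0.01, between
#' the 58% and 23% films, log-linear in beta in between); WVP anchors to the
#' measured values at 36/48/58% and extrapolates log-linearly to 23%.
#' Respiration rate, dehydration rate and day-7 firmness reflect the
#' qualitative postharvest trends (slower respiration and dehydration,
#' firmer fruit under more crystalline coatings).
#'
#' @param d_ratio D_eM(58%) / D_eM(23%) (default 0.01).
#' @param d_eM_23_cm2_s D_eM of the untreated (23%) film, cm^2/s
#'   (default 1e-5).
#' @param d_B_cm3_min Rig baseline volumetric diffusion factor, cm^3/min
#'   (default 0.02).
#' @return Data frame with one row per condition: `annealing_h`,
#'   `beta_sheet_pct`, `true_D_eM_cm2_s`, `true_wvp_g_m_s_pa`,
#'   `true_wvtr_g_m2_s`, `true_respiration_ml_kg_h`, `true_k_per_day`,
#'   `true_firmness_n`, `true_D_B_cm3_min`.
#' @export
#' @examples
#' scenario_conditions()
scenario_conditions <- function(d_ratio = 0.01, d_eM_23_cm2_s = 1e-5,
                                d_B_cm3_min = 0.02) {
  if (d_ratio <= 0 || d_ratio >= 1) stop("d_ratio must lie in (0, 1)", call. = FALSE)
  beta <- c(23, 36, 48, 58)
  # measured WVP at 36/48/58% beta; 23% extrapolated on the same log-linear
  # trend in beta-sheet content
  wvp_meas <- c(7.93e-9, 5.37e-10, 6.49e-11)
  bmeas <- beta[2:4]
  co <- stats::coef(stats::lm(log10(wvp_meas) ~ bmeas))
  wvp <- c(10^(co[[1]] + co[[2]] * beta[1]), wvp_meas)
  delta_p <- 2645 * 0.75
  data.frame(
    annealing_h = c(0, 1, 6, 12),
    beta_sheet_pct = beta,
    true_D_eM_cm2_s = d_eM_23_cm2_s * d_ratio^((beta - beta[1]) /
                                                 (beta[4] - beta[1])),
    true_wvp_g_m_s_pa = unname(wvp),
    true_wvtr_g_m2_s = unname(wvp) * delta_p / 75e-6,
    true_respiration_ml_kg_h = c(22, 18, 14, 10),
    true_k_per_day = c(0.193, 0.120, 0.090, 0.070),
    true_firmness_n = c(2.0, 2.5, 3.0, 3.5),
    true_D_B_cm3_min = d_B_cm3_min
  )
}
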