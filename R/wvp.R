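# Cup-method water vapour permeability (ASTM E96 style). Desiccant inside
# the cup holds ~0 %RH, a saturated NaCl desiccator outside holds 75 %RH;
# moisture crossing the film shows up as cup weight gain. WVTR is the
# regression slope of weight on time per unit opening area, and
# WVP = WVTR * d / (S * (RH1 - RH2) / 100).

#' Desiccant-cup weighing record
#'
#' One cup experiment: weight versus time, film/cup geometry and the
#' humidity boundary conditions. The driving pressure is `S * (RH1-RH2)/100`
#' with S the saturation vapour pressure of water at the test temperature.
#'
#' @param t_h Weighing times, hours, strictly increasing.
#' @param weight_g Cup weight, g.
#' @param area_m2 Circular opening area, m^2 (default Ø 14 mm).
#' @param thickness_m Film thickness, m (default 75e-6).
#' @param rh_out Relative humidity outside the cup (desiccator), percent
#'   (default 75).
#' @param rh_in Relative humidity inside the cup, percent (default 0).
#' @param s_pa Saturation vapour pressure, Pa (default 2645 at 22 C).
#' @param temperature_c Test temperature, C (metadata only).
#' @param replicate_id Replicate label.
#' @return An object of class `cup_experiment`.
#' @export
cup_experiment <- function(t_h, weight_g, area_m2 = pi * 0.007^2,
                           thickness_m = 75e-6, rh_out = 75, rh_in = 0,
                           s_pa = 2645, temperature_c = 22,
                           replicate_id = NA_character_) {
  if (area_m2 <= 0 || thickness_m <= 0 || s_pa <= 0) {
    stop("area, thickness and saturation pressure must be positive",
         call. = FALSE)
  }
  if (!(rh_in >= 0 && rh_in < rh_out && rh_out <= 100)) {
    stop("require 0 <= rh_in < rh_out <= 100", call. = FALSE)
  }
  ts <- timeseries(t_h, weight_g, t_unit = "h", y_unit = "g",
                   replicate_id = replicate_id)
  structure(
    list(t_h = convert_unit(ts$t_min, "min", "h"), weight_g = ts$y,
         area_m2 = area_m2, thickness_m = thickness_m,
         rh_out = rh_out, rh_in = rh_in, s_pa = s_pa,
         temperature_c = temperature_c, replicate_id = ts$replicate_id),
    class = "cup_experiment"
  )
}

#' @export
print.cup_experiment <- function(x, ...) {
  cat(sprintf(
    "Cup experiment: %d weighings over %g h, A = %.4g m^2, d = %g um, RH %g%% -> %g%%\n",
    length(x$t_h), max(x$t_h), x$area_m2, x$thickness_m * 1e6,
    x$rh_out, x$rh_in))
  invisible(x)
}

#' Water vapour transmission rate from a cup record
#'
#' OLS slope of weight on time, divided by the opening area and converted to
#' g m^-2 s^-1. Weight gain (desiccant in the cup) is the normal direction; a
#' negative slope (inverted/evaporation cup) is taken by absolute value with
#' `direction = "loss"`. A quality gate flags regressions with r^2 <= 0.98,
#' the linearity threshold used for accepting cup runs.
#'
#' @param cup A [cup_experiment()] (>= 3 weighings).
#' @return List with `wvtr_g_m2_s`, `slope_g_h`, `r_squared`, `direction`
#'   and `quality_flag` (TRUE when r^2 <= 0.98).
#' @export
#' @examples
#' cup <- cup_experiment(0:5, 20 + 0.001 * 0:5, area_m2 = 1.5394e-4)
#' fit_wvtr(cup)$wvtr_g_m2_s  # (0.001/3600)/1.5394e-4 = 1.804e-3
fit_wvtr <- function(cup) {
  stopifnot(inherits(cup, "cup_experiment"))
  if (length(cup$t_h) < 3) {
    stop("insufficient data: at least 3 weighings required", call. = FALSE)
  }
  fit <- stats::lm(cup$weight_g ~ cup$t_h)
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cup$weight_g - mean(cup$weight_g))^2)
  r2 <- if (ss_tot < 1e-300) 0 else max(0, min(1, 1 - ss_res / ss_tot))
  wvtr <- convert_unit(abs(slope) / cup$area_m2, "g/m2/h", "g/m2/s")
  list(wvtr_g_m2_s = wvtr,
       slope_g_h = slope,
       r_squared = r2,
       direction = if (slope >= 0) "gain" else "loss",
       quality_flag = r2 <= 0.98)
}

#' Water vapour permeability from a transmission rate
#'
#' `WVP = WVTR * d / delta_p` with `delta_p = S * (RH1 - RH2) / 100` the
#' vapour-pressure difference across the film. RH values are percentages.
#' `delta_p_pa` overrides the computed driving pressure (some reports quote
#' a driving pressure that differs from S * dRH; the override reproduces
#' such values without touching the formula default).
#'
#' @param wvtr_g_m2_s Transmission rate, g m^-2 s^-1.
#' @param thickness_m Film thickness, m.
#' @param s_pa Saturation vapour pressure, Pa.
#' @param rh1 Upstream (wet side) RH, percent.
#' @param rh2 Downstream (dry side) RH, percent.
#' @param delta_p_pa Optional explicit driving pressure, Pa.
#' @return List with `wvp_g_m_s_pa`, `delta_p_pa` and the inputs.
#' @export
#' @examples
#' compute_wvp(1e-4, 75e-6, 2645, 75, 0)$wvp_g_m_s_pa  # 3.781e-12
compute_wvp <- function(wvtr_g_m2_s, thickness_m, s_pa = 2645, rh1 = 75,
                        rh2 = 0, delta_p_pa = NULL) {
  if (thickness_m <= 0 || s_pa <= 0) {
    stop("thickness and saturation pressure must be positive", call. = FALSE)
  }
  if (is.null(delta_p_pa)) {
    if (rh1 <= rh2) stop("require rh1 > rh2", call. = FALSE)
    delta_p_pa <- s_pa * (rh1 - rh2) / 100
  }
  if (delta_p_pa <= 0) stop("driving pressure must be positive", call. = FALSE)
  list(wvp_g_m_s_pa = wvtr_g_m2_s * thickness_m / delta_p_pa,
       wvtr_g_m2_s = wvtr_g_m2_s,
       thickness_m = thickness_m,
       delta_p_pa = delta_p_pa)
}

#' Fit water vapour permeability from a cup experiment
#'
#' The full cup-method estimator: [fit_wvtr()] for the transmission rate,
#' then [compute_wvp()] with the experiment's film thickness and humidity
#' boundary conditions.
#'
#' @param cup A [cup_experiment()].
#' @param delta_p_pa Optional explicit driving pressure, Pa (overrides
#'   `S * dRH / 100`).
#' @return An object of class `wvp_fit` with `wvtr_g_m2_s`, `wvp_g_m_s_pa`,
#'   `r_squared`, `delta_p_pa`, `quality_flag` and `direction`.
#' @export
#' @examples
#' cup <- gen_cup_series(5e-4, seed = 1)
#' fit <- fit_wvp(cup)
#' coef(fit)
fit_wvp <- function(cup, delta_p_pa = NULL) {
  tr <- fit_wvtr(cup)
  pv <- compute_wvp(tr$wvtr_g_m2_s, cup$thickness_m, cup$s_pa,
                    cup$rh_out, cup$rh_in, delta_p_pa = delta_p_pa)
  structure(
    c(tr[c("wvtr_g_m2_s", "slope_g_h", "r_squared", "direction",
           "quality_flag")],
      pv[c("wvp_g_m_s_pa", "delta_p_pa")],
      list(cup = cup)),
    class = "wvp_fit"
  )
}

#' @export
print.wvp_fit <- function(x, ...) {
  cat("Cup-method water vapour fit\n")
  cat(sprintf("  WVTR = %.4g g m^-2 s^-1 (r^2 = %.4f%s, %s)\n",
              x$wvtr_g_m2_s, x$r_squared,
              if (x$quality_flag) ", QUALITY FLAG: r^2 <= 0.98" else "",
              x$direction))
  cat(sprintf("  WVP  = %.4g g m^-1 s^-1 Pa^-1 (delta_p = %.2f Pa)\n",
              x$wvp_g_m_s_pa, x$delta_p_pa))
  invisible(x)
}

#' @export
coef.wvp_fit <- function(object, ...) {
  c(wvtr_g_m2_s = object$wvtr_g_m2_s,
    wvp_g_m_s_pa = object$wvp_g_m_s_pa,
    r_squared = object$r_squared,
    delta_p_pa = object$delta_p_pa)
}

#' @export
predict.wvp_fit <- function(object, t_h, ...) {
  w0 <- unname(stats::coef(stats::lm(object$cup$weight_g ~ object$cup$t_h))[1])
  w0 + object$slope_g_h * t_h
}

#' Fold change between two water vapour permeabilities
#'
#' Ratio `a / b` of two WVP values (or `wvp_fit` objects); used to express
#' how much less permeable a high-crystallinity film is than a low one.
#'
#' @param a,b WVP values (g m^-1 s^-1 Pa^-1) or `wvp_fit` objects.
#' @return The fold change `a / b`.
#' @export
#' @examples
#' wvp_ratio(7.93e-9, 6.49e-11)  # ~122
wvp_ratio <- function(a, b) {
  val <- function(x) if (inherits(x, "wvp_fit")) x$wvp_g_m_s_pa else x
  a <- val(a)
  b <- val(b)
  if (b <= 0) stop("denominator WVP must be positive", call. = FALSE)
  a / b
}
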