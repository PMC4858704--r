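# Two-chamber oxygen permeation analysis.
#
# Mass balance in the receiving chamber (well-mixed fluid, no oxygen
# consumption, linear concentration profile across the film, instantaneous
# steady state):
#
#   V_R dc_R/dt = A_M j_M + Q_B                      (chamber balance)
#   j_M  = (D_eM / l) (c_D - c_R)                    (membrane flux)
#   Q_B  = D_B (c* - c_R)                            (baseline ingress)
#
# With c* = c_D (air saturation measured in the donor chamber) these combine
# into the first-order law
#
#   dc_R/dt = alpha (c_D - c_R),  alpha = k_M D_eM + D_B / V_R,
#   k_M = A_M / (l V_R)
#
# whose integral c_R(t) = c_D - (c_D - c_R0) exp(-alpha t) makes
# ln(c_D - c_R) linear in t. alpha comes from that log-linear slope; the
# rig's leak rate alpha_rs is measured once with an impermeable rubber
# stopper in place of the film (D_eM = 0, so D_B = alpha_rs V_R), and
# D_eM = (alpha - alpha_rs) / k_M.

#' Two-chamber diffusion cell geometry
#'
#' Physical constants of the permeation rig: the circular opening between the
#' donor and receiving chambers, the mounted film thickness, and the
#' receiving-chamber volume. The derived constant `k_M = A_M / (l * V_R)`
#' (cm^-2) converts the fitted first-order rate into a diffusivity.
#'
#' @param area_cm2 Membrane opening area, cm^2 (default 2.75).
#' @param thickness_um Film thickness, micrometres (default 75, the midpoint
#'   of the 70-80 um films studied).
#' @param volume_cm3 Receiving-chamber volume, cm^3 (default 100; rig
#'   dependent, always confirm against the cell in use).
#' @return An object of class `chamber_geometry` with fields `A_M` (cm^2),
#'   `l` (cm), `V_R` (cm^3) and `k_M` (cm^-2).
#' @export
#' @examples
#' chamber_geometry()  # k_M = 2.75 / (0.0075 * 100) = 3.667 cm^-2
chamber_geometry <- function(area_cm2 = 2.75, thickness_um = 75,
                             volume_cm3 = 100) {
  if (area_cm2 <= 0 || thickness_um <= 0 || volume_cm3 <= 0) {
    stop("all geometry parameters must be strictly positive", call. = FALSE)
  }
  l_cm <- convert_unit(thickness_um, "um", "cm")
  structure(
    list(A_M = area_cm2, l = l_cm, V_R = volume_cm3,
         k_M = area_cm2 / (l_cm * volume_cm3)),
    class = "chamber_geometry"
  )
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf(
    "Diffusion cell: A_M = %g cm^2, l = %g cm, V_R = %g cm^3, k_M = %.4g cm^-2\n",
    x$A_M, x$l, x$V_R, x$k_M))
  invisible(x)
}

#' Receiving-chamber oxygen record
#'
#' Dissolved-oxygen concentration in the receiving chamber versus time, with
#' the (constant) donor concentration and the saturation concentration c*.
#' The donor chamber is large and stirred, so `c_D` is taken constant over a
#' run; c* defaults to `c_D` since the donor sits at air saturation.
#'
#' @param t_min Sampling times, minutes, strictly increasing.
#' @param c_R Receiving-chamber dissolved oxygen, mg/L, non-negative.
#' @param c_D Donor-chamber concentration, mg/L (> 0).
#' @param c_star Saturation concentration, mg/L; defaults to `c_D`.
#' @param replicate_id Replicate label.
#' @return An object of class `oxygen_series`.
#' @export
oxygen_series <- function(t_min, c_R, c_D, c_star = c_D,
                          replicate_id = NA_character_) {
  if (c_D <= 0) stop("c_D must be positive", call. = FALSE)
  if (any(c_R < 0)) stop("c_R must be non-negative", call. = FALSE)
  ts <- timeseries(t_min, c_R, t_unit = "min", y_unit = "mg/L",
                   replicate_id = replicate_id)
  structure(
    list(t_min = ts$t_min, c_R = ts$y, c_D = c_D, c_star = c_star,
         replicate_id = ts$replicate_id),
    class = "oxygen_series"
  )
}

#' @export
print.oxygen_series <- function(x, ...) {
  cat(sprintf(
    "Oxygen series: %d points over %g min, c_D = %g mg/L, final c_R = %g mg/L\n",
    length(x$t_min), max(x$t_min), x$c_D, x$c_R[length(x$c_R)]))
  invisible(x)
}

#' Right-hand side of the chamber mass balance
#'
#' Rate of change of the receiving-chamber concentration:
#' `(A_M * D_eM / (l * V_R)) * (c_D - c_R) + (D_B / V_R) * (c_star - c_R)`.
#' With `c_star = c_D` this is the combined first-order law
#' `alpha * (c_D - c_R)` with `alpha = k_M * D_eM + D_B / V_R`.
#'
#' @param c_R Receiving concentration, mg/L (vectorised).
#' @param c_D Donor concentration, mg/L.
#' @param d_eM Effective membrane diffusivity, cm^2/min.
#' @param d_B Baseline volumetric diffusion factor, cm^3/min.
#' @param geometry A [chamber_geometry()].
#' @param c_star Saturation concentration, mg/L; defaults to `c_D`.
#' @return dc_R/dt in mg L^-1 min^-1.
#' @export
#' @examples
#' g <- chamber_geometry(2.75, 75, 100)
#' model_rhs(0, 1, d_eM = 2.727e-3, d_B = 0, g)  # ~0.01 mg/L/min
model_rhs <- function(c_R, c_D, d_eM, d_B, geometry, c_star = c_D) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (d_eM < 0 || d_B < 0) stop("diffusivities must be >= 0", call. = FALSE)
  geometry$k_M * d_eM * (c_D - c_R) + (d_B / geometry$V_R) * (c_star - c_R)
}

#' Closed-form solution of the first-order permeation law
#'
#' `c_R(t) = c_D - (c_D - c_R0) * exp(-alpha * t)`: exponential relaxation of
#' the receiving chamber toward the donor concentration at the combined rate
#' `alpha = k_M * D_eM + D_B / V_R`.
#'
#' @param t_min Times, minutes (vectorised).
#' @param c_R0 Initial receiving concentration, mg/L.
#' @param c_D Donor concentration, mg/L.
#' @param alpha Diffusion factor, min^-1 (>= 0).
#' @return c_R at `t_min`, mg/L.
#' @export
#' @examples
#' solve_closed_form(100, c_R0 = 0, c_D = 8, alpha = 0.01)  # 8*(1-exp(-1))
solve_closed_form <- function(t_min, c_R0, c_D, alpha) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  c_D - (c_D - c_R0) * exp(-alpha * t_min)
}

#' Fit the diffusion factor from a concentration record
#'
#' Ordinary least squares of `ln(c_D - c_R)` on time; the diffusion factor
#' alpha is minus the slope. Points at or above the donor concentration
#' (sensor overshoot, zero deficit) are excluded rather than erroring, and
#' the exclusion count is reported. At least 4 usable points are required.
#'
#' @param series An [oxygen_series()].
#' @return An object of class `diffusion_fit`: `alpha` (min^-1),
#'   `intercept`, `r_squared`, `n_points_used`, `n_excluded`.
#' @export
fit_diffusion_factor <- function(series) {
  stopifnot(inherits(series, "oxygen_series"))
  deficit <- series$c_D - series$c_R
  keep <- deficit > 0
  n_excluded <- sum(!keep)
  if (sum(keep) < 4) {
    stop("insufficient data: fewer than 4 points with c_D - c_R > 0",
         call. = FALSE)
  }
  t <- series$t_min[keep]
  ly <- log(deficit[keep])
  if (stats::var(t) == 0) stop("zero time variance", call. = FALSE)
  fit <- stats::lm(ly ~ t)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot < 1e-300) {
    if (ss_res < 1e-12) 1 else 0   # constant record: perfect flat fit
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  structure(
    list(alpha = -unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points_used = sum(keep),
         n_excluded = n_excluded,
         replicate_id = series$replicate_id),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "Diffusion factor fit: alpha = %.4g min^-1 (r^2 = %.4f, %d points, %d excluded)\n",
    x$alpha, x$r_squared, x$n_points_used, x$n_excluded))
  invisible(x)
}

#' Rig baseline from a rubber-stopper run
#'
#' With an oxygen-impermeable stopper mounted instead of a film, the membrane
#' term vanishes (D_eM = 0) and the fitted rate is the rig's leak rate
#' alpha_rs, giving the baseline volumetric diffusion factor
#' `D_B = alpha_rs * V_R`.
#'
#' @param stopper_series An [oxygen_series()] recorded with the stopper.
#' @param geometry A [chamber_geometry()].
#' @return List with `alpha_rs` (min^-1), `D_B` (cm^3/min) and the underlying
#'   `fit`.
#' @export
baseline_factor <- function(stopper_series, geometry) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  fit <- fit_diffusion_factor(stopper_series)
  alpha_rs <- max(0, fit$alpha)
  list(alpha_rs = alpha_rs, D_B = alpha_rs * geometry$V_R, fit = fit)
}

#' Effective membrane diffusivity from fitted rates
#'
#' Subtracts the rig baseline from the film-run rate and converts through the
#' cell constant: `D_eM = (alpha - alpha_rs) / k_M`. A film rate below the
#' baseline is physically a zero-diffusivity film measured within rig noise,
#' so the estimate clips to 0 with `below_baseline = TRUE` instead of going
#' negative.
#'
#' @param alpha Film-run diffusion factor, min^-1.
#' @param alpha_rs Stopper-run diffusion factor, min^-1.
#' @param geometry A [chamber_geometry()].
#' @return List with `D_eM_cm2_s`, `D_eM_cm2_min`, `below_baseline`,
#'   `alpha`, `alpha_rs`, `D_B` (cm^3/min) and `k_M`.
#' @export
#' @examples
#' g <- chamber_geometry(2.75, 75, 100)
#' effective_diffusivity(0.012, 0.002, g)$D_eM_cm2_s  # 4.545e-5
effective_diffusivity <- function(alpha, alpha_rs, geometry) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (!is.finite(alpha) || !is.finite(alpha_rs)) {
    stop("alpha and alpha_rs must be finite", call. = FALSE)
  }
  d_min <- (alpha - alpha_rs) / geometry$k_M
  below <- d_min <= 0   # no transmembrane transport detectable
  if (below) d_min <- 0
  list(D_eM_cm2_s = convert_unit(d_min, "cm2/min", "cm2/s"),
       D_eM_cm2_min = d_min,
       below_baseline = below,
       alpha = alpha, alpha_rs = alpha_rs,
       D_B = alpha_rs * geometry$V_R,
       k_M = geometry$k_M)
}

#' Analyse a film from replicate runs and a stopper baseline
#'
#' The full estimator for one film: each replicate concentration record is
#' fitted log-linearly for its diffusion factor, the replicate rates are
#' averaged (mean +/- sd), the stopper record gives the rig baseline, and the
#' effective membrane oxygen diffusivity follows from the mean rate.
#' Replicates whose fit fails (e.g. saturated records) are dropped with a
#' warning; at least one usable replicate is required.
#'
#' @param replicates A single [oxygen_series()] or a list of them (films are
#'   typically run 3 times consecutively).
#' @param stopper_series An [oxygen_series()] from the rubber-stopper run.
#' @param geometry A [chamber_geometry()].
#' @return An object of class `oxygen_fit` with per-replicate fits, the mean
#'   and sd of alpha, the baseline, and the derived diffusivity.
#' @export
#' @examples
#' g <- chamber_geometry()
#' reps <- lapply(1:3, function(i)
#'   gen_oxygen_experiment(1e-6, 0.02, g, seed = i))
#' stp <- gen_stopper_experiment(0.02, g, seed = 99)
#' fit <- analyze_film(reps, stp, g)
#' coef(fit)["D_eM_cm2_s"]
analyze_film <- function(replicates, stopper_series, geometry) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (inherits(replicates, "oxygen_series")) replicates <- list(replicates)
  if (length(replicates) < 1) stop("at least one replicate required", call. = FALSE)
  fits <- list()
  for (i in seq_along(replicates)) {
    f <- tryCatch(fit_diffusion_factor(replicates[[i]]), error = function(e) e)
    if (inherits(f, "error")) {
      warning("replicate ", i, " unusable (", conditionMessage(f),
              "); continuing with the rest", call. = FALSE)
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) == 0) {
    stop("no usable replicate concentration records", call. = FALSE)
  }
  alphas <- vapply(fits, `[[`, 0, "alpha")
  base <- baseline_factor(stopper_series, geometry)
  eff <- effective_diffusivity(mean(alphas), base$alpha_rs, geometry)
  structure(
    list(replicate_fits = fits,
         alpha = alphas,
         alpha_mean = mean(alphas),
         alpha_sd = if (length(alphas) > 1) stats::sd(alphas) else 0,
         alpha_rs = base$alpha_rs,
         D_B = base$D_B,
         D_eM_cm2_s = eff$D_eM_cm2_s,
         D_eM_cm2_min = eff$D_eM_cm2_min,
         below_baseline = eff$below_baseline,
         geometry = geometry,
         c_D = mean(vapply(replicates, `[[`, 0, "c_D")),
         n_replicates = length(fits)),
    class = "oxygen_fit"
  )
}

#' @export
print.oxygen_fit <- function(x, ...) {
  cat("Two-chamber oxygen diffusivity fit\n")
  cat(sprintf("  alpha     = %.4g +/- %.2g min^-1 (%d replicate(s))\n",
              x$alpha_mean, x$alpha_sd, x$n_replicates))
  cat(sprintf("  alpha_rs  = %.4g min^-1 (D_B = %.4g cm^3/min)\n",
              x$alpha_rs, x$D_B))
  cat(sprintf("  D_eM      = %.4g cm^2/s%s\n", x$D_eM_cm2_s,
              if (x$below_baseline) "  [below baseline, clipped to 0]" else ""))
  invisible(x)
}

#' @export
summary.oxygen_fit <- function(object, ...) {
  reps <- data.frame(
    replicate = vapply(object$replicate_fits, `[[`, "", "replicate_id"),
    alpha_per_min = object$alpha,
    r_squared = vapply(object$replicate_fits, `[[`, 0, "r_squared"),
    n_points_used = vapply(object$replicate_fits, `[[`, 0L, "n_points_used"),
    n_excluded = vapply(object$replicate_fits, `[[`, 0L, "n_excluded")
  )
  structure(list(replicates = reps, fit = object), class = "summary.oxygen_fit")
}

#' @export
print.summary.oxygen_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-replicate log-linear fits:\n")
  print(x$replicates, row.names = FALSE)
  invisible(x)
}

#' @export
coef.oxygen_fit <- function(object, ...) {
  c(alpha_per_min = object$alpha_mean,
    alpha_rs_per_min = object$alpha_rs,
    D_B_cm3_per_min = object$D_B,
    D_eM_cm2_s = object$D_eM_cm2_s)
}

#' Predicted receiving-chamber concentration from a fitted film
#'
#' @param object An `oxygen_fit`.
#' @param t_min Times (minutes) at which to evaluate the fitted relaxation.
#' @param c_R0 Initial concentration, mg/L (default 0).
#' @param ... Unused.
#' @return Predicted c_R, mg/L.
#' @export
predict.oxygen_fit <- function(object, t_min, c_R0 = 0, ...) {
  solve_closed_form(t_min, c_R0 = c_R0, c_D = object$c_D,
                    alpha = max(0, object$alpha_mean))
}

#' @export
plot.oxygen_fit <- function(x, t_max_min = NULL, ...) {
  tm <- if (is.null(t_max_min)) 360 else t_max_min
  tt <- seq(0, tm, length.out = 200)
  graphics::plot(tt, predict(x, tt), type = "l",
                 xlab = "time [min]", ylab = "c_R [mg/L]",
                 main = "Fitted receiving-chamber relaxation", ...)
  graphics::abline(h = x$c_D, lty = 2)
  invisible(x)
}
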