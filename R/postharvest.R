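# Postharvest physiology metrics: closed-jar respiration rate, gravimetric
# dehydration, puncture-test firmness, and one-/two-way ANOVA with Tukey HSD
# for group comparisons at alpha = 0.05.

#' Closed-jar headspace CO2 record
#'
#' @param t_h Sampling times, hours, strictly increasing.
#' @param co2_pct Headspace CO2, percent v/v, non-negative.
#' @param mass_kg Fruit mass in the jar, kg (> 0).
#' @param headspace_ml Jar free (empty) volume, ml (> 0); must be measured
#'   by the user, it is not derivable from jar size alone.
#' @param replicate_id Replicate label.
#' @return An object of class `headspace_series`.
#' @export
headspace_series <- function(t_h, co2_pct, mass_kg, headspace_ml,
                             replicate_id = NA_character_) {
  if (mass_kg <= 0 || headspace_ml <= 0) {
    stop("mass and headspace volume must be positive", call. = FALSE)
  }
  if (any(co2_pct < 0)) stop("co2_pct must be >= 0", call. = FALSE)
  ts <- timeseries(t_h, co2_pct, t_unit = "h", y_unit = "pct",
                   replicate_id = replicate_id)
  structure(
    list(t_h = convert_unit(ts$t_min, "min", "h"), co2_pct = ts$y,
         mass_kg = mass_kg, headspace_ml = headspace_ml,
         replicate_id = ts$replicate_id),
    class = "headspace_series"
  )
}

#' Respiration rate from headspace CO2 accumulation
#'
#' `rate = (dCO2/100 * V_headspace) / (m * dt)` in ml CO2 kg^-1 h^-1, with
#' dCO2 the difference between the first and last CO2 reading inside the
#' chosen window and dt the corresponding elapsed time in hours. The
#' endpoint difference follows the source method; `method = "slope"` uses
#' the OLS slope of CO2 on time over the window instead, which is more
#' robust for noisy analysers.
#'
#' @param series A [headspace_series()].
#' @param window Length-2 time window in hours (default: the full record).
#' @param method `"endpoints"` (default) or `"slope"`.
#' @return Respiration rate, ml CO2 kg^-1 h^-1.
#' @export
#' @examples
#' hs <- headspace_series(c(0, 6), c(0, 1.2), mass_kg = 0.1,
#'                        headspace_ml = 900)
#' respiration_rate(hs)  # 18
respiration_rate <- function(series, window = NULL,
                             method = c("endpoints", "slope")) {
  stopifnot(inherits(series, "headspace_series"))
  method <- match.arg(method)
  if (is.null(window)) window <- range(series$t_h)
  keep <- series$t_h >= window[1] & series$t_h <= window[2]
  if (sum(keep) < 2) stop("window must span at least 2 samples", call. = FALSE)
  t <- series$t_h[keep]
  co2 <- series$co2_pct[keep]
  slope_pct_h <- if (method == "endpoints") {
    dt <- t[length(t)] - t[1]
    if (dt <= 0) stop("zero elapsed time in window", call. = FALSE)
    (co2[length(co2)] - co2[1]) / dt
  } else {
    unname(stats::coef(stats::lm(co2 ~ t))[2])
  }
  (slope_pct_h / 100) * series$headspace_ml / series$mass_kg
}

#' Gravimetric berry weight record
#'
#' @param day Sampling days, strictly increasing.
#' @param w_g Berry weight, g, non-negative.
#' @param w0_g Day-0 reference weight, g (> 0); defaults to the first
#'   recorded weight.
#' @param replicate_id Replicate label.
#' @return An object of class `weight_series`.
#' @export
weight_series <- function(day, w_g, w0_g = NULL,
                          replicate_id = NA_character_) {
  ts <- timeseries(day, w_g, t_unit = "day", y_unit = "g",
                   replicate_id = replicate_id)
  if (any(w_g < 0)) stop("weights must be >= 0", call. = FALSE)
  if (is.null(w0_g)) w0_g <- w_g[1]
  if (w0_g <= 0) stop("w0_g must be positive", call. = FALSE)
  structure(
    list(day = convert_unit(ts$t_min, "min", "day"), w_g = ts$y,
         w0_g = w0_g, replicate_id = ts$replicate_id),
    class = "weight_series"
  )
}

#' Fraction of original weight lost by a given day
#'
#' `1 - w(day)/w0`, with linear interpolation between adjacent sampling
#' days; days outside the recorded range are an error.
#'
#' @param series A [weight_series()].
#' @param day Day (vectorised) at which to evaluate the loss.
#' @return Weight-loss fraction(s).
#' @export
#' @examples
#' ws <- weight_series(c(0, 7, 14), c(20, 11, 6))
#' weight_loss_fraction(ws, 14)  # 0.70
weight_loss_fraction <- function(series, day) {
  stopifnot(inherits(series, "weight_series"))
  if (any(day < min(series$day)) || any(day > max(series$day))) {
    stop("day outside the recorded range ", min(series$day), "-",
         max(series$day), call. = FALSE)
  }
  w <- stats::approx(series$day, series$w_g, xout = day)$y
  1 - w / series$w0_g
}

#' Puncture-test force-displacement record
#'
#' @param displacement_mm Probe displacement, mm, non-negative increasing.
#' @param force_n Measured force, N.
#' @param probe_diameter_mm Probe diameter, mm (default 5).
#' @param max_depth_mm Penetration depth defining the firmness window, mm
#'   (default 8).
#' @param speed_mm_s Cross-head speed, mm/s (default 1; metadata).
#' @param replicate_id Replicate label.
#' @return An object of class `puncture_curve`.
#' @export
puncture_curve <- function(displacement_mm, force_n, probe_diameter_mm = 5,
                           max_depth_mm = 8, speed_mm_s = 1,
                           replicate_id = NA_character_) {
  d <- as.numeric(displacement_mm)
  f <- as.numeric(force_n)
  if (length(d) == 0) stop("empty curve", call. = FALSE)
  if (length(d) != length(f)) stop("length mismatch", call. = FALSE)
  if (anyNA(d) || anyNA(f)) stop("missing values are not allowed", call. = FALSE)
  if (any(d < 0) || any(diff(d) <= 0)) {
    stop("displacement must be non-negative and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(displacement_mm = d, force_n = f,
         probe_diameter_mm = probe_diameter_mm,
         max_depth_mm = max_depth_mm, speed_mm_s = speed_mm_s,
         replicate_id = as.character(replicate_id)),
    class = "puncture_curve"
  )
}

#' Maximum penetration force (firmness)
#'
#' Maximum force recorded over displacements in `[0, max_depth]` mm. Curves
#' that stop short of the full depth are used as-is with a warning.
#'
#' @param curve A [puncture_curve()].
#' @param max_depth_mm Depth window, mm; defaults to the curve's own
#'   `max_depth_mm`.
#' @return Maximum force, N.
#' @export
max_penetration_force <- function(curve, max_depth_mm = NULL) {
  stopifnot(inherits(curve, "puncture_curve"))
  if (is.null(max_depth_mm)) max_depth_mm <- curve$max_depth_mm
  if (max(curve$displacement_mm) < max_depth_mm) {
    warning("curve truncated at ", max(curve$displacement_mm),
            " mm (< ", max_depth_mm, " mm window)", call. = FALSE)
  }
  keep <- curve$displacement_mm <= max_depth_mm
  if (!any(keep)) stop("no samples inside the depth window", call. = FALSE)
  max(curve$force_n[keep])
}

#' Firmness summary over replicate curves
#'
#' Per-curve maxima and their mean +/- sd.
#'
#' @param curves List of [puncture_curve()] objects.
#' @return List with `per_curve` (N), `mean_n` and `sd_n`.
#' @export
firmness_summary <- function(curves) {
  if (inherits(curves, "puncture_curve")) curves <- list(curves)
  maxima <- vapply(curves, max_penetration_force, 0)
  list(per_curve = maxima, mean_n = mean(maxima),
       sd_n = if (length(maxima) > 1) stats::sd(maxima) else 0)
}

#' One- or two-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Group comparison of scalar metrics at alpha = 0.05: per-factor F and p
#' from `stats::aov`, and the Tukey honestly-significant-difference table
#' with a significance flag per pair.
#'
#' @param value Numeric metric values.
#' @param group Primary grouping factor (coerced).
#' @param group2 Optional second factor for a two-way (additive) design.
#' @param design `"one-way"` (default) or `"two-way"`; two-way requires
#'   `group2`.
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return An object of class `group_comparison`: `anova` (factor, df, F,
#'   p), `tukey` (factor, pair, diff, lwr, upr, p_adj, significant) and the
#'   fitted `aov` object.
#' @export
#' @examples
#' gc <- group_compare(c(1, 1.1, 0.9, 5, 5.2, 4.8),
#'                     rep(c("a", "b"), each = 3))
#' gc$anova$p
group_compare <- function(value, group, group2 = NULL,
                          design = c("one-way", "two-way"), alpha = 0.05) {
  design <- match.arg(design)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  df <- data.frame(value = value, g1 = group)
  if (design == "two-way") {
    if (is.null(group2)) stop("two-way design requires group2", call. = FALSE)
    df$g2 <- factor(group2)
    fit <- stats::aov(value ~ g1 + g2, data = df)
  } else {
    fit <- stats::aov(value ~ g1, data = df)
  }
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  keep <- terms != "Residuals"
  anova_tab <- data.frame(
    factor = terms[keep],
    df = an$Df[keep],
    F = an$`F value`[keep],
    p = an$`Pr(>F)`[keep]
  )
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)
  tukey_tab <- do.call(rbind, lapply(names(tk), function(nm) {
    m <- tk[[nm]]
    data.frame(factor = nm, pair = rownames(m), diff = m[, "diff"],
               lwr = m[, "lwr"], upr = m[, "upr"], p_adj = m[, "p adj"],
               significant = m[, "p adj"] < alpha, row.names = NULL)
  }))
  structure(list(anova = anova_tab, tukey = tukey_tab, alpha = alpha,
                 design = design, fit = fit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s ANOVA with Tukey HSD (alpha = %g)\n", x$design, x$alpha))
  print(x$anova, row.names = FALSE)
  cat("\nPairwise (Tukey HSD):\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}
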