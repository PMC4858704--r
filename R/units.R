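# Unit registry and conversions. Canonical internal units: time in minutes,
# length in cm, area in cm^2, volume in cm^3, mass in g, concentration in
# mg/L, pressure in Pa. Diffusivities are carried in cm^2/min internally and
# reported in cm^2/s; WVTR is reported in g/m^2/s.

.unit_registry <- local({
  u <- rbind(
    data.frame(unit = c("s", "min", "h", "day"),
               dimension = "time",
               factor = c(1 / 60, 1, 60, 1440)),
    data.frame(unit = c("um", "mm", "cm", "m"),
               dimension = "length",
               factor = c(1e-4, 0.1, 1, 100)),
    data.frame(unit = c("mm2", "cm2", "m2"),
               dimension = "area",
               factor = c(1e-2, 1, 1e4)),
    data.frame(unit = c("uL", "mL", "cm3", "L", "m3"),
               dimension = "volume",
               factor = c(1e-3, 1, 1, 1e3, 1e6)),
    data.frame(unit = c("ug", "mg", "g", "kg"),
               dimension = "mass",
               factor = c(1e-6, 1e-3, 1, 1e3)),
    data.frame(unit = c("ug/L", "mg/L", "g/L"),
               dimension = "concentration",
               factor = c(1e-3, 1, 1e3)),
    data.frame(unit = c("Pa", "kPa", "atm"),
               dimension = "pressure",
               factor = c(1, 1e3, 101325)),
    data.frame(unit = c("cm2/min", "cm2/s", "m2/s"),
               dimension = "diffusivity",
               factor = c(1, 60, 6e5)),
    data.frame(unit = c("g/m2/min", "g/m2/h", "g/m2/s"),
               dimension = "areal_mass_flux",
               factor = c(1, 1 / 60, 60)),
    data.frame(unit = c("pct", "frac"),
               dimension = "ratio",
               factor = c(1, 100)),
    data.frame(unit = "N", dimension = "force", factor = 1),
    data.frame(unit = "arb", dimension = "arbitrary", factor = 1)
  )
  rownames(u) <- u$unit
  u
})

#' Registered measurement units
#'
#' The package stores all quantities in fixed canonical units (time in
#' minutes, length in cm, volume in cm^3, mass in g, concentration in mg/L,
#' pressure in Pa) and converts on entry and on report. This returns the
#' registry of recognised unit symbols.
#'
#' @return A data frame with columns `unit`, `dimension` and `factor` (the
#'   multiplier taking one unit to the dimension's canonical unit).
#' @export
#' @examples
#' units_registered()[units_registered()$dimension == "time", ]
units_registered <- function() {
  r <- .unit_registry
  rownames(r) <- NULL
  r
}

unit_info <- function(unit) {
  hit <- match(unit, .unit_registry$unit)
  if (is.na(hit)) {
    stop("unknown unit '", unit, "'; see units_registered()", call. = FALSE)
  }
  .unit_registry[hit, ]
}

#' Convert a quantity between registered units
#'
#' Exact multiplicative conversion between two units of the same dimension;
#' incompatible dimensions are an error. Conversions round-trip to within
#' 1e-12 relative.
#'
#' @param x Numeric quantity (vectorised).
#' @param from,to Unit symbols, as listed by [units_registered()].
#' @return `x` expressed in `to` units.
#' @export
#' @examples
#' convert_unit(75, "um", "cm")          # film thickness, 0.0075 cm
#' convert_unit(1, "g/m2/h", "g/m2/s")   # 2.7778e-4
convert_unit <- function(x, from, to) {
  fi <- unit_info(from)
  ti <- unit_info(to)
  if (fi$dimension != ti$dimension) {
    stop("incompatible dimensions: '", from, "' is ", fi$dimension,
         ", '", to, "' is ", ti$dimension, call. = FALSE)
  }
  x * (fi$factor / ti$factor)
}

#' Construct a validated time series
#'
#' The shared container for instrument records: a strictly increasing time
#' axis (stored canonically in minutes) and one measurement channel with a
#' declared unit. At least two points are required and missing values are
#' rejected.
#'
#' @param t Numeric time values in `t_unit`.
#' @param y Numeric measurements in `y_unit`.
#' @param t_unit Time unit of the input (`"s"`, `"min"`, `"h"` or `"day"`).
#' @param y_unit Measurement unit; any registered unit, or `"arb"`.
#' @param replicate_id Optional replicate label.
#' @return An object of class `silk_ts` with fields `t_min`, `y`, `y_unit`
#'   and `replicate_id`.
#' @export
#' @examples
#' ts <- timeseries(c(0, 1, 2), c(20, 19.2, 18.6), t_unit = "day",
#'                  y_unit = "g", replicate_id = "berry-1")
#' ts_time(ts, "day")
timeseries <- function(t, y, t_unit = "min", y_unit = "arb",
                       replicate_id = NA_character_) {
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) != length(y)) {
    stop("t and y must have equal length", call. = FALSE)
  }
  if (length(t) < 2) stop("a time series needs at least 2 points", call. = FALSE)
  if (anyNA(t) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("time must be strictly increasing (duplicated or unordered stamps)",
         call. = FALSE)
  }
  if (unit_info(t_unit)$dimension != "time") {
    stop("'", t_unit, "' is not a time unit", call. = FALSE)
  }
  unit_info(y_unit)  # validate
  structure(
    list(t_min = convert_unit(t, t_unit, "min"), y = y,
         y_unit = y_unit, replicate_id = as.character(replicate_id)),
    class = "silk_ts"
  )
}

#' @export
print.silk_ts <- function(x, ...) {
  cat("Time series (", length(x$t_min), " points, ",
      format(min(x$t_min)), "-", format(max(x$t_min)), " min, y in ",
      x$y_unit, ")\n", sep = "")
  if (!is.na(x$replicate_id)) cat("replicate:", x$replicate_id, "\n")
  invisible(x)
}

#' Extract the time axis of a series in a chosen unit
#'
#' @param x A `silk_ts`.
#' @param unit Target time unit.
#' @return Numeric vector of times.
#' @export
ts_time <- function(x, unit = "min") {
  stopifnot(inherits(x, "silk_ts"))
  convert_unit(x$t_min, "min", unit)
}

# Header columns are "<name>_<unit>" with "/" spelled "_per_":
# "t_min", "c_mg_per_L", "w_g", "co2_pct".
parse_column_unit <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2) return(NULL)
  for (k in 2:length(parts)) {
    unit <- paste(parts[k:length(parts)], collapse = "_")
    unit <- gsub("_per_", "/", paste0("_", unit))
    unit <- sub("^_", "", unit)
    unit <- gsub("_", "/", unit)
    if (unit %in% .unit_registry$unit) {
      return(list(name = paste(parts[1:(k - 1)], collapse = "_"), unit = unit))
    }
  }
  NULL
}

#' Read a two-column CSV time series
#'
#' Reads a comma-separated, UTF-8, header-first file whose column names
#' declare their units as `<name>_<unit>` with `/` spelled `_per_`
#' (e.g. `t_min`, `c_mg_per_L`, `w_g`). Values are converted to canonical
#' units on entry and time ordering is enforced. Malformed numeric cells
#' raise an error naming the offending line.
#'
#' @param path CSV file path.
#' @param time_col,value_col Column names (without unit suffix) to use;
#'   defaults: first column is time, second is the measurement.
#' @param replicate_id Optional replicate label; defaults to the file name.
#' @return A [timeseries()] object.
#' @export
read_timeseries <- function(path, time_col = NULL, value_col = NULL,
                            replicate_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("expected at least 2 columns in ", path, call. = FALSE)
  meta <- lapply(names(raw), parse_column_unit)
  bad <- vapply(meta, is.null, logical(1))
  if (any(bad)) {
    stop("column(s) without a recognised unit suffix: ",
         paste(names(raw)[bad], collapse = ", "), call. = FALSE)
  }
  names(meta) <- vapply(meta, `[[`, "", "name")
  cols <- vapply(meta, `[[`, "", "name")
  tc <- if (is.null(time_col)) cols[1] else time_col
  vc <- if (is.null(value_col)) cols[2] else value_col
  for (want in c(tc, vc)) {
    if (!want %in% cols) stop("no column named '", want, "' in ", path, call. = FALSE)
  }
  num <- function(col_idx) {
    txt <- raw[[col_idx]]
    val <- suppressWarnings(as.numeric(txt))
    if (anyNA(val)) {
      line <- which(is.na(val))[1] + 1L  # +1 for the header row
      stop("malformed value '", txt[is.na(val)][1], "' at line ", line,
           " of ", path, call. = FALSE)
    }
    val
  }
  it <- match(tc, cols)
  iv <- match(vc, cols)
  timeseries(num(it), num(iv),
             t_unit = meta[[it]]$unit, y_unit = meta[[iv]]$unit,
             replicate_id = if (is.null(replicate_id)) basename(path)
                            else replicate_id)
}

#' Write a time series to CSV
#'
#' Inverse of [read_timeseries()]: columns are named with canonical unit
#' suffixes so a round trip reproduces the stored values.
#'
#' @param x A `silk_ts`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "silk_ts"))
  yname <- paste0("y_", gsub("/", "_per_", x$y_unit))
  df <- data.frame(t_min = x$t_min, y = x$y)
  names(df)[2] <- yname
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Describe a coating condition
#'
#' One experimental arm of the coating study: how many dips in the 1 wt%
#' fibroin suspension, how long the water-annealing post-process ran, and the
#' resulting film crystallinity and thickness. Water annealing (water vapour
#' under vacuum at 22 C) raises the protein's relative beta-sheet content,
#' which in turn governs the film's gas and water-vapour barrier properties.
#'
#' @param dip_steps Number of dip-coating passes (>= 1).
#' @param annealing_hours Water-annealing exposure, hours (>= 0).
#' @param beta_sheet_pct Relative beta-sheet content, percent in [0, 100].
#' @param thickness_um Film thickness, micrometres (> 0).
#' @return An object of class `coating_condition`.
#' @export
#' @examples
#' coating_condition(4, 12, 58, 75)
coating_condition <- function(dip_steps, annealing_hours, beta_sheet_pct,
                              thickness_um) {
  if (dip_steps < 1 || dip_steps != round(dip_steps)) {
    stop("dip_steps must be a positive integer", call. = FALSE)
  }
  if (annealing_hours < 0) stop("annealing_hours must be >= 0", call. = FALSE)
  if (beta_sheet_pct < 0 || beta_sheet_pct > 100) {
    stop("beta_sheet_pct must lie in [0, 100]", call. = FALSE)
  }
  if (thickness_um <= 0) stop("thickness_um must be positive", call. = FALSE)
  structure(
    list(dip_steps = as.integer(dip_steps),
         annealing_hours = annealing_hours,
         beta_sheet_pct = beta_sheet_pct,
         thickness_um = thickness_um),
    class = "coating_condition"
  )
}

#' @export
print.coating_condition <- function(x, ...) {
  cat(sprintf(
    "Coating condition: %d dip(s), %g h water annealing, %g%% beta-sheet, %g um\n",
    x$dip_steps, x$annealing_hours, x$beta_sheet_pct, x$thickness_um))
  invisible(x)
}

silk_log <- function(stage, ...) {
  if (isTRUE(getOption("silkcoat.verbose", FALSE))) {
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  }
  invisible(NULL)
}
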