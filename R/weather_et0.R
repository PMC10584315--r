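#' Saturation vapour pressure (Tetens form)
#'
#' Saturation vapour pressure of air at temperature `t`, using the FAO-56
#' Tetens formulation. Strictly increasing and positive over the valid range.
#'
#' @param t Air temperature in degrees Celsius (must exceed -40).
#' @return Saturation vapour pressure in kPa.
#' @examples
#' saturation_vapour_pressure(20) # ~2.338 kPa
#' @export
saturation_vapour_pressure <- function(t) {
  stopifnot(is.numeric(t))
  if (any(t <= -40)) stop("temperature out of range: t must exceed -40 degC")
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Slope of the saturation vapour pressure curve
#'
#' Derivative of the Tetens saturation curve with respect to temperature,
#' the Delta term of the Penman-Monteith combination equation.
#'
#' @inheritParams saturation_vapour_pressure
#' @return Slope in kPa per degree Celsius.
#' @export
slope_vapour_curve <- function(t) {
  4098 * saturation_vapour_pressure(t) / (t + 237.3)^2
}

#' Psychrometric constant from site altitude
#'
#' Computes atmospheric pressure from altitude with the standard-atmosphere
#' lapse formula and converts it to the psychrometric constant gamma.
#'
#' @param altitude Site elevation in metres above sea level (>= -430).
#' @return Psychrometric constant in kPa per degree Celsius.
#' @export
psychrometric_constant <- function(altitude) {
  stopifnot(is.numeric(altitude))
  if (any(altitude < -430)) stop("altitude below -430 m is not supported")
  pressure <- 101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
  0.665e-3 * pressure
}

#' Site description for radiation and pressure terms
#'
#' @param latitude Decimal degrees, in \[-90, 90\].
#' @param altitude Metres above sea level.
#' @param station_id Optional station label.
#' @return An object of class `site_info`.
#' @export
site_info <- function(latitude, altitude, station_id = NA_character_) {
  stopifnot(is.numeric(latitude), length(latitude) == 1L,
            is.numeric(altitude), length(altitude) == 1L)
  if (latitude < -90 || latitude > 90) stop("latitude must lie in [-90, 90]")
  structure(list(latitude = latitude, altitude = altitude,
                 station_id = station_id), class = "site_info")
}

#' @export
print.site_info <- function(x, ...) {
  cat(sprintf("<site_info> lat %.4f deg, alt %.0f m%s\n", x$latitude,
              x$altitude,
              if (is.na(x$station_id)) "" else paste0(", station ", x$station_id)))
  invisible(x)
}

# Solar geometry ------------------------------------------------------------

#' Extraterrestrial radiation for daily periods
#'
#' Top-of-atmosphere solar radiation from latitude and day of year
#' (solar constant 0.0820 MJ m-2 min-1).
#'
#' @param latitude Decimal degrees.
#' @param doy Day of year (1-366).
#' @return Ra in MJ m-2 day-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- sunset_hour_angle(phi, decl)
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

# sunset hour angle; errors on polar night (no sunrise), clamps polar day
sunset_hour_angle <- function(phi, decl) {
  x <- -tan(phi) * tan(decl)
  if (any(x >= 1)) {
    stop("unsupported site: polar night (sun never rises on this day)")
  }
  acos(pmax(x, -1))
}

#' Daylight hours
#'
#' Maximum possible sunshine duration for a latitude and day of year.
#'
#' @inheritParams extraterrestrial_radiation
#' @return Daylength N in hours.
#' @export
daylight_hours <- function(latitude, doy) {
  phi <- latitude * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  24 / pi * sunset_hour_angle(phi, decl)
}

# Radiation balance ----------------------------------------------------------

#' Net radiation at the crop surface
#'
#' FAO-56 daily radiation balance: Angstrom shortwave from sunshine duration,
#' albedo-reduced net shortwave, and Stefan-Boltzmann net longwave with
#' humidity and cloudiness corrections.
#'
#' @param day One-row weather record (list or data.frame row) with `date`,
#'   `tmax`, `tmin`, `sunshine_hours`, `rh_mean`.
#' @param site A [site_info()] object.
#' @param albedo Surface albedo; 0.23 for the reference grass surface.
#' @param angstrom_a,angstrom_b Angstrom regression coefficients relating
#'   relative sunshine duration to the fraction of Ra reaching the surface.
#' @return Net radiation Rn in MJ m-2 day-1.
#' @export
net_radiation <- function(day, site, albedo = 0.23,
                          angstrom_a = 0.25, angstrom_b = 0.50) {
  doy <- as.integer(strftime(as.Date(day$date), "%j"))
  ra <- extraterrestrial_radiation(site$latitude, doy)
  n_max <- daylight_hours(site$latitude, doy)
  n_rel <- min(day$sunshine_hours, n_max) / n_max
  rs <- (angstrom_a + angstrom_b * n_rel) * ra
  rso <- (0.75 + 2e-5 * site$altitude) * ra
  rns <- (1 - albedo) * rs
  ea <- actual_vapour_pressure(day$tmax, day$tmin, day$rh_mean)
  sigma <- 4.903e-9 # MJ K-4 m-2 day-1
  tk4 <- ((day$tmax + 273.16)^4 + (day$tmin + 273.16)^4) / 2
  cloud <- if (rso > 0) pmin(rs / rso, 1) else 1
  rnl <- sigma * tk4 * (0.34 - 0.14 * sqrt(ea)) * (1.35 * cloud - 0.35)
  rns - rnl
}

# es as mean of the saturation pressures at the temperature extremes;
# ea reduced from mean relative humidity (only RH mean is available)
mean_saturation_vp <- function(tmax, tmin) {
  (saturation_vapour_pressure(tmax) + saturation_vapour_pressure(tmin)) / 2
}

actual_vapour_pressure <- function(tmax, tmin, rh_mean) {
  rh_mean / 100 * mean_saturation_vp(tmax, tmin)
}

#' Assemble the Penman-Monteith terms for one day
#'
#' @inheritParams net_radiation
#' @param g Soil heat flux density (MJ m-2 day-1); 0 at the daily step.
#' @return A `penman_terms` list with fields `rn`, `g`, `t_mean`, `u2`,
#'   `es`, `ea`, `delta`, `gamma`.
#' @export
penman_terms <- function(day, site, albedo = 0.23, angstrom_a = 0.25,
                         angstrom_b = 0.50, g = 0) {
  t_mean <- (day$tmax + day$tmin) / 2
  terms <- list(
    rn = net_radiation(day, site, albedo, angstrom_a, angstrom_b),
    g = g,
    t_mean = t_mean,
    u2 = day$wind_u2,
    es = mean_saturation_vp(day$tmax, day$tmin),
    ea = actual_vapour_pressure(day$tmax, day$tmin, day$rh_mean),
    delta = slope_vapour_curve(t_mean),
    gamma = psychrometric_constant(site$altitude)
  )
  structure(terms, class = "penman_terms")
}

#' Reference evapotranspiration (Penman-Monteith combination equation)
#'
#' Daily grass-reference evapotranspiration
#' \deqn{ET_0 = \frac{0.408\,\Delta\,(R_n - G) +
#'   \gamma\,\frac{900}{T+273}\,u_2\,(e_s - e_a)}
#'   {\Delta + \gamma\,(1 + 0.34\,u_2)}}
#' A negative radiative balance (rare winter days) is clamped to zero with
#' a warning so that negative atmospheric demand never propagates.
#'
#' @param terms A [penman_terms()] object.
#' @return ET0 in mm per day (non-negative).
#' @export
et0_penman_monteith <- function(terms) {
  num <- 0.408 * terms$delta * (terms$rn - terms$g) +
    terms$gamma * 900 / (terms$t_mean + 273) * terms$u2 * (terms$es - terms$ea)
  den <- terms$delta + terms$gamma * (1 + 0.34 * terms$u2)
  et0 <- num / den
  if (any(et0 < 0)) {
    warning("negative computed ET0 clamped to 0")
    et0 <- pmax(et0, 0)
  }
  et0
}

# Weather series -------------------------------------------------------------

weather_columns <- c("date", "tmax", "tmin", "precip", "sunshine_hours",
                     "rh_mean", "wind_u2")

#' Validate a daily weather series
#'
#' Checks the physical invariants of each day: tmax >= tmin, non-negative
#' precipitation and wind, relative humidity in \[0, 100\], sunshine within
#' \[0, 24\] h and, when present, non-negative ET0.
#'
#' @param weather Data frame with columns `date`, `tmax`, `tmin`, `precip`,
#'   `sunshine_hours`, `rh_mean`, `wind_u2` and optionally `et0`.
#' @return The validated data frame, invisibly, with `date` as `Date`.
#' @export
validate_weather <- function(weather) {
  missing_cols <- setdiff(weather_columns, names(weather))
  if (length(missing_cols)) {
    stop("weather series lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  weather$date <- as.Date(weather$date)
  for (col in setdiff(weather_columns, "date")) {
    bad <- which(is.na(weather[[col]]))
    if (length(bad)) {
      stop(sprintf("missing %s on %s", col, paste(weather$date[bad[1]])))
    }
  }
  check <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad)) {
      stop(sprintf("%s violated on %s", what, paste(weather$date[bad[1]])))
    }
  }
  check(weather$tmax >= weather$tmin, "tmax >= tmin")
  check(weather$precip >= 0, "precip >= 0")
  check(weather$rh_mean >= 0 & weather$rh_mean <= 100, "rh_mean in [0,100]")
  check(weather$wind_u2 >= 0, "wind_u2 >= 0")
  check(weather$sunshine_hours >= 0 & weather$sunshine_hours <= 24,
        "sunshine_hours in [0,24]")
  if ("et0" %in% names(weather)) check(weather$et0 >= 0, "et0 >= 0")
  invisible(weather)
}

#' Attach Penman-Monteith ET0 to every day of a weather series
#'
#' Pure per-day computation: the result is invariant under reordering of the
#' input rows, and idempotent (a series that already carries `et0` values is
#' returned with those values recomputed identically).
#'
#' @param weather Daily weather data frame (see [validate_weather()]).
#' @param site A [site_info()] object.
#' @param albedo,angstrom_a,angstrom_b Radiation-balance settings.
#' @return The weather data frame with an `et0` column (mm/day).
#' @export
attach_et0 <- function(weather, site, albedo = 0.23,
                       angstrom_a = 0.25, angstrom_b = 0.50) {
  weather <- validate_weather(weather)
  weather$date <- as.Date(weather$date)
  if (nrow(weather) == 0L) {
    weather$et0 <- numeric(0)
    return(weather)
  }
  weather$et0 <- vapply(seq_len(nrow(weather)), function(i) {
    day <- weather[i, ]
    suppressWarnings(
      et0_penman_monteith(penman_terms(day, site, albedo, angstrom_a, angstrom_b))
    )
  }, numeric(1))
  weather
}

#' Read and write the daily weather CSV dialect
#'
#' One row per day, ISO-8601 dates, fixed header
#' `date,tmax,tmin,precip,sunshine_hours,rh_mean,wind_u2[,et0]`; missing
#' values are empty fields.
#'
#' @param path File path.
#' @return `read_weather_csv` returns a validated weather data frame.
#' @export
read_weather_csv <- function(path) {
  weather <- utils::read.csv(path, stringsAsFactors = FALSE)
  weather$date <- as.Date(weather$date)
  validate_weather(weather)
  weather
}

#' @rdname read_weather_csv
#' @param weather Weather data frame to write.
#' @export
write_weather_csv <- function(weather, path) {
  cols <- c(weather_columns, intersect("et0", names(weather)))
  out <- weather[, cols]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
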