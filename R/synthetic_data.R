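#' Climate specification for the stochastic weather generator
#'
#' Parametric description of an arid continental climate: monthly rainfall
#' occurrence probabilities with Gamma-distributed event depths, sinusoidal
#' annual temperature cycles with a shared AR(1) daily anomaly, monthly mean
#' relative humidity, log-normal wind and sunshine expressed as a fraction
#' of astronomical daylength.
#'
#' @param annual_rain_mm Expected mean annual rainfall implied by the rain
#'   parameters (documentation target, mm).
#' @param may_oct_rain_mm Expected May-October rainfall sum (mm).
#' @param tmax_seasonal,tmin_seasonal Length-2 numeric `(mean, amplitude)` of
#'   the annual cosine cycle for the daily temperature extremes (degC), peak
#'   in mid-July.
#' @param rain_prob_by_month Length-12 daily rainfall occurrence
#'   probabilities.
#' @param rain_gamma Length-2 `(shape, scale)` of the Gamma event-depth
#'   distribution (mm).
#' @param rh_by_month Length-12 monthly mean relative humidity (%).
#' @param wind_lognorm Length-2 `(mu, sigma)` of log wind speed at 2 m.
#' @param sunshine_frac Mean sunshine duration as a fraction of daylength.
#' @param diurnal_floor Minimum tmax - tmin (degC).
#' @param latitude,altitude Site coordinates used for daylength and, in the
#'   simulator, for ET0.
#' @return A `climate_spec` object.
#' @seealso [ningxia_climate()] for the packaged arid-zone preset.
#' @export
climate_spec <- function(annual_rain_mm, may_oct_rain_mm,
                         tmax_seasonal, tmin_seasonal,
                         rain_prob_by_month, rain_gamma, rh_by_month,
                         wind_lognorm, sunshine_frac,
                         diurnal_floor = 5, latitude = 36.8, altitude = 1489) {
  stopifnot(length(tmax_seasonal) == 2L, length(tmin_seasonal) == 2L,
            length(rain_prob_by_month) == 12L, length(rain_gamma) == 2L,
            length(rh_by_month) == 12L, length(wind_lognorm) == 2L)
  if (any(rain_prob_by_month < 0 | rain_prob_by_month > 1)) {
    stop("rain_prob_by_month must lie in [0, 1]")
  }
  if (any(rain_gamma <= 0)) stop("rain_gamma shape and scale must be positive")
  if (tmax_seasonal[2] < 0 || tmin_seasonal[2] < 0) {
    stop("temperature amplitude must be non-negative")
  }
  if (sunshine_frac <= 0 || sunshine_frac > 1) {
    stop("sunshine_frac must lie in (0, 1]")
  }
  structure(list(
    annual_rain_mm = annual_rain_mm, may_oct_rain_mm = may_oct_rain_mm,
    tmax_seasonal = tmax_seasonal, tmin_seasonal = tmin_seasonal,
    rain_prob_by_month = rain_prob_by_month, rain_gamma = rain_gamma,
    rh_by_month = rh_by_month, wind_lognorm = wind_lognorm,
    sunshine_frac = sunshine_frac, diurnal_floor = diurnal_floor,
    latitude = latitude, altitude = altitude
  ), class = "climate_spec")
}

#' Arid central-Ningxia climate preset
#'
#' Emulates the central arid zone of Ningxia (continental arid climate,
#' roughly 270 mm mean annual rainfall concentrated in summer, high
#' evaporative demand, large diurnal temperature range, station altitude
#' 1489 m). Monthly expected rainfall totals sum to 270 mm with about
#' 238 mm falling May-October, between the two growing-season sums the
#' region records in typical years.
#'
#' @return A [climate_spec()] object.
#' @export
ningxia_climate <- function() {
  monthly_rain <- c(2, 3, 8, 13, 28, 38, 52, 52, 42, 26, 4, 2) # mm, sums 270
  days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  event_mean <- 0.7 * 12 # gamma shape * scale, mm per wet day (convective)
  climate_spec(
    annual_rain_mm = sum(monthly_rain),
    may_oct_rain_mm = sum(monthly_rain[5:10]),
    tmax_seasonal = c(15.5, 14.5),
    tmin_seasonal = c(2.5, 14.5),
    rain_prob_by_month = monthly_rain / (days_in_month * event_mean),
    rain_gamma = c(0.7, 12),
    rh_by_month = c(48, 45, 42, 40, 42, 48, 55, 60, 62, 58, 55, 52),
    wind_lognorm = c(log(2), 0.35),
    sunshine_frac = 0.68,
    latitude = 36.8, altitude = 1489
  )
}

#' Generate seeded synthetic daily weather
#'
#' Draws a multi-year daily weather series from a [climate_spec()]:
#' Bernoulli-Gamma rainfall by month, cosine seasonal temperature cycles
#' plus a shared AR(1) anomaly (so tmax >= tmin holds by construction with
#' a fixed diurnal floor), monthly humidity with Gaussian noise, log-normal
#' wind, and sunshine as a noisy fraction of daylength reduced on wet days.
#' Output is bit-reproducible for a fixed seed.
#'
#' @param spec A [climate_spec()].
#' @param years Number of calendar years to generate (>= 1).
#' @param seed Integer seed governing every random stream.
#' @param start_year First calendar year of the series.
#' @return A weather data frame passing [validate_weather()].
#' @export
generate_weather <- function(spec, years, seed = 1L, start_year = 2015L) {
  stopifnot(inherits(spec, "climate_spec"))
  if (years < 1) stop("years must be >= 1")
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1L)),
               by = "day")
  n <- length(dates)
  doy <- as.integer(strftime(dates, "%j"))
  month <- as.integer(strftime(dates, "%m"))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  # rainfall: monthly Bernoulli occurrence x Gamma amounts
  wet <- stats::runif(n) < spec$rain_prob_by_month[month]
  amounts <- stats::rgamma(n, shape = spec$rain_gamma[1],
                           scale = spec$rain_gamma[2])
  precip <- ifelse(wet, amounts, 0)

  # temperatures: seasonal cosine (peak ~doy 197) + shared AR(1) anomaly
  seas <- cos(2 * pi * (doy - 197) / 365.25)
  anom <- as.numeric(stats::filter(stats::rnorm(n, 0, 2.5), 0.7,
                                   method = "recursive"))
  tmax <- spec$tmax_seasonal[1] + spec$tmax_seasonal[2] * seas + anom +
    stats::rnorm(n, 0, 1)
  tmin <- spec$tmin_seasonal[1] + spec$tmin_seasonal[2] * seas + anom +
    stats::rnorm(n, 0, 1)
  low <- tmax - tmin < spec$diurnal_floor
  tmax[low] <- tmin[low] + spec$diurnal_floor

  rh <- pmin(pmax(spec$rh_by_month[month] + stats::rnorm(n, 0, 8), 5), 100)
  wind <- stats::rlnorm(n, spec$wind_lognorm[1], spec$wind_lognorm[2])
  daylen <- vapply(doy, daylight_hours, numeric(1), latitude = spec$latitude)
  frac <- pmin(pmax(spec$sunshine_frac + stats::rnorm(n, 0, 0.15), 0.05), 1)
  frac[wet] <- frac[wet] * 0.5
  sunshine <- frac * daylen

  weather <- data.frame(
    date = dates, tmax = tmax, tmin = tmin, precip = precip,
    sunshine_hours = sunshine, rh_mean = rh, wind_u2 = wind
  )
  validate_weather(weather)
  weather
}

#' Sample noisy observations from a simulated trajectory
#'
#' Emulates field measurement of canopy cover or biomass: the daily "truth"
#' trajectory is sampled at the given dates and perturbed with iid Gaussian
#' noise, then clipped to the variable's validity range (canopy cover to
#' \[0, 100\] %, biomass to non-negative values).
#'
#' @param truth Data frame with columns `date` and `value` (daily truth).
#' @param sampling_dates Dates at which observations are taken; all must lie
#'   within the truth's span.
#' @param noise_sd Measurement noise standard deviation, in the variable's
#'   units.
#' @param variable `"canopy_cover"` (% units) or `"biomass"` (t/ha).
#' @param seed Integer seed.
#' @return Data frame `date`, `variable`, `value`.
#' @export
generate_observations <- function(truth, sampling_dates, noise_sd,
                                  variable = c("canopy_cover", "biomass"),
                                  seed = 1L) {
  variable <- match.arg(variable)
  stopifnot(noise_sd >= 0)
  truth$date <- as.Date(truth$date)
  sampling_dates <- as.Date(sampling_dates)
  outside <- sampling_dates[sampling_dates < min(truth$date) |
                              sampling_dates > max(truth$date)]
  if (length(outside)) {
    stop("sampling date outside the truth's span: ", paste(outside[1]))
  }
  idx <- match(sampling_dates, truth$date)
  if (anyNA(idx)) {
    stop("sampling date not present in the truth series: ",
         paste(sampling_dates[which(is.na(idx))[1]]))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  values <- truth$value[idx] + stats::rnorm(length(idx), 0, noise_sd)
  values <- if (variable == "canopy_cover") pmin(pmax(values, 0), 100)
            else pmax(values, 0)
  data.frame(date = sampling_dates, variable = variable, value = values)
}

# Fixtures -------------------------------------------------------------------

fixture_registry <- c("table1_treatments", "table2_stage_allocation",
                      "table3_soil", "table4_crop_params", "table5_scenarios",
                      "table6_scenarioI", "table7_scenarioII")

#' List the packaged reference tables
#'
#' @return Character vector of fixture names accepted by [load_fixture()].
#' @export
fixture_names <- function() fixture_registry

#' Load a packaged reference table
#'
#' The package ships the published experimental-design and scenario-result
#' tables (field treatments, growth-stage irrigation allocation, soil
#' hydraulic properties, calibrated crop parameters, the 30-scheme scenario
#' grid and the two scenario result tables) as plain CSVs, transcribed
#' verbatim. Result tables are evidence for the selection and fitting
#' routines, not simulator output.
#'
#' @param name One of [fixture_names()].
#' @return A data frame.
#' @export
load_fixture <- function(name) {
  if (!name %in% fixture_registry) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_registry, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "aquadrip")
  if (path == "") {
    # source-tree fallback for development
    path <- file.path("inst", "extdata", paste0(name, ".csv"))
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}
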