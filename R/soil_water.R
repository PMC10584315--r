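#' Layered soil profile
#'
#' Builds a validated soil profile from per-layer hydraulic properties.
#' Layers must be contiguous from the surface and each must satisfy
#' 0 < wilting point < field capacity < saturation < 1.
#'
#' @param layers Data frame with columns `top_cm`, `bottom_cm`, `theta_wp`,
#'   `theta_fc`, `theta_sat`, `bulk_density` (the soil-table CSV schema).
#' @return A `soil_profile` object (the validated data frame).
#' @export
soil_profile <- function(layers) {
  req <- c("top_cm", "bottom_cm", "theta_wp", "theta_fc", "theta_sat")
  missing_cols <- setdiff(req, names(layers))
  if (length(missing_cols)) {
    stop("soil table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  layers <- layers[order(layers$top_cm), , drop = FALSE]
  if (layers$top_cm[1] != 0) stop("layers must start at 0 cm")
  if (nrow(layers) > 1 &&
      any(layers$top_cm[-1] != layers$bottom_cm[-nrow(layers)])) {
    stop("layers must be contiguous")
  }
  with(layers, {
    if (any(bottom_cm <= top_cm)) stop("bottom_cm must exceed top_cm")
    if (any(!(0 < theta_wp & theta_wp < theta_fc & theta_fc < theta_sat &
                theta_sat < 1))) {
      stop("each layer needs 0 < theta_wp < theta_fc < theta_sat < 1")
    }
  })
  structure(layers, class = c("soil_profile", "data.frame"))
}

#' Read a soil profile CSV
#'
#' @param path CSV in the soil-table schema (see [soil_profile()]).
#' @return A `soil_profile`.
#' @export
read_soil_csv <- function(path) {
  soil_profile(utils::read.csv(path, stringsAsFactors = FALSE))
}

profile_depth_m <- function(profile) max(profile$bottom_cm) / 100

# thickness (mm) of each layer lying within the top `depth_m` of soil
layer_mm_within <- function(profile, depth_m) {
  depth_cm <- depth_m * 100
  pmax(pmin(profile$bottom_cm, depth_cm) - pmin(profile$top_cm, depth_cm), 0) * 10
}

#' Total available water of the root zone
#'
#' Water held between field capacity and wilting point over the current
#' rooting depth, TAW = sum over layers of (theta_fc - theta_wp) * depth,
#' with the deepest rooted layer prorated.
#'
#' @param profile A [soil_profile()].
#' @param root_depth Rooting depth in metres (must not exceed the profile).
#' @return TAW in mm.
#' @export
total_available_water <- function(profile, root_depth) {
  if (root_depth < 0) stop("root_depth must be non-negative")
  if (root_depth > profile_depth_m(profile) + 1e-9) {
    stop("root_depth exceeds the described soil profile")
  }
  sum((profile$theta_fc - profile$theta_wp) * layer_mm_within(profile, root_depth))
}

#' Depletion-driven water stress coefficient
#'
#' Ks as a function of relative root-zone depletion Dr/TAW: 1 (no stress)
#' while depletion is at or below the upper threshold, 0 at or beyond the
#' lower threshold, with a linear (default) or convex transition between.
#'
#' @param dr Root-zone depletion (mm, >= 0).
#' @param taw Total available water (mm, > 0).
#' @param thr_upper,thr_lower Thresholds as fractions of TAW,
#'   0 <= upper < lower <= 1.
#' @param shape `"linear"` or `"convex"` transition.
#' @return Ks in \[0, 1\], non-increasing in `dr`.
#' @export
stress_coefficient <- function(dr, taw, thr_upper, thr_lower,
                               shape = c("linear", "convex")) {
  shape <- match.arg(shape)
  if (any(thr_upper >= thr_lower)) {
    stop("thr_upper must be strictly below thr_lower")
  }
  stopifnot(taw > 0, all(dr >= 0))
  drel <- dr / taw
  srel <- (drel - thr_upper) / (thr_lower - thr_upper) # 0..1 across the band
  srel <- pmin(pmax(srel, 0), 1)
  if (shape == "linear") {
    1 - srel
  } else {
    fshape <- 3
    1 - (exp(srel * fshape) - 1) / (exp(fshape) - 1)
  }
}

#' Linear root deepening
#'
#' Rooting depth grows linearly from `z_min` at planting to `z_max` by the
#' day the canopy reaches its maximum, then stays constant.
#'
#' @param day_index Days after planting (>= 0).
#' @param z_min Initial effective depth (m).
#' @param z_max Maximum effective root depth (m).
#' @param max_day Day after planting at which `z_max` is reached.
#' @return Rooting depth in metres, non-decreasing in `day_index`.
#' @export
update_root_depth <- function(day_index, z_min = 0.20, z_max = 0.45,
                              max_day = 110) {
  stopifnot(all(day_index >= 0), z_max >= z_min, max_day > 0)
  pmin(z_min + (z_max - z_min) * day_index / max_day, z_max)
}

#' Initial soil water state
#'
#' @param profile A [soil_profile()].
#' @param init `"fc"` for a profile at field capacity, or a number in
#'   \[0, 1\] giving the fraction of TAW-above-wilting filled per layer.
#' @param root_depth Initial rooting depth (m).
#' @return A `water_state` list: per-layer theta, root depth, TAW, depletion
#'   and zeroed cumulative fluxes.
#' @export
initial_water_state <- function(profile, init = "fc", root_depth = 0.20) {
  theta <- if (identical(init, "fc")) {
    profile$theta_fc
  } else {
    stopifnot(is.numeric(init), init >= 0, init <= 1)
    profile$theta_wp + init * (profile$theta_fc - profile$theta_wp)
  }
  state <- list(theta = theta, root_depth = root_depth,
                taw = total_available_water(profile, root_depth), dr = 0,
                drainage_cum = 0, e_cum = 0, tr_cum = 0)
  state$dr <- root_zone_depletion(profile, theta, root_depth)
  class(state) <- "water_state"
  state
}

root_zone_depletion <- function(profile, theta, root_depth) {
  mm <- layer_mm_within(profile, root_depth)
  sum(pmax(profile$theta_fc - theta, 0) * mm)
}

storage_mm <- function(profile, theta) {
  sum(theta * (profile$bottom_cm - profile$top_cm) * 10)
}

#' One day of the layered bucket water balance
#'
#' Applies, in order: infiltration of rain plus drip irrigation into the top
#' layer with an instantaneous cascade of any excess above field capacity to
#' the next layer (excess leaving the bottom layer is deep drainage); soil
#' evaporation from a thin surface depth (0.10 m) of the top layer, reduced
#' by a quadratic drying coefficient between field capacity and the air-dry
#' floor (0.5 * wilting point), approximating two-stage drying;
#' then transpiration extracted over the root zone in proportion to each
#' rooted layer's plant-available water. Realized fluxes never exceed demand nor
#' available water and the balance closes to machine precision.
#'
#' @param state A `water_state` (see [initial_water_state()]).
#' @param profile A [soil_profile()].
#' @param rain,irrigation Water inputs (mm, >= 0).
#' @param e_demand,tr_demand Evaporation and transpiration demand (mm, >= 0).
#' @param root_depth Today's rooting depth (m); defaults to the state's.
#' @return A list: updated `state`, and realized `drainage`, `e_real`,
#'   `tr_real` (mm).
#' @export
soil_water_step <- function(state, profile, rain, irrigation,
                            e_demand, tr_demand, root_depth = NULL) {
  stopifnot(rain >= 0, irrigation >= 0, e_demand >= 0, tr_demand >= 0)
  if (is.null(root_depth)) root_depth <- state$root_depth
  theta <- state$theta
  thick <- (profile$bottom_cm - profile$top_cm) * 10 # mm

  # infiltration + cascade drainage
  push <- rain + irrigation
  for (i in seq_along(theta)) {
    if (push <= 0) break
    room <- (profile$theta_fc[i] - theta[i]) * thick[i]
    take <- min(push, max(room, 0))
    theta[i] <- theta[i] + take / thick[i]
    push <- push - take
  }
  drainage <- max(push, 0)

  # soil evaporation from a thin surface depth of the top layer, with a
  # quadratic drying coefficient approximating two-stage evaporation
  theta_ad <- 0.5 * profile$theta_wp[1] # air-dry floor
  z_e <- min(thick[1], 100) # evaporating surface depth, mm of soil
  kr <- (theta[1] - theta_ad) / (profile$theta_fc[1] - theta_ad)
  kr <- min(max(kr, 0), 1)^2
  evap_avail <- max((theta[1] - theta_ad) * z_e, 0)
  e_real <- min(e_demand * kr, evap_avail)
  theta[1] <- theta[1] - e_real / thick[1]

  # transpiration over the root zone, proportional to available water
  mm_in <- layer_mm_within(profile, root_depth)
  avail <- pmax(theta - profile$theta_wp, 0) * mm_in
  tr_real <- min(tr_demand, sum(avail))
  if (tr_real > 0) {
    frac <- avail / sum(avail)
    theta <- theta - (tr_real * frac) / thick
  }

  new_state <- state
  new_state$theta <- theta
  new_state$root_depth <- root_depth
  new_state$taw <- total_available_water(profile, root_depth)
  new_state$dr <- root_zone_depletion(profile, theta, root_depth)
  new_state$drainage_cum <- state$drainage_cum + drainage
  new_state$e_cum <- state$e_cum + e_real
  new_state$tr_cum <- state$tr_cum + tr_real
  list(state = new_state, drainage = drainage, e_real = e_real,
       tr_real = tr_real)
}
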