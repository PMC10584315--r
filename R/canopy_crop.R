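#' Convert leaf area index to canopy cover
#'
#' CC = 1.005 * (1 - exp(-0.6 * LAI))^1.2, capped at full cover. Used to
#' translate field LAI measurements into the model's canopy state variable.
#'
#' @param lai Leaf area index (>= 0).
#' @return Canopy cover as a fraction in \[0, 1\], increasing in `lai`.
#' @examples
#' lai_to_cc(3) # ~0.809
#' @export
lai_to_cc <- function(lai) {
  stopifnot(is.numeric(lai))
  if (any(lai < 0)) stop("lai must be non-negative")
  pmin(1.005 * (1 - exp(-0.6 * lai))^1.2, 1)
}

#' Growing degree days for one day
#'
#' Thermal time from the clipped daily temperature extremes: both are first
#' limited to the `[t_base, t_upper]` band, then the excess of their mean
#' over the base temperature is accumulated.
#'
#' @param tmax,tmin Daily temperature extremes (degC, tmax >= tmin).
#' @param t_base Base temperature below which development stops (degC).
#' @param t_upper Upper temperature limit (degC).
#' @return Degree-days (>= 0).
#' @export
gdd <- function(tmax, tmin, t_base = 10, t_upper = 35) {
  stopifnot(t_base < t_upper)
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  tx <- pmin(pmax(tmax, t_base), t_upper)
  tn <- pmin(pmax(tmin, t_base), t_upper)
  pmax((tx + tn) / 2 - t_base, 0)
}

#' Canopy development parameters
#'
#' Defaults are the calibrated potato values: initial cover 0.9%, maximum
#' cover 94%, canopy growth coefficient 0.966% per growing degree day,
#' canopy decline coefficient 0.798% per growing degree day, thermal limits
#' 10/35 degC. The phase calendar (days after planting) anchors emergence,
#' attainment of maximum canopy, onset of senescence and maturity to the
#' observed potato phenology (canopy still small at 50 DAP, maximal around
#' 110 DAP, growth ceased by about 140-150 DAP).
#'
#' @param cc0 Initial canopy cover at emergence (%).
#' @param cgc Canopy growth coefficient (% per GDD, relative rate).
#' @param ccx Maximum canopy cover (%).
#' @param cdc Canopy decline coefficient (% per GDD).
#' @param t_base,t_upper Thermal-time limits (degC).
#' @param emergence_day,max_canopy_day,senescence_day,maturity_day Phase
#'   calendar in days after planting.
#' @return A `canopy_params` list.
#' @export
canopy_params <- function(cc0 = 0.9, cgc = 0.966, ccx = 94, cdc = 0.798,
                          t_base = 10, t_upper = 35, emergence_day = 20,
                          max_canopy_day = 110, senescence_day = 115,
                          maturity_day = 150) {
  stopifnot(0 < cc0, cc0 < ccx, ccx <= 100, cgc > 0, cdc > 0,
            t_base < t_upper,
            emergence_day < max_canopy_day,
            max_canopy_day <= senescence_day,
            senescence_day < maturity_day)
  structure(list(cc0 = cc0, cgc = cgc, ccx = ccx, cdc = cdc,
                 t_base = t_base, t_upper = t_upper,
                 emergence_day = emergence_day,
                 max_canopy_day = max_canopy_day,
                 senescence_day = senescence_day,
                 maturity_day = maturity_day), class = "canopy_params")
}

#' Initial canopy state
#'
#' @param params A [canopy_params()].
#' @return A `canopy_state` list (`cc` fraction, phase, cumulative GDD,
#'   GDD accumulated since senescence onset).
#' @export
initial_canopy_state <- function(params) {
  structure(list(cc = 0, phase = "pre-emergence", gdd_cum = 0, gdd_sen = 0),
            class = "canopy_state")
}

#' Advance the canopy one day
#'
#' Before emergence the cover is zero. From emergence the green cover grows
#' on thermal time at relative rate `cgc` (exponential while below half the
#' maximum, exponentially saturating towards `ccx` above it), scaled by the
#' expansion stress coefficient `ks_exp`; cover within 0.2 percentage point
#' of `ccx` snaps to the plateau. On days when depletion crosses the
#' senescence threshold (`ks_sen` < 1) the cover instead declines at the
#' stress-attenuated rate `cdc * (1 - ks_sen)` per GDD — a recoverable,
#' proportional early senescence. From the calendar senescence day the
#' cover follows the decline envelope
#' `cc = ccx * (1 - 0.05 * (exp(cdc/ccx * gdd) - 1))`,
#' applied as an upper bound so a deficit-reduced canopy never regrows.
#'
#' @param state A `canopy_state`.
#' @param params A [canopy_params()].
#' @param gdd_day Thermal time accrued today (degC day).
#' @param day_index Days after planting.
#' @param ks_exp Expansion stress coefficient in \[0, 1\].
#' @param ks_sen Senescence stress coefficient in \[0, 1\] (1 = no stress).
#' @return The updated `canopy_state`.
#' @export
canopy_step <- function(state, params, gdd_day, day_index,
                        ks_exp = 1, ks_sen = 1) {
  cc <- state$cc
  ccx <- params$ccx / 100
  gdd_cum <- state$gdd_cum + gdd_day
  gdd_sen <- state$gdd_sen
  phase <- state$phase

  if (day_index >= params$maturity_day) {
    phase <- "mature"
  } else if (day_index < params$emergence_day) {
    phase <- "pre-emergence"
    cc <- 0
  } else if (day_index >= params$senescence_day) {
    # calendar senescence: canonical exponential decline from CCx, taken as
    # an upper envelope so deficit-reduced canopies never increase
    phase <- "senescence"
    gdd_sen <- gdd_sen + gdd_day
    envelope <- ccx * (1 - 0.05 * (exp(params$cdc / params$ccx * gdd_sen) - 1))
    cc <- min(cc, max(envelope, 0))
  } else if (phase == "pre-emergence") {
    cc <- params$cc0 / 100 # emergence day: cover starts at CC0
    phase <- "growth"
  } else {
    if (ks_sen < 1) {
      # stress-driven early senescence: proportional, recoverable decline
      cc <- max(cc - params$cdc / 100 * (1 - ks_sen) * gdd_day, 0)
      phase <- "growth"
    } else {
      r <- params$cgc / 100 * ks_exp # relative growth rate per GDD
      dcc <- if (cc <= ccx / 2) r * cc * gdd_day else r * (ccx - cc) * gdd_day
      cc <- min(cc + dcc, ccx)
      if (ccx - cc < 0.002) cc <- ccx # plateau snap
      phase <- if (cc >= ccx) "max" else "growth"
    }
  }

  out <- state
  out$cc <- min(max(cc, 0), ccx)
  out$phase <- phase
  out$gdd_cum <- gdd_cum
  out$gdd_sen <- gdd_sen
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted canopy cover for transpiration
#'
#' The transpiration equation uses an adjusted cover CC* rather than the
#' green cover itself. Under the micro-advective policy (default)
#' `CC* = 1.72 CC - CC^2 + 0.30 CC^3`, which raises the effective cover of
#' partial canopies to account for micro-advective energy supply from the
#' exposed soil; the identity policy uses CC unchanged.
#'
#' @param cc Canopy cover fraction in \[0, 1\].
#' @param policy `"micro_advective"` or `"identity"`.
#' @return Adjusted cover in \[0, 1\].
#' @export
adjust_cc_star <- function(cc, policy = c("micro_advective", "identity")) {
  policy <- match.arg(policy)
  stopifnot(all(cc >= 0 & cc <= 1))
  if (policy == "identity") return(cc)
  pmin(pmax(1.72 * cc - cc^2 + 0.30 * cc^3, 0), 1)
}
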