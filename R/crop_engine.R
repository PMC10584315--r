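#' Water-stress threshold set
#'
#' Fractions of total available water at which each stress process starts
#' (upper) and is complete (lower). Defaults are the calibrated potato
#' values: canopy expansion 0.26-0.66, stomatal closure from 0.65, early
#' canopy senescence from 0.69 (both completing at full depletion).
#'
#' @param p_exp_upper,p_exp_lower Expansion-stress band.
#' @param p_sto_upper Stomatal-closure onset.
#' @param p_sen_upper Early-senescence onset.
#' @param shape Transition shape passed to [stress_coefficient()]; the
#'   simulation default is the convex response typical of crop stress
#'   curves, under which moderate depletion costs little and stress bites
#'   progressively harder towards the lower threshold.
#' @return A `stress_thresholds` list.
#' @export
stress_thresholds <- function(p_exp_upper = 0.26, p_exp_lower = 0.66,
                              p_sto_upper = 0.65, p_sen_upper = 0.69,
                              shape = "convex") {
  stopifnot(0 <= p_exp_upper, p_exp_upper < p_exp_lower, p_exp_lower <= 1,
            0 <= p_sto_upper, p_sto_upper < 1, 0 <= p_sen_upper,
            p_sen_upper < 1)
  structure(list(p_exp_upper = p_exp_upper, p_exp_lower = p_exp_lower,
                 p_sto_upper = p_sto_upper, p_sen_upper = p_sen_upper,
                 shape = shape), class = "stress_thresholds")
}

#' Crop parameter set
#'
#' Bundles the calibrated crop parameters: maximum transpiration coefficient
#' 1.15, normalized water productivity 20 g/m2, reference harvest index 55%,
#' maximum effective root depth 0.45 m, the canopy parameters and stress
#' thresholds, plus two conversion settings the yield chain needs — the
#' tuber dry-matter fraction used to express dry yield as fresh-tuber yield
#' (default 0.11) and the harvest-index adjustment factor `f_hi`
#' (default 1, i.e. no stress adjustment of HI).
#'
#' @param kc_tr_x Maximum crop transpiration coefficient.
#' @param wp_star Normalized water productivity (g biomass per m2 per unit
#'   Tr/ET0).
#' @param hi0 Reference harvest index (%).
#' @param canopy A [canopy_params()].
#' @param thresholds A [stress_thresholds()].
#' @param z_max Maximum effective root depth (m).
#' @param z_min Initial root depth (m).
#' @param dm_fraction Tuber dry-matter fraction in (0, 1].
#' @param f_hi Harvest-index adjustment factor in \[0, 1.2\].
#' @param ke Soil evaporation coefficient for wet bare soil.
#' @param fw Wetted-and-exposed surface fraction for soil evaporation;
#'   drip emitters wet only a small part of the surface, so the
#'   evaporating fraction is `min(1 - CC, fw)` (0.3 is the conventional
#'   drip value).
#' @param cc_star_policy Policy for [adjust_cc_star()].
#' @return A `crop_parameters` list.
#' @export
crop_parameters <- function(kc_tr_x = 1.15, wp_star = 20, hi0 = 55,
                            canopy = canopy_params(),
                            thresholds = stress_thresholds(),
                            z_max = 0.45, z_min = 0.20, dm_fraction = 0.11,
                            f_hi = 1, ke = 1.10, fw = 0.3,
                            cc_star_policy = "micro_advective") {
  stopifnot(0 < hi0, hi0 <= 100, wp_star > 0, 0 < dm_fraction,
            dm_fraction <= 1, f_hi >= 0, f_hi <= 1.2, kc_tr_x > 0,
            z_max >= z_min, fw > 0, fw <= 1)
  structure(list(kc_tr_x = kc_tr_x, wp_star = wp_star, hi0 = hi0,
                 canopy = canopy, thresholds = thresholds, z_max = z_max,
                 z_min = z_min, dm_fraction = dm_fraction, f_hi = f_hi,
                 ke = ke, fw = fw, cc_star_policy = cc_star_policy),
            class = "crop_parameters")
}

#' Daily crop transpiration
#'
#' Tr = Ks * (CC* x KcTr,x) * ET0: atmospheric demand scaled by the adjusted
#' canopy cover, the maximum transpiration coefficient and the (stomatal)
#' water stress coefficient.
#'
#' @param ks Water stress coefficient in \[0, 1\].
#' @param cc_star Adjusted canopy cover fraction in \[0, 1\].
#' @param kc_tr_x Maximum crop transpiration coefficient.
#' @param et0 Reference evapotranspiration (mm/day).
#' @return Transpiration in mm/day, bounded by `kc_tr_x * et0`.
#' @export
transpiration <- function(ks, cc_star, kc_tr_x, et0) {
  stopifnot(all(ks >= 0 & ks <= 1), all(cc_star >= 0 & cc_star <= 1),
            all(et0 >= 0))
  ks * cc_star * kc_tr_x * et0
}

#' Daily biomass increment from normalized transpiration
#'
#' B accrues as WP* times the ET0-normalized transpiration, the
#' water-driven production core: `dB = WP* * Tr / ET0` in g/m2, converted
#' to t/ha (1 g/m2 = 0.01 t/ha). Days without atmospheric demand
#' (ET0 = 0) contribute nothing.
#'
#' @param wp_star Normalized water productivity (g/m2).
#' @param tr Realized transpiration (mm).
#' @param et0 Reference evapotranspiration (mm).
#' @return Biomass increment in t/ha (dry).
#' @export
biomass_increment <- function(wp_star, tr, et0) {
  stopifnot(all(tr >= 0), all(et0 >= 0))
  inc <- ifelse(et0 > 0, wp_star * tr / et0, 0)
  inc * 0.01
}

#' Yield from final biomass via the harvest index
#'
#' Dry tuber yield Y = f_HI * HI0 * B; fresh yield divides by the tuber
#' dry-matter fraction.
#'
#' @param b Final above-ground biomass (t/ha, dry).
#' @param hi0 Reference harvest index (%).
#' @param f_hi Harvest-index adjustment factor.
#' @param dm_fraction Tuber dry-matter fraction (> 0).
#' @return List with `yield_dry` and `yield_fresh` (t/ha).
#' @export
yield_from_biomass <- function(b, hi0, f_hi = 1, dm_fraction = 0.11) {
  stopifnot(b >= 0, hi0 >= 0, f_hi >= 0, f_hi <= 1.2)
  if (dm_fraction <= 0) stop("dm_fraction must be positive")
  yield_dry <- f_hi * hi0 / 100 * b
  list(yield_dry = yield_dry, yield_fresh = yield_dry / dm_fraction)
}

#' Water use efficiency
#'
#' WUE = Y / ET expressed in kg of fresh tuber per m3 of water consumed:
#' with Y in t/ha (1000 kg/ha) and ET in mm (10 m3/ha), WUE = 100 * Y / ET.
#'
#' @param y_fresh Fresh tuber yield (t/ha).
#' @param et_total Seasonal evapotranspiration (mm, > 0).
#' @return WUE in kg/m3.
#' @export
water_use_efficiency <- function(y_fresh, et_total) {
  stopifnot(y_fresh >= 0)
  if (any(et_total <= 0)) stop("et_total must be positive")
  100 * y_fresh / et_total
}

#' Run a full-season daily simulation
#'
#' Integrates the weather forcing, soil water balance, canopy development
#' and production chain day by day from planting to maturity. Each day:
#' ET0 (computed from the weather if absent), thermal time, root deepening,
#' stress coefficients from yesterday's relative depletion, canopy update,
#' transpiration and soil-evaporation demand, the bucket water balance
#' (which caps both fluxes by available water), and the biomass increment
#' from realized transpiration.
#'
#' @param weather Daily weather covering the season; `et0` is computed via
#'   [attach_et0()] when missing (requires `site`).
#' @param soil A [soil_profile()].
#' @param crop A [crop_parameters()].
#' @param plan An [irrigation_plan()] (events outside the season are
#'   ignored); `NULL` for rainfed.
#' @param planting_date Planting date (`Date` or ISO string).
#' @param site A [site_info()], needed only when `et0` must be computed.
#' @param initial_water `"fc"` or a fraction, see [initial_water_state()].
#' @return A `simulation_result`: `daily` data frame (date, et0, rain,
#'   irrigation, e, tr, drainage, cc, cc_star, dr, taw, ks_exp, ks_sto,
#'   ks_sen, root_depth, b_cum) and season totals (`biomass_final`,
#'   `yield_dry`, `yield_fresh`, `et_total`, `wue`, `irrigation_total`,
#'   `rain_total`, `drainage_total`).
#' @export
run_simulation <- function(weather, soil, crop, plan = NULL, planting_date,
                           site = NULL, initial_water = "fc") {
  planting_date <- as.Date(planting_date)
  weather$date <- as.Date(weather$date)
  season_dates <- planting_date + seq_len(crop$canopy$maturity_day) - 1L
  idx <- match(season_dates, weather$date)
  if (anyNA(idx)) {
    stop("weather series lacks ", paste(season_dates[which(is.na(idx))[1]]))
  }
  wx <- weather[idx, , drop = FALSE]
  if (!"et0" %in% names(wx)) {
    if (is.null(site)) stop("weather has no et0 column and no site was given")
    wx <- attach_et0(wx, site)
  }

  irrig <- numeric(nrow(wx))
  if (!is.null(plan)) {
    pos <- match(as.Date(plan$date), season_dates)
    keep <- !is.na(pos)
    irrig[pos[keep]] <- irrig[pos[keep]] + plan$depth_mm[keep]
  }

  n <- nrow(wx)
  wstate <- initial_water_state(soil, initial_water, crop$z_min)
  cstate <- initial_canopy_state(crop$canopy)
  thr <- crop$thresholds
  daily <- data.frame(
    date = wx$date, et0 = wx$et0, rain = wx$precip, irrigation = irrig,
    e = 0, tr = 0, drainage = 0, cc = 0, cc_star = 0, dr = 0, taw = 0,
    ks_exp = 1, ks_sto = 1, ks_sen = 1, root_depth = 0, b_cum = 0
  )
  b_cum <- 0

  for (i in seq_len(n)) {
    day_index <- i - 1L
    root <- update_root_depth(day_index, crop$z_min, crop$z_max,
                              crop$canopy$max_canopy_day)
    taw <- total_available_water(soil, root)
    dr <- root_zone_depletion(soil, wstate$theta, root)
    ks_exp <- stress_coefficient(dr, taw, thr$p_exp_upper, thr$p_exp_lower,
                                 thr$shape)
    ks_sto <- stress_coefficient(dr, taw, thr$p_sto_upper, 1, thr$shape)
    ks_sen <- stress_coefficient(dr, taw, thr$p_sen_upper, 1, thr$shape)

    gdd_day <- gdd(wx$tmax[i], wx$tmin[i], crop$canopy$t_base,
                   crop$canopy$t_upper)
    cstate <- canopy_step(cstate, crop$canopy, gdd_day, day_index,
                          ks_exp = ks_exp, ks_sen = ks_sen)
    cc <- cstate$cc
    cc_star <- adjust_cc_star(cc, crop$cc_star_policy)

    tr_demand <- transpiration(ks_sto, cc_star, crop$kc_tr_x, wx$et0[i])
    e_demand <- crop$ke * min(1 - cc, crop$fw) * wx$et0[i]
    step <- soil_water_step(wstate, soil, wx$precip[i], irrig[i],
                            e_demand, tr_demand, root_depth = root)
    wstate <- step$state
    b_cum <- b_cum + biomass_increment(crop$wp_star, step$tr_real, wx$et0[i])

    daily$e[i] <- step$e_real
    daily$tr[i] <- step$tr_real
    daily$drainage[i] <- step$drainage
    daily$cc[i] <- cc
    daily$cc_star[i] <- cc_star
    daily$dr[i] <- wstate$dr
    daily$taw[i] <- taw
    daily$ks_exp[i] <- ks_exp
    daily$ks_sto[i] <- ks_sto
    daily$ks_sen[i] <- ks_sen
    daily$root_depth[i] <- root
    daily$b_cum[i] <- b_cum
  }

  yields <- yield_from_biomass(b_cum, crop$hi0, crop$f_hi, crop$dm_fraction)
  et_total <- sum(daily$e) + sum(daily$tr)
  structure(list(
    daily = daily,
    biomass_final = b_cum,
    yield_dry = yields$yield_dry,
    yield_fresh = yields$yield_fresh,
    et_total = et_total,
    wue = if (et_total > 0) water_use_efficiency(yields$yield_fresh, et_total)
          else 0,
    irrigation_total = sum(irrig),
    rain_total = sum(wx$precip),
    drainage_total = sum(daily$drainage),
    planting_date = planting_date
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>\n")
  cat(sprintf("  season: %s + %d days\n", format(x$planting_date),
              nrow(x$daily)))
  cat(sprintf("  biomass %.2f t/ha, yield %.2f t/ha fresh (%.2f dry)\n",
              x$biomass_final, x$yield_fresh, x$yield_dry))
  cat(sprintf("  ET %.0f mm, irrigation %.0f mm, rain %.0f mm, WUE %.2f kg/m3\n",
              x$et_total, x$irrigation_total, x$rain_total, x$wue))
  invisible(x)
}

#' Write the daily trajectory of a simulation to CSV
#'
#' @param result A `simulation_result`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_daily_csv <- function(result, path) {
  out <- result$daily
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
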