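#' Run the scenario grid over multiple weather years
#'
#' Simulates every scheme of a scenario grid (see [build_scenario_grid()])
#' for each supplied weather year and averages the season outputs across
#' years — the multi-year scenario study. Irrigation events follow the
#' fixed quota x cycle schedule starting at the observed first-irrigation
#' date (May 18 of each year by default).
#'
#' @param grid Scenario grid data frame (`scheme`, `quota_mm`, `cycle_days`,
#'   `n_events`, `total_m3_ha`).
#' @param weather Weather data frame spanning all requested years (with or
#'   without `et0`).
#' @param soil A [soil_profile()].
#' @param crop A [crop_parameters()].
#' @param years Calendar years to simulate.
#' @param site A [site_info()] (needed if `et0` is absent).
#' @param planting_mmdd,irrigation_start_mmdd Month-day anchors for planting
#'   and the first irrigation event.
#' @param initial_water Initial soil water condition per season.
#' @return A `scenario_results` data frame: one row per scheme with
#'   multi-year mean `yield_t_ha`, `biomass_t_ha`, `wue_kg_m3`, `et_mm`,
#'   and a `per_year` attribute holding the year-by-year breakdown.
#' @export
run_scenario_set <- function(grid, weather, soil, crop, years, site = NULL,
                             planting_mmdd = "04-30",
                             irrigation_start_mmdd = "05-18",
                             initial_water = "fc") {
  weather$date <- as.Date(weather$date)
  if (!"et0" %in% names(weather)) {
    if (is.null(site)) stop("weather has no et0 column and no site was given")
    weather <- attach_et0(weather, site)
  }
  per_year <- do.call(rbind, lapply(years, function(yr) {
    planting <- as.Date(sprintf("%d-%s", yr, planting_mmdd))
    irr_start <- as.Date(sprintf("%d-%s", yr, irrigation_start_mmdd))
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      plan <- build_fixed_plan(irr_start, grid$quota_mm[i],
                               grid$cycle_days[i], grid$n_events[i])
      sim <- run_simulation(weather, soil, crop, plan, planting,
                            initial_water = initial_water)
      data.frame(scheme = grid$scheme[i], year = yr,
                 yield_t_ha = sim$yield_fresh,
                 biomass_t_ha = sim$biomass_final,
                 wue_kg_m3 = sim$wue, et_mm = sim$et_total,
                 total_m3_ha = grid$total_m3_ha[i])
    }))
  }))
  agg <- stats::aggregate(
    per_year[c("yield_t_ha", "biomass_t_ha", "wue_kg_m3", "et_mm")],
    by = list(scheme = per_year$scheme), FUN = mean
  )
  results <- merge(grid, agg, by = "scheme", sort = FALSE)
  results <- results[match(grid$scheme, results$scheme), , drop = FALSE]
  rownames(results) <- NULL
  attr(results, "per_year") <- per_year
  class(results) <- c("scenario_results", "data.frame")
  results
}

#' Quadratic irrigation-yield response fit
#'
#' Least-squares fit of `yield = a + b x + c x^2` to (total irrigation
#' volume, yield) pairs — the classic diminishing-returns water production
#' function whose vertex `-b/(2c)` locates the irrigation volume of maximum
#' yield when the curve is concave.
#'
#' @param points Data frame with columns `total_m3_ha` and `yield_t_ha` (at
#'   least 3 distinct x values).
#' @return A `quadratic_fit` list: coefficients `a`, `b`, `c`, `r2`,
#'   `vertex_x` (NA when `c` is zero), `n_points`.
#' @export
fit_yield_response <- function(points) {
  x <- points$total_m3_ha
  y <- points$yield_t_ha
  if (length(unique(x)) < 3) stop("need at least 3 distinct irrigation totals")
  fit <- stats::lm(y ~ x + I(x^2))
  co <- unname(stats::coef(fit))
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(a = co[1], b = co[2], c = co[3], r2 = r2,
                 vertex_x = if (co[3] != 0) -co[2] / (2 * co[3]) else NA_real_,
                 n_points = length(x)), class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> y = %.4g + %.4g x + %.4g x^2 (n=%d)\n",
              x$a, x$b, x$c, x$n_points))
  cat(sprintf("  R2 = %.3f; vertex at x = %.0f\n", x$r2, x$vertex_x))
  invisible(x)
}

#' Select the best scheme under a criterion
#'
#' Argmax of yield or water use efficiency over scenario results, with ties
#' broken in favour of less total irrigation water, then by scheme order.
#'
#' @param results Data frame with `scheme`, `total_m3_ha` and the criterion
#'   columns (`yield_t_ha`, `wue_kg_m3`).
#' @param criterion `"yield"` or `"wue"`.
#' @param subset Optional logical vector or scheme-id character vector
#'   restricting the candidates.
#' @return A list: `scheme`, `value`, and the selected `row`.
#' @export
select_optimal <- function(results, criterion = c("yield", "wue"),
                           subset = NULL) {
  criterion <- match.arg(criterion)
  if (!is.null(subset)) {
    results <- if (is.character(subset)) {
      results[results$scheme %in% subset, , drop = FALSE]
    } else results[subset, , drop = FALSE]
  }
  if (nrow(results) == 0) stop("no candidate schemes after filtering")
  col <- if (criterion == "yield") "yield_t_ha" else "wue_kg_m3"
  ord <- order(-results[[col]], results$total_m3_ha,
               seq_len(nrow(results)))
  best <- results[ord[1], , drop = FALSE]
  list(scheme = best$scheme, value = best[[col]], row = best)
}

#' Season-summary table in the scenario-report layout
#'
#' @param results A `scenario_results` data frame.
#' @param digits Decimals for display rounding (full precision is kept in
#'   the returned CSV-ready frame when `digits = NA`).
#' @return Data frame with columns `scheme`, `quota_mm`, `cycle_days`,
#'   `n_events`, `yield_t_ha`, `biomass_t_ha`, `wue_kg_m3`, `et_mm`.
#' @export
report_tables <- function(results, digits = NA) {
  cols <- c("scheme", "quota_mm", "cycle_days", "n_events",
            "yield_t_ha", "biomass_t_ha", "wue_kg_m3", "et_mm")
  out <- as.data.frame(results)[, intersect(cols, names(results)),
                                drop = FALSE]
  if (!is.na(digits)) {
    num <- c("yield_t_ha", "biomass_t_ha", "wue_kg_m3", "et_mm")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' The printed 5-day-cycle yield-response points
#'
#' Convenience accessor for the quadratic fit: extracts the
#' (total volume, yield) pairs for one irrigation cycle from a results
#' table (packaged fixture or simulation output).
#'
#' @param results Data frame with `cycle_days`, `yield_t_ha` and a total
#'   volume column (`total_m3_ha`, or derivable from `quota_mm * n_events`
#'   or `amount_mm`).
#' @param cycle_days Irrigation cycle to select.
#' @return Data frame `total_m3_ha`, `yield_t_ha`.
#' @export
yield_response_points <- function(results, cycle_days = 5) {
  rows <- results[results$cycle_days == cycle_days, , drop = FALSE]
  total <- if ("total_m3_ha" %in% names(rows)) {
    rows$total_m3_ha
  } else if (all(c("quota_mm", "n_events") %in% names(rows))) {
    mm_to_m3_ha(rows$quota_mm * rows$n_events)
  } else if ("amount_mm" %in% names(rows)) {
    mm_to_m3_ha(rows$amount_mm)
  } else stop("cannot derive total irrigation volume from these columns")
  data.frame(total_m3_ha = total, yield_t_ha = rows$yield_t_ha)
}
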