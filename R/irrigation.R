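#' Convert an irrigation depth to a volume per hectare
#'
#' 1 mm of water over one hectare is 10 m3.
#'
#' @param depth_mm Depth in mm (>= 0).
#' @return Volume in m3/ha.
#' @export
mm_to_m3_ha <- function(depth_mm) {
  stopifnot(all(depth_mm >= 0))
  10 * depth_mm
}

#' Irrigation plan
#'
#' An ordered set of drip irrigation events (date, depth in mm).
#'
#' @param dates Event dates, strictly increasing.
#' @param depth_mm Event depths in mm (> 0), recycled to the dates.
#' @param label Optional plan label.
#' @return An `irrigation_plan` data frame with columns `date`, `depth_mm`.
#' @export
irrigation_plan <- function(dates, depth_mm, label = "") {
  dates <- as.Date(dates)
  depth_mm <- rep_len(depth_mm, length(dates))
  if (any(depth_mm <= 0)) stop("event depths must be positive")
  if (length(dates) > 1 && any(diff(dates) <= 0)) {
    stop("event dates must be strictly increasing")
  }
  structure(data.frame(date = dates, depth_mm = depth_mm),
            class = c("irrigation_plan", "data.frame"), label = label)
}

#' Total depth of a plan
#'
#' @param plan An [irrigation_plan()].
#' @return Sum of event depths (mm).
#' @export
plan_total <- function(plan) sum(plan$depth_mm)

#' Fixed quota-by-cycle irrigation schedule
#'
#' Events every `cycle_days` starting at `start_date`, each applying
#' `quota_mm` — the quota x cycle schedule of the scenario study. The
#' default irrigation window mirrors the field practice (first event
#' May 18, last by August 26).
#'
#' @param start_date First event date.
#' @param quota_mm Depth per event (mm).
#' @param cycle_days Days between events.
#' @param n_events Number of events.
#' @param season_end Optional latest allowed event date; events past it are
#'   an error.
#' @return An [irrigation_plan()].
#' @export
build_fixed_plan <- function(start_date, quota_mm, cycle_days, n_events,
                             season_end = NULL) {
  stopifnot(n_events >= 1, cycle_days >= 1, quota_mm > 0)
  start_date <- as.Date(start_date)
  dates <- start_date + cycle_days * (seq_len(n_events) - 1L)
  if (!is.null(season_end) && max(dates) > as.Date(season_end)) {
    stop("plan extends past the season end (", paste(as.Date(season_end)), ")")
  }
  irrigation_plan(dates, quota_mm,
                  label = sprintf("%gmm_x%d_every%dd", quota_mm, n_events,
                                  cycle_days))
}

#' The 30-scheme scenario grid
#'
#' Scenario I fixes the season irrigation amount (90-210 mm) and varies the
#' cycle (5/7/10 days with 12/9/6 events; the per-event quota is the amount
#' divided by the event count). Scenario II fixes the per-event quota
#' (10-24 mm) and varies the cycle, so the season total varies. Totals
#' satisfy `total_m3_ha = 10 * quota_mm * n_events` for every scheme.
#'
#' @return Data frame with columns `scheme`, `scenario`, `amount_mm` (season
#'   depth, scenario I), `quota_mm`, `cycle_days`, `n_events`,
#'   `total_m3_ha`.
#' @export
build_scenario_grid <- function() {
  cycles <- c(5, 7, 10)
  events <- c(12, 9, 6)
  amounts <- c(90, 120, 150, 180, 210)
  quotas <- c(10, 13, 18, 20, 24)
  s1 <- expand.grid(cycle_i = 1:3, amount = amounts)[, 2:1]
  grid1 <- data.frame(
    scheme = paste0("A", 1:15), scenario = "I",
    amount_mm = s1$amount,
    quota_mm = s1$amount / events[s1$cycle_i],
    cycle_days = cycles[s1$cycle_i], n_events = events[s1$cycle_i]
  )
  s2 <- expand.grid(cycle_i = 1:3, quota = quotas)[, 2:1]
  grid2 <- data.frame(
    scheme = paste0("A", 16:30), scenario = "II",
    amount_mm = s2$quota * events[s2$cycle_i],
    quota_mm = s2$quota,
    cycle_days = cycles[s2$cycle_i], n_events = events[s2$cycle_i]
  )
  grid <- rbind(grid1, grid2)
  grid$total_m3_ha <- mm_to_m3_ha(grid$quota_mm * grid$n_events)
  grid
}

#' Distribute a season total over growth stages
#'
#' Splits `total_mm` across the five potato growth stages according to a
#' stage allocation table (percentage and event count per stage, as in the
#' field experiment), placing each stage's events evenly through its window.
#'
#' @param total_mm Season irrigation depth (mm).
#' @param allocation Data frame with columns `stage`, `window_start`,
#'   `window_end` (dates or "mm-dd"), `pct`, `events`; percentages must sum
#'   to 100.
#' @param year Calendar year used to resolve "mm-dd" windows.
#' @return An [irrigation_plan()] whose total equals `total_mm`.
#' @export
allocate_by_stage <- function(total_mm, allocation, year = 2020) {
  stopifnot(total_mm > 0)
  if (abs(sum(allocation$pct) - 100) > 1e-6) {
    stop("stage percentages must sum to 100")
  }
  bad <- allocation$events > 0 & allocation$pct <= 0
  if (any(bad)) {
    stop("stage '", allocation$stage[which(bad)[1]],
         "' has events but a zero percentage")
  }
  resolve <- function(x) {
    if (all(grepl("^\\d{2}-\\d{2}$", x))) as.Date(paste0(year, "-", x))
    else as.Date(x)
  }
  dates <- list()
  depths <- list()
  for (i in seq_len(nrow(allocation))) {
    k <- allocation$events[i]
    if (k == 0) next
    w0 <- resolve(allocation$window_start[i])
    w1 <- resolve(allocation$window_end[i])
    span <- as.numeric(w1 - w0)
    offsets <- round(span * (seq_len(k)) / (k + 1))
    dates[[length(dates) + 1L]] <- w0 + offsets
    depths[[length(depths) + 1L]] <-
      rep(allocation$pct[i] / 100 * total_mm / k, k)
  }
  irrigation_plan(do.call(c, dates), unlist(depths),
                  label = sprintf("staged_%gmm", total_mm))
}

#' Read and write irrigation plan CSVs
#'
#' Dialect: `date,depth_mm,label`, ISO dates.
#'
#' @param path File path.
#' @return `read_plan_csv` returns an [irrigation_plan()].
#' @export
read_plan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  irrigation_plan(df$date, df$depth_mm,
                  label = if ("label" %in% names(df)) df$label[1] else "")
}

#' @rdname read_plan_csv
#' @param plan Plan to write.
#' @export
write_plan_csv <- function(plan, path) {
  out <- data.frame(date = format(plan$date, "%Y-%m-%d"),
                    depth_mm = plan$depth_mm,
                    label = attr(plan, "label") %||% "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
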