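check_paired <- function(s, m) {
  if (length(s) != length(m)) {
    stop("simulated and measured series differ in length (",
         length(s), " vs ", length(m), ")")
  }
  if (length(s) < 1) stop("empty series")
  if (anyNA(s) || anyNA(m)) stop("paired series must have no missing values")
}

#' Root mean square error
#'
#' `sqrt(mean((Si - Mi)^2))` between simulated (`s`) and measured (`m`)
#' values; zero exactly when the series are identical.
#'
#' @param s Simulated values.
#' @param m Measured values (same length).
#' @return RMSE in the data units.
#' @export
rmse <- function(s, m) {
  check_paired(s, m)
  sqrt(mean((s - m)^2))
}

#' Normalized root mean square error
#'
#' RMSE expressed as a percentage of the measured mean.
#'
#' @inheritParams rmse
#' @return NRMSE in percent.
#' @export
nrmse <- function(s, m) {
  check_paired(s, m)
  m_bar <- mean(m)
  if (m_bar == 0) stop("measured mean is zero; NRMSE undefined")
  rmse(s, m) / m_bar * 100
}

#' Willmott's index of agreement
#'
#' `d = 1 - sum((Si-Mi)^2) / sum((|Si - Mbar| + |Mi - Mbar|)^2)`, bounded
#' in \[0, 1\] with 1 for perfect agreement.
#'
#' @inheritParams rmse
#' @return d, dimensionless.
#' @export
index_of_agreement <- function(s, m) {
  check_paired(s, m)
  m_bar <- mean(m)
  denom <- sum((abs(s - m_bar) + abs(m - m_bar))^2)
  if (denom == 0) {
    stop("index of agreement undefined: all values equal the measured mean")
  }
  1 - sum((s - m)^2) / denom
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' `R2 = [sum((Si-Sbar)(Mi-Mbar))]^2 / (sum((Si-Sbar)^2) sum((Mi-Mbar)^2))`.
#'
#' @inheritParams rmse
#' @return R2 in \[0, 1\].
#' @export
r_squared <- function(s, m) {
  check_paired(s, m)
  if (length(s) < 2) stop("R2 needs at least two points")
  ss <- sum((s - mean(s))^2)
  mm <- sum((m - mean(m))^2)
  if (ss == 0 || mm == 0) {
    stop("R2 undefined: a series has zero variance")
  }
  sum((s - mean(s)) * (m - mean(m)))^2 / (ss * mm)
}

#' All four goodness-of-fit statistics
#'
#' @inheritParams rmse
#' @return A one-row data frame: `n`, `rmse`, `nrmse`, `d`, `r2`.
#' @export
goodness_of_fit <- function(s, m) {
  data.frame(n = length(s), rmse = rmse(s, m), nrmse = nrmse(s, m),
             d = index_of_agreement(s, m), r2 = r_squared(s, m))
}

#' Evaluate a simulation against observed series
#'
#' Aligns observations to the simulated daily trajectory by date (exact
#' match first, otherwise the nearest simulated day within one day) and
#' computes RMSE, NRMSE, the index of agreement and R2. Canopy cover is
#' compared in percent, biomass in t/ha.
#'
#' @param sim A `simulation_result` from [run_simulation()].
#' @param obs Observation data frame `date`, `variable`, `value` (see
#'   [generate_observations()]).
#' @param variable `"canopy_cover"` or `"biomass"`.
#' @return A one-row data frame as from [goodness_of_fit()], plus
#'   `variable`.
#' @export
evaluate_simulation <- function(sim, obs,
                                variable = c("canopy_cover", "biomass")) {
  variable <- match.arg(variable)
  obs <- obs[obs$variable == variable, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations of ", variable)
  obs_dates <- as.Date(obs$date)
  sim_dates <- sim$daily$date
  idx <- match(obs_dates, sim_dates)
  for (j in which(is.na(idx))) {
    gap <- abs(as.numeric(sim_dates - obs_dates[j]))
    if (min(gap) <= 1) idx[j] <- which.min(gap)
  }
  if (anyNA(idx)) {
    stop("no simulated day within 1 day of ", paste(obs_dates[which(is.na(idx))[1]]))
  }
  s <- if (variable == "canopy_cover") sim$daily$cc[idx] * 100
       else sim$daily$b_cum[idx]
  out <- goodness_of_fit(s, obs$value)
  cbind(variable = variable, out)
}

#' Qualitative rating of goodness-of-fit statistics
#'
#' Applies the interpretation bands used in calibration reports: NRMSE below
#' 10% "very good", below 30% "moderate"; d and R2 above 0.9 "excellent".
#'
#' @param fit A row from [goodness_of_fit()].
#' @return Named character vector of ratings.
#' @export
rate_fit <- function(fit) {
  c(nrmse = if (fit$nrmse < 10) "very good" else if (fit$nrmse < 30)
      "moderate" else "poor",
    d = if (fit$d > 0.9) "excellent" else "fair",
    r2 = if (fit$r2 > 0.9) "excellent" else "fair")
}
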