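# shared builders for the test suite; everything is generated in code

test_site <- function() site_info(latitude = 36.8, altitude = 1489,
                                  station_id = "synthetic")

test_soil <- function() soil_profile(load_fixture("table3_soil"))

# constant warm weather with a prescribed et0 column: lets canopy/engine
# tests control thermal time and demand exactly
warm_weather <- function(n, start = "2020-04-30", tmax = 30, tmin = 20,
                         precip = 0, et0 = 5) {
  data.frame(
    date = as.Date(start) + seq_len(n) - 1L,
    tmax = tmax, tmin = tmin, precip = precip,
    sunshine_hours = 9, rh_mean = 50, wind_u2 = 2, et0 = et0
  )
}

# straight-line independent FAO-56 chain (kept free of package internals
# except the public Tetens helpers' formulas, re-derived inline)
fao56_et0_oracle <- function(tmax, tmin, rh, sun, u2, doy, lat, alt) {
  es0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  t_mean <- (tmax + tmin) / 2
  delta <- 4098 * es0(t_mean) / (t_mean + 237.3)^2
  gamma <- 0.665e-3 * 101.3 * ((293 - 0.0065 * alt) / 293)^5.26
  es <- (es0(tmax) + es0(tmin)) / 2
  ea <- rh / 100 * es
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmax(pmin(-tan(phi) * tan(decl), 1), -1))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  nmax <- 24 / pi * ws
  rs <- (0.25 + 0.50 * min(sun, nmax) / nmax) * ra
  rso <- (0.75 + 2e-5 * alt) * ra
  rns <- 0.77 * rs
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * min(rs / rso, 1) - 0.35)
  rn <- rns - rnl
  et0 <- (0.408 * delta * rn +
            gamma * 900 / (t_mean + 273) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
  max(et0, 0)
}

# brute-force goodness-of-fit formulas, written as explicit loops
brute_gof <- function(s, m) {
  n <- length(s)
  sq <- 0
  for (i in seq_len(n)) sq <- sq + (s[i] - m[i])^2
  m_bar <- sum(m) / n
  s_bar <- sum(s) / n
  den_d <- 0
  for (i in seq_len(n)) den_d <- den_d + (abs(s[i] - m_bar) + abs(m[i] - m_bar))^2
  num_r <- 0; den_s <- 0; den_m <- 0
  for (i in seq_len(n)) {
    num_r <- num_r + (s[i] - s_bar) * (m[i] - m_bar)
    den_s <- den_s + (s[i] - s_bar)^2
    den_m <- den_m + (m[i] - m_bar)^2
  }
  list(rmse = sqrt(sq / n), nrmse = sqrt(sq / n) / m_bar * 100,
       d = 1 - sq / den_d, r2 = num_r^2 / (den_s * den_m))
}

# normal-equations quadratic least squares, independent of stats::lm;
# solved in a centred/scaled basis for conditioning, mapped back after
brute_quadfit <- function(x, y) {
  mu <- mean(x); sg <- stats::sd(x)
  z <- (x - mu) / sg
  X <- cbind(1, z, z^2)
  cz <- solve(t(X) %*% X, t(X) %*% y)
  c2 <- cz[3] / sg^2
  b <- cz[2] / sg - 2 * mu * cz[3] / sg^2
  a <- cz[1] - cz[2] * mu / sg + cz[3] * mu^2 / sg^2
  yhat <- a + b * x + c2 * x^2
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, c = c2, r2 = r2, vertex_x = -b / (2 * c2))
}

# a dry-climate spec: near-zero rainfall so irrigation dominates supply
dry_climate <- function() {
  spec <- ningxia_climate()
  spec$rain_prob_by_month <- rep(0.02, 12)
  spec
}
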