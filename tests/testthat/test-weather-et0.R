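test_that("vapour pressure and psychrometric terms match hand evaluations", {
  expect_equal(saturation_vapour_pressure(20), 2.338, tolerance = 1e-3)
  expect_equal(saturation_vapour_pressure(0), 0.6108)
  expect_gt(saturation_vapour_pressure(25), saturation_vapour_pressure(20))

  expect_equal(slope_vapour_curve(20), 0.1447, tolerance = 1e-3)
  expect_gt(slope_vapour_curve(30), slope_vapour_curve(20))
  expect_true(is.finite(slope_vapour_curve(0)))

  expect_equal(psychrometric_constant(1489), 0.0565, tolerance = 1e-3)
  expect_equal(psychrometric_constant(0), 0.0674, tolerance = 1e-3)
  expect_lt(psychrometric_constant(2000), psychrometric_constant(0))
})

test_that("terms are positive across the valid domain", {
  t <- seq(-35, 50, length.out = 200)
  expect_true(all(saturation_vapour_pressure(t) > 0))
  expect_true(all(slope_vapour_curve(t) > 0))
  expect_true(all(psychrometric_constant(seq(-400, 4000, by = 100)) > 0))
  expect_error(saturation_vapour_pressure(-45), "out of range")
})

test_that("extraterrestrial radiation and daylength behave at anchors", {
  # equinox at the equator
  expect_equal(extraterrestrial_radiation(0, 80), 37.6, tolerance = 0.01)
  expect_equal(daylight_hours(0, 80), 12, tolerance = 0.1)
  # polar night is rejected
  expect_error(daylight_hours(75, 355), "polar night")
})

test_that("net radiation increases with sunshine and stays below solar input", {
  site <- test_site()
  day <- list(date = as.Date("2020-07-01"), tmax = 30, tmin = 16,
              sunshine_hours = 4, rh_mean = 50)
  day2 <- day; day2$sunshine_hours <- 8
  expect_gt(net_radiation(day2, site), net_radiation(day, site))
  ra <- extraterrestrial_radiation(site$latitude, 183)
  expect_lt(net_radiation(day2, site), ra)
})

test_that("the combination equation reproduces the worked case", {
  terms <- structure(list(rn = 13.28, g = 0, t_mean = 20, u2 = 2,
                          es = 2.0, ea = 1.0, delta = 0.145, gamma = 0.066),
                     class = "penman_terms")
  expect_equal(et0_penman_monteith(terms), 4.66, tolerance = 0.005)
  # both numerator terms vanish
  terms0 <- terms; terms0$rn <- 0; terms0$u2 <- 0
  expect_equal(et0_penman_monteith(terms0), 0)
  # aerodynamic term is monotone in wind when a vapour deficit exists
  terms3 <- terms; terms3$u2 <- 3
  expect_gt(et0_penman_monteith(terms3), et0_penman_monteith(terms))
})

test_that("attach_et0 agrees with an independent FAO-56 chain on random days", {
  set.seed(101)
  n <- 1000
  lat <- runif(n, -60, 60)
  alt <- runif(n, 0, 3000)
  tmin <- runif(n, -10, 25)
  tmax <- tmin + runif(n, 1, 18)
  rh <- runif(n, 10, 95)
  u2 <- runif(n, 0, 8)
  doy <- sample(365, n, replace = TRUE)
  sun <- runif(n, 0, 10)
  for (i in sample(n, 250)) { # spot-check a quarter for speed
    day <- data.frame(date = as.Date("2019-12-31") + doy[i], tmax = tmax[i],
                      tmin = tmin[i], precip = 0, sunshine_hours = sun[i],
                      rh_mean = rh[i], wind_u2 = u2[i])
    site <- site_info(lat[i], alt[i])
    got <- suppressWarnings(
      et0_penman_monteith(penman_terms(day, site))
    )
    want <- fao56_et0_oracle(tmax[i], tmin[i], rh[i], sun[i], u2[i],
                             as.integer(strftime(day$date, "%j")),
                             lat[i], alt[i])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("attach_et0 is idempotent, order-invariant and bounded", {
  w <- generate_weather(ningxia_climate(), years = 1, seed = 3)
  site <- test_site()
  w1 <- attach_et0(w, site)
  expect_true(all(w1$et0 > 0 & w1$et0 < 16))
  # idempotence
  w2 <- attach_et0(w1, site)
  expect_identical(w1$et0, w2$et0)
  # pure per-day computation: reordering input reorders output
  shuffle <- sample(nrow(w))
  w3 <- attach_et0(w[shuffle, ], site)
  expect_equal(w3$et0, w1$et0[shuffle])
  # empty series passes through
  w0 <- attach_et0(w[0, ], site)
  expect_equal(nrow(w0), 0L)
})

test_that("weather CSV dialect round-trips and validates", {
  w <- generate_weather(ningxia_climate(), years = 1, seed = 9)
  w <- attach_et0(w, test_site())
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(w, path)
  w2 <- read_weather_csv(path)
  expect_equal(w2$tmax, w$tmax, tolerance = 1e-12)
  expect_equal(w2$date, w$date)
  expect_equal(w2$et0, w$et0, tolerance = 1e-12)

  bad <- w; bad$tmax[5] <- bad$tmin[5] - 1
  expect_error(validate_weather(bad), "tmax >= tmin")
  bad2 <- w; bad2$rh_mean[3] <- NA
  expect_error(validate_weather(bad2), "missing rh_mean")
})
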