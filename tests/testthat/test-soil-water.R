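test_that("total available water matches the layered hand computation", {
  soil <- test_soil()
  expect_equal(total_available_water(soil, 0.45), 43.5)
  expect_equal(total_available_water(soil, 0), 0)
  # full profile: 0.09*200 + 0.10*200 + 0.11*200 mm
  expect_equal(total_available_water(soil, 0.60), 60.0)
  expect_error(total_available_water(soil, 0.7), "exceeds")
  # increasing in root depth
  depths <- seq(0, 0.6, by = 0.05)
  taw <- vapply(depths, total_available_water, numeric(1), profile = soil)
  expect_true(all(diff(taw) > 0))
})

test_that("stress coefficient hits its thresholds and matches brute force", {
  expect_equal(stress_coefficient(0.20 * 50, 50, 0.26, 0.66), 1)
  expect_equal(stress_coefficient(0.80 * 50, 50, 0.26, 0.66), 0)
  expect_equal(stress_coefficient(0.46 * 50, 50, 0.26, 0.66), 0.5)
  expect_error(stress_coefficient(1, 50, 0.7, 0.6), "strictly below")

  # brute-force piecewise evaluation on a dense grid
  drel <- seq(0, 1.2, length.out = 1000)
  got <- stress_coefficient(drel * 80, 80, 0.26, 0.66)
  want <- vapply(drel, function(x) {
    if (x <= 0.26) 1
    else if (x >= 0.66) 0
    else (0.66 - x) / (0.66 - 0.26)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  # convex variant: bounded, monotone, gentler than linear inside the band
  conv <- stress_coefficient(drel * 80, 80, 0.26, 0.66, shape = "convex")
  expect_true(all(conv >= 0 & conv <= 1))
  expect_true(all(diff(conv) <= 1e-12))
  inside <- drel > 0.27 & drel < 0.65
  expect_true(all(conv[inside] > got[inside]))
})

test_that("root deepening ramps linearly and saturates at z_max", {
  expect_equal(update_root_depth(0), 0.20)
  expect_equal(update_root_depth(110), 0.45)
  expect_equal(update_root_depth(200), 0.45)
  expect_equal(update_root_depth(55), 0.20 + 0.25 * 55 / 110)
  expect_true(all(diff(update_root_depth(0:150)) >= 0))
})

test_that("a quiescent day at field capacity changes nothing", {
  soil <- test_soil()
  st <- initial_water_state(soil)
  out <- soil_water_step(st, soil, 0, 0, 0, 0)
  expect_equal(out$state$theta, st$theta)
  expect_equal(out$drainage, 0)
  expect_equal(out$e_real, 0)
  expect_equal(out$tr_real, 0)
})

test_that("irrigation onto a full profile drains entirely", {
  soil <- test_soil()
  st <- initial_water_state(soil)
  before <- sum(st$theta * (soil$bottom_cm - soil$top_cm) * 10)
  out <- soil_water_step(st, soil, 0, 20, 0, 0)
  after <- sum(out$state$theta * (soil$bottom_cm - soil$top_cm) * 10)
  expect_equal(out$drainage, 20)
  expect_equal(after, before)
})

test_that("transpiration is capped by plant-available water", {
  soil <- test_soil()
  # start just above wilting: 3 mm available in the root zone
  st <- initial_water_state(soil, init = 3 / 43.5, root_depth = 0.45)
  out <- soil_water_step(st, soil, 5, 0, 0, 10, root_depth = 0.45)
  expect_lte(out$tr_real, 8 + 1e-9)
  expect_true(all(out$state$theta >= soil$theta_wp - 1e-12))
})

test_that("the daily balance closes over random seasons", {
  soil <- test_soil()
  set.seed(77)
  for (season in 1:100) {
    st <- initial_water_state(soil, init = runif(1, 0.3, 1),
                              root_depth = 0.45)
    start <- sum(st$theta * (soil$bottom_cm - soil$top_cm) * 10)
    inflow <- 0; out_dr <- 0; out_e <- 0; out_tr <- 0
    for (d in 1:60) {
      rain <- if (runif(1) < 0.2) rgamma(1, 0.7, scale = 12) else 0
      irr <- if (runif(1) < 0.15) 20 else 0
      step <- soil_water_step(st, soil, rain, irr, runif(1, 0, 5),
                              runif(1, 0, 6))
      # per-day closure
      prev <- sum(st$theta * (soil$bottom_cm - soil$top_cm) * 10)
      st <- step$state
      now <- sum(st$theta * (soil$bottom_cm - soil$top_cm) * 10)
      expect_lt(abs(now - prev - (rain + irr - step$drainage -
                                    step$e_real - step$tr_real)), 1e-9)
      inflow <- inflow + rain + irr
      out_dr <- out_dr + step$drainage
      out_e <- out_e + step$e_real
      out_tr <- out_tr + step$tr_real
    }
    end <- sum(st$theta * (soil$bottom_cm - soil$top_cm) * 10)
    expect_lt(abs((end - start) - (inflow - out_dr - out_e - out_tr)), 1e-6)
  }
})

test_that("extra irrigation never increases end-of-day depletion", {
  soil <- test_soil()
  set.seed(123)
  for (k in 1:25) {
    st <- initial_water_state(soil, init = runif(1, 0.2, 0.9),
                              root_depth = 0.45)
    rain <- runif(1, 0, 10); e <- runif(1, 0, 5); tr <- runif(1, 0, 6)
    base <- soil_water_step(st, soil, rain, 0, e, tr)
    more <- soil_water_step(st, soil, rain, runif(1, 1, 25), e, tr)
    expect_lte(more$state$dr, base$state$dr + 1e-9)
  }
})

test_that("soil profiles validate their layering", {
  bad <- load_fixture("table3_soil")
  bad$theta_fc[1] <- 0.05 # below wilting point
  expect_error(soil_profile(bad), "theta_wp < theta_fc")
  gap <- load_fixture("table3_soil")
  gap$top_cm[2] <- 25
  expect_error(soil_profile(gap), "contiguous")
})
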