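test_that("quadratic fits match the normal-equations oracle", {
  # exact parabola
  pts <- data.frame(total_m3_ha = c(-2, -1, 0, 1, 2),
                    yield_t_ha = c(4, 1, 0, 1, 4))
  fit <- fit_yield_response(pts)
  expect_equal(fit$a, 0, tolerance = 1e-9)
  expect_equal(fit$b, 0, tolerance = 1e-9)
  expect_equal(fit$c, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # duplicate point on an exact fit changes nothing
  fit2 <- fit_yield_response(rbind(pts, pts[3, ]))
  expect_equal(fit2$c, fit$c, tolerance = 1e-9)

  set.seed(55)
  for (k in 1:50) {
    n <- sample(4:12, 1)
    x <- sort(runif(n, 500, 3000))
    y <- 5 + 0.03 * x - 6e-6 * x^2 + rnorm(n, 0, 2)
    got <- fit_yield_response(data.frame(total_m3_ha = x, yield_t_ha = y))
    want <- brute_quadfit(x, y)
    expect_equal(got$a, want$a, tolerance = 1e-9)
    expect_equal(got$b, want$b, tolerance = 1e-9)
    expect_equal(got$c, want$c, tolerance = 1e-9)
    expect_equal(got$vertex_x, want$vertex_x, tolerance = 1e-6)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
  }
  expect_error(fit_yield_response(pts[1:2, ]), "distinct")
})

test_that("the pooled 5-day yield response is concave", {
  t6 <- load_fixture("table6_scenarioI")
  t6$total_m3_ha <- mm_to_m3_ha(t6$amount_mm)
  t7 <- load_fixture("table7_scenarioII")
  t7$total_m3_ha <- mm_to_m3_ha(t7$quota_mm * t7$n_events)
  pooled <- unique(rbind(yield_response_points(t6, 5),
                         yield_response_points(t7, 5)))
  expect_gte(nrow(pooled), 8)
  fit <- fit_yield_response(pooled)
  expect_lt(fit$c, 0)
})

test_that("selection reproduces the published scheme choices", {
  t6 <- load_fixture("table6_scenarioI")
  t6$total_m3_ha <- mm_to_m3_ha(t6$amount_mm)
  expect_equal(select_optimal(t6, "yield")$scheme, "A10")
  expect_equal(select_optimal(t6, "wue")$scheme, "A10")
  expect_equal(t6$scheme[which.min(t6$yield_t_ha)], "A1")

  t7 <- load_fixture("table7_scenarioII")
  t7$total_m3_ha <- mm_to_m3_ha(t7$quota_mm * t7$n_events)
  expect_equal(select_optimal(t7, "yield")$scheme, "A25")
  expect_equal(select_optimal(t7, "wue")$scheme, "A26")
  # subset filtering and empty-subset error
  expect_equal(select_optimal(t7, "yield", subset = c("A16", "A17"))$scheme,
               "A16")
  expect_error(select_optimal(t7, "yield", subset = character(0)), "no candidate")
})

test_that("ties are broken toward less irrigation water", {
  res <- data.frame(scheme = c("B1", "B2"), total_m3_ha = c(2400, 1800),
                    yield_t_ha = c(40, 40), wue_kg_m3 = c(10, 12))
  expect_equal(select_optimal(res, "yield")$scheme, "B2")
})

test_that("multi-year scenario runs average their per-year results", {
  grid <- build_scenario_grid()[c(2, 11, 26), ] # a small cross-section
  w <- attach_et0(generate_weather(ningxia_climate(), 2, seed = 14,
                                   start_year = 2019), test_site())
  res <- run_scenario_set(grid, w, test_soil(), crop_parameters(),
                          years = 2019:2020)
  expect_equal(nrow(res), 3)
  per <- attr(res, "per_year")
  expect_equal(nrow(per), 6)
  for (s in res$scheme) {
    expect_equal(res$yield_t_ha[res$scheme == s],
                 mean(per$yield_t_ha[per$scheme == s]), tolerance = 1e-12)
  }
  # single year: the mean is that year's value
  res1 <- run_scenario_set(grid[1, ], w, test_soil(), crop_parameters(),
                           years = 2019)
  expect_equal(res1$yield_t_ha,
               attr(res1, "per_year")$yield_t_ha, tolerance = 1e-12)
})

test_that("report tables keep the fixture column layout", {
  t7 <- load_fixture("table7_scenarioII")
  out <- report_tables(t7)
  expect_equal(names(out),
               c("scheme", "quota_mm", "cycle_days", "n_events",
                 "yield_t_ha", "biomass_t_ha", "wue_kg_m3", "et_mm"))
  expect_equal(nrow(report_tables(t7[0, ])), 0)
  rounded <- report_tables(t7, digits = 2)
  expect_equal(rounded$yield_t_ha, round(t7$yield_t_ha, 2))
})

test_that("the fixture-driven reproduction report passes its claims", {
  sel <- reproduce("selections")
  expect_true(all(sel$pass))
  yr <- reproduce("yield_response")
  expect_true(all(yr$pass, na.rm = TRUE))
})
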