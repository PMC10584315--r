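Package: aquadrip
Title: Water-Driven Potato Growth Simulation and Drip Irrigation Scheduling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Daily water-driven crop growth simulation for potato under drip
    irrigation in arid environments, in the style of the FAO AquaCrop model:
    FAO-56 Penman-Monteith reference evapotranspiration, a layered bucket
    soil water balance with depletion-based stress coefficients, canopy
    cover development on thermal time, normalized-water-productivity biomass
    accumulation and harvest-index yield formation. Includes a seeded
    stochastic weather generator for arid continental climates, irrigation
    plan and scenario-grid builders (quota x cycle), goodness-of-fit
    statistics (RMSE, NRMSE, Willmott's index of agreement, R squared) for
    calibration and validation workflows, and quadratic irrigation-yield
    response fitting to locate optimal irrigation volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
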