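# Synthetic weather generation and scenario transforms.

test_that("RW generation is deterministic and leaves the caller's RNG alone", {
  clim <- balticClimatology(seed = 42L)
  set.seed(7)
  before <- .Random.seed
  a <- generateRWForcing(clim, 2000, 3)
  expect_identical(before, .Random.seed)
  b <- generateRWForcing(clim, 2000, 3)
  expect_identical(a, b)
  c <- generateRWForcing(balticClimatology(seed = 43L), 2000, 3)
  expect_false(identical(forcingVariable(a, "airTemp"),
                         forcingVariable(c, "airTemp")))
})

test_that("zero noise collapses every year onto the pure seasonal cycle", {
  clim <- constClimatology(basins = c("a", "b"), airTemp = c(2, 7),
                           wind = 6, precip = 1e-3, radiation = 100,
                           discharge = 1e6)
  fs <- generateRWForcing(clim, 1990, 4)
  for (v in c("airTemp", "wind", "precip", "radiation", "discharge")) {
    m <- forcingVariable(fs, v)
    y1 <- m[1:365, ]
    for (k in 1:3) expect_equal(m[k * 365 + 1:365, ], y1)
  }
})

test_that("long-run grand mean matches the configured climatological mean", {
  # The generator's own distribution: grand mean ~ N(mean, noiseSd/sqrt(n)).
  clim <- balticClimatology(seed = 11L)
  fs <- generateRWForcing(clim, 2000, 100)
  ta <- forcingVariable(fs, "airTemp")
  met <- clim@met
  for (b in basinIds(clim)) {
    row <- met[met$basin == b & met$variable == "airTemp", ]
    se <- row$noiseSd / sqrt(100)
    expect_lt(abs(mean(ta[, b]) - row$mean), 3 * se)
  }
})

test_that("RW series is stationary: no significant trend over 60 years", {
  fs <- generateRWForcing(balticClimatology(seed = 5L), 2000, 60)
  for (v in c("airTemp", "wind", "discharge")) {
    m <- forcingVariable(fs, v)
    annual <- rowsum(m[, "gotland"], forcingYears(fs)) / 365
    yr <- sort(unique(forcingYears(fs)))
    fit <- summary(stats::lm(annual ~ yr))$coefficients
    expect_gt(fit["yr", "Pr(>|t|)"], 0.01)
  }
})

test_that("generator rejects invalid arguments", {
  clim <- balticClimatology()
  expect_error(generateRWForcing(clim, 2000, 0), "invalid argument")
  expect_error(generateRWForcing(clim, 2000, -3), "invalid argument")
  badMet <- clim@met
  badMet$amplitude[1] <- -1
  expect_error(climatologyParams(clim@basins, badMet, clim@loads),
               "amplitude")
})

test_that("a1b transform hits its period-mean ratios exactly", {
  fs <- generateRWForcing(balticClimatology(seed = 3L), 2000, 20)
  tr <- applyA1bTransform(fs, scenarioSpec(climate = "a1b"))
  for (b in basinIds(fs)) {
    expect_equal(mean(forcingVariable(tr, "wind")[, b]) /
                   mean(forcingVariable(fs, "wind")[, b]), 1.07,
                 tolerance = 1e-12)
    expect_equal(mean(forcingVariable(tr, "precip")[, b]) /
                   mean(forcingVariable(fs, "precip")[, b]), 1.20,
                 tolerance = 1e-12)
    expect_equal(mean(forcingVariable(tr, "airTemp")[, b]) /
                   mean(forcingVariable(fs, "airTemp")[, b]), 1.60,
                 tolerance = 1e-12)
  }
  # untouched fields and the identity transform
  expect_identical(forcingVariable(tr, "dinLoad"),
                   forcingVariable(fs, "dinLoad"))
  expect_identical(forcingVariable(tr, "contAirConc"),
                   forcingVariable(fs, "contAirConc"))
  ident <- applyA1bTransform(fs, scenarioSpec(climate = "a1b",
                                              a1bWindFactor = 1,
                                              a1bTempFactor = 1,
                                              a1bPrecipFactor = 1))
  expect_equal(ident@data, fs@data)
  # pointwise multiplicative mode scales every degC value
  mult <- applyA1bTransform(fs, scenarioSpec(climate = "a1b",
                                             a1bTempMode = "multiplicative"))
  expect_equal(forcingVariable(mult, "airTemp"),
               forcingVariable(fs, "airTemp") * 1.6)
})

test_that("offset-mode a1b warms winters while multiplicative cools them", {
  clim <- constClimatology(basins = "box", airTemp = 2)
  clim@met$amplitude[clim@met$variable == "airTemp"] <- 11
  fs <- generateRWForcing(clim, 2000, 1)
  base <- forcingVariable(fs, "airTemp")[, 1]
  off <- forcingVariable(applyA1bTransform(fs, scenarioSpec(climate = "a1b")),
                         "airTemp")[, 1]
  mul <- forcingVariable(
    applyA1bTransform(fs, scenarioSpec(climate = "a1b",
                                       a1bTempMode = "multiplicative")),
    "airTemp")[, 1]
  coldest <- which.min(base)
  expect_gt(off[coldest], base[coldest])   # uniformly warmer
  expect_lt(mul[coldest], base[coldest])   # literal scaling chills winters
})

test_that("nutrient-load scenarios follow their ramps", {
  fs <- generateRWForcing(balticClimatology(), 2000, 91)
  # CL: identical at every step
  expect_identical(buildNutrientLoads(scenarioSpec(nutrients = "CL"), fs), fs)
  # BSAP: endpoint of the linear ramp
  bs <- buildNutrientLoads(
    scenarioSpec(nutrients = "BSAP", bsapTargetFactor = 0.5,
                 bsapTargetYear = 2020), fs)
  i2020 <- which(forcingYears(fs) == 2020 & forcingDoy(fs) == 1)
  expect_equal(forcingVariable(bs, "dinLoad")[i2020, ],
               0.5 * forcingVariable(fs, "dinLoad")[i2020, ])
  i2030 <- which(forcingYears(fs) == 2030 & forcingDoy(fs) == 1)
  expect_equal(forcingVariable(bs, "dipLoad")[i2030, ],
               0.5 * forcingVariable(fs, "dipLoad")[i2030, ])  # held constant
  # IL: midpoint of a ramp to 2.0x over 90 years
  il <- buildNutrientLoads(
    scenarioSpec(nutrients = "IL", ilTargetFactor = 2, ilTargetYear = 2090),
    fs)
  i2045 <- which(forcingYears(fs) == 2045 & forcingDoy(fs) == 1)
  expect_equal(forcingVariable(il, "dinLoad")[i2045, ],
               1.5 * forcingVariable(fs, "dinLoad")[i2045, ])
  # meteorology and contaminant channels untouched
  expect_identical(forcingVariable(il, "wind"), forcingVariable(fs, "wind"))
  expect_identical(forcingVariable(il, "contRiverLoad"),
                   forcingVariable(fs, "contRiverLoad"))
})

test_that("emission scenarios apply the step cut from the reduction year", {
  fs <- generateRWForcing(balticClimatology(), 2000, 20)
  spec <- scenarioSpec(emissions = "red_river", reductionYear = 2006,
                       reductionFraction = 0.9)
  rr <- buildEmissionScenario(spec, fs)
  pre <- forcingYears(fs) < 2006
  expect_identical(forcingVariable(rr, "contRiverLoad")[pre, ],
                   forcingVariable(fs, "contRiverLoad")[pre, ])
  expect_equal(forcingVariable(rr, "contRiverLoad")[!pre, ],
               0.1 * forcingVariable(fs, "contRiverLoad")[!pre, ])
  expect_identical(forcingVariable(rr, "contAirConc"),
                   forcingVariable(fs, "contAirConc"))
  ra <- buildEmissionScenario(scenarioSpec(emissions = "red_air"), fs)
  expect_equal(forcingVariable(ra, "contAirConc")[!pre, ],
               0.1 * forcingVariable(fs, "contAirConc")[!pre, ])
  expect_identical(forcingVariable(ra, "contRiverLoad"),
                   forcingVariable(fs, "contRiverLoad"))
  # null scenario and range error
  expect_identical(buildEmissionScenario(scenarioSpec(), fs), fs)
  expect_error(buildEmissionScenario(
    scenarioSpec(emissions = "red_river", reductionYear = 1980), fs),
    "range error")
})

test_that("emission and nutrient transforms commute", {
  fs <- generateRWForcing(balticClimatology(seed = 9L), 2000, 30)
  em <- scenarioSpec(emissions = "red_river", nutrients = "BSAP")
  a <- buildEmissionScenario(em, buildNutrientLoads(em, fs))
  b <- buildNutrientLoads(em, buildEmissionScenario(em, fs))
  expect_identical(a@data, b@data)
})

test_that("scenario labels are validated", {
  expect_error(scenarioSpec(climate = "rcp85"), "climate")
  expect_error(scenarioSpec(nutrients = "none"), "nutrients")
  expect_error(scenarioSpec(emissions = "off"), "emissions")
  expect_error(scenarioSpec(reductionFraction = 1.2), "reductionFraction")
  expect_error(scenarioSpec(a1bWindFactor = -1), "multipliers")
})
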