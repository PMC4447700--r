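# Plankton-detritus dynamics, organic carbon pools and elemental budgets.

test_that("without nutrients phytoplankton decays and mineralization feeds DIN", {
  geom <- singleBoxGeometry()
  st <- initialState(geom, init = list(
    tSurf = 15, bioSurf = list(din = 0, dip = 0, phy = 50, det = 20,
                               doc = 0),
    bioDeep = list(din = 0, dip = 0, det = 0, doc = 0), sedOC = 0))
  fd <- constForcingDay(geom, airTemp = 15, radiation = 200)
  hp <- hydroParams(vMix = 0)
  phy <- din <- numeric(200)
  for (i in 1:200) {
    st <- stepBiogeo(st, geom, fd, hydro = hp)
    phy[i] <- st$bio$surf[, "phy"]
    din[i] <- st$bio$surf[, "din"]
  }
  expect_true(all(diff(phy) < 0))            # monotone decay toward zero
  expect_lt(phy[200], 1e-4 * 50)
  expect_true(all(diff(din) > 0))            # DIN rises via mineralization only
})

test_that("a closed box conserves nitrogen and phosphorus", {
  geom <- singleBoxGeometry(sedBurial = 0)   # burial off: fully closed
  params <- biogeoParams()
  st <- initialState(geom, init = list(
    tSurf = 12, bioSurf = list(din = 40, dip = 8, phy = 10, det = 10,
                               doc = 100)))
  n0 <- totalNitrogenKg(st, geom, params)
  fd <- constForcingDay(geom, airTemp = 12, radiation = 150)
  hp <- hydroParams(vMix = 0.05)
  for (i in 1:3650) st <- stepBiogeo(st, geom, fd, params, hydro = hp)
  n1 <- totalNitrogenKg(st, geom, params)
  expect_lt(abs(n1 - n0) / n0, 1e-3)
  expect_true(all(st$bio$surf >= 0) && all(st$bio$deep >= 0) &&
                all(st$bio$sedOC >= 0))
})

test_that("chemostat equilibrium matches the analytic solution", {
  # dilution D, inflow concentration N_in, growth mu N/(N+K):
  # N* = K D / (mu - D), PHY* = (N_in - N*) / ncRatio.
  # Rates well below 1/day so the daily-step integration sits within 0.5 %
  # of the continuous-time equilibrium.
  q <- 2e4                                  # m3/day through a 1e7 m3 box
  nin <- 20                                 # mg N/m3 in the inflow
  params <- biogeoParams(muMax = 0.05, kN = 10, kP = 0, kI = 0,
                         mortality = 0, rMin20 = 0, sinkingVelocity = 0,
                         docExudation = 0, docDecay = 0,
                         sedMineralization = 0)
  clim <- constClimatology(airTemp = 20, radiation = 100, discharge = q,
                           dinLoad = nin * q * 1e-6,  # kg/day
                           dipLoad = 2)               # P in huge excess
  geom <- singleBoxGeometry(sedBurial = 0)
  cfg <- simulationConfig(geometry = geom, climatology = clim,
                          chemical = inertChemical(),
                          biogeo = params, hydro = hydroParams(vMix = 0),
                          startYear = 2000, endYear = 2014)
  out <- runSimulation(cfg)
  d <- q / 1e7
  nStar <- params$kN * d / (params$muMax - d)
  phyStar <- (nin - nStar) / params$ncRatio
  lastPhy <- tail(variableSeries(out, "box", "phytoplankton")$value, 1)
  lastDin <- tail(variableSeries(out, "box", "din")$value, 1)
  expect_equal(lastPhy, phyStar, tolerance = 5e-3)
  expect_equal(lastDin, nStar, tolerance = 5e-3)
})

test_that("POC is the derived sum of phytoplankton and detritus", {
  geom <- balticGeometry()
  st <- initialState(geom)
  expect_equal(pocConcentration(st),
               st$bio$surf[, "phy"] + st$bio$surf[, "det"])
  expect_equal(pocConcentration(st, "deep"), st$bio$deep[, "det"])
})

test_that("nutrient-poor basins stay oligotrophic relative to loaded ones", {
  # the northern basin's small P load keeps its POC far below the central
  # basin's, and its response to raised loads stays bounded
  run <- function(scale) {
    runSimulation(simulationConfig(
      climatology = balticClimatology(seed = 2L, nutrientScale = scale),
      startYear = 2000, endYear = 2007))
  }
  out1 <- run(1)
  out15 <- run(1.5)
  meanPoc <- function(out, b) {
    s <- variableSeries(out, b, "poc")
    mean(s$value[s$year >= 2003])
  }
  expect_lt(meanPoc(out1, "bothnian"), 0.5 * meanPoc(out1, "gotland"))
  change <- meanPoc(out15, "bothnian") / meanPoc(out1, "bothnian")
  expect_lt(change, 1.6)                     # bounded response to 1.5x loads
  expect_gt(change, 0.9)
})
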