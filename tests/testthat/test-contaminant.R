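# Phase partitioning, air-water exchange, transformation, settling,
# advection of the contaminant.

test_that("phase partitioning follows the three-phase formula", {
  ch <- chemicalProperties("x", logKow = 6, logKaw = 0, logKoc = 5,
                           kdocFraction = 0, dUow = 0)
  # no sorbent: everything truly dissolved
  f0 <- phasePartition(ch, doc = 0, poc = 0, tempC = 25)
  expect_equal(f0$fDiss, 1)
  expect_equal(f0$fDoc, 0)
  expect_equal(f0$fPoc, 0)
  # K_OC = 1e5 L/kg, POC = 1 mg C/L = 1e-6 kg C/L: f_diss = 1/1.1
  f1 <- phasePartition(ch, doc = 0, poc = 1, tempC = 25)
  expect_equal(f1$fDiss, 1 / 1.1, tolerance = 1e-12)
  expect_equal(f1$fPoc, 0.1 / 1.1, tolerance = 1e-12)
  # doubling K_OC strictly decreases f_diss for any positive POC
  ch2 <- chemicalProperties("x2", logKow = 6, logKaw = 0,
                            logKoc = 5 + log10(2), kdocFraction = 0, dUow = 0)
  for (poc in c(0.01, 0.5, 2, 20)) {
    expect_lt(phasePartition(ch2, 0, poc, 25)$fDiss,
              phasePartition(ch, 0, poc, 25)$fDiss)
  }
  # fractions always sum to one exactly
  set.seed(1)
  doc <- runif(50, 0, 20); poc <- runif(50, 0, 20)
  f <- phasePartition(d5Properties(), doc, poc, tempC = runif(50, -1, 25))
  expect_equal(f$fDiss + f$fDoc + f$fPoc, rep(1, 50))
  expect_error(phasePartition(ch, -1, 0), "validation error")
})

test_that("two-film air-water flux handles ice, equilibrium and resistances", {
  chem <- d5Properties()
  # complete ice cover blocks the flux regardless of the gradient
  expect_equal(airWaterFlux(cDiss = 5, cAir = 0.5, tempC = 2, wind = 8,
                            iceFraction = 1, chem), 0)
  # equilibrium: C_diss = C_air / K_AW(T) (both sides as ng/m3)
  kaw <- kawT(chem, 10)
  cDissEq <- 0.5 / kaw / 1000                 # ng/L
  expect_equal(airWaterFlux(cDissEq, 0.5, 10, 8, 0, chem), 0,
               tolerance = 1e-12)
  # series-resistance arithmetic
  expect_equal(overallTransferVelocity(1e-5, 1e-3, 2), 1 / (1e5 + 500))
  # supersaturated water outgasses; ice scales the flux linearly
  f0 <- airWaterFlux(5, 0.5, 10, 8, 0, chem)
  expect_lt(f0, 0)
  expect_equal(airWaterFlux(5, 0.5, 10, 8, 0.75, chem), 0.25 * f0)
})

test_that("hydrolysis decays only the dissolved fraction", {
  k <- 0.02
  chem <- chemicalProperties("hyd", logKow = 4, logKaw = 0, logKoc = -6,
                             kdocFraction = 0, dUaw = 0, dUow = 0,
                             hydrolysisRate25 = k, hydrolysisEa = 0)
  geom <- singleBoxGeometry()
  # fully dissolved (no sorbents): C(t) = C0 exp(-k t) to machine precision
  st <- initialState(geom, init = list(
    mSurf = 100, bioSurf = list(din = 0, dip = 0, phy = 0, det = 0, doc = 0),
    bioDeep = list(din = 0, dip = 0, det = 0, doc = 0)))
  for (n in 1:50) {
    st <- transformationLosses(st, geom, chem)
    expect_equal(unname(st$cont$mSurf), 100 * exp(-k * n), tolerance = 1e-12)
  }
  # zero rates leave the state unchanged
  st2 <- initialState(geom, init = list(mSurf = 42, mDeep = 7, mSed = 3))
  st3 <- transformationLosses(st2, geom, inertChemical())
  expect_equal(st3$cont, st2$cont)
  # with f_POC = 1/2 the hydrolyzable mass is lost at half the rate
  chemSorb <- chemicalProperties("hyd2", logKow = 4, logKaw = 0, logKoc = 5,
                                 kdocFraction = 0, dUaw = 0, dUow = 0,
                                 hydrolysisRate25 = k, hydrolysisEa = 0)
  pocHalf <- 1e6 / 1e5                       # mg C/L giving K_OC*POC = 1
  stH <- initialState(geom, init = list(
    mSurf = 100,
    bioSurf = list(din = 0, dip = 0, phy = 0, det = pocHalf * 1000, doc = 0)))
  lossFree <- 100 * (1 - exp(-k))
  stH1 <- transformationLosses(stH, geom, chemSorb)
  expect_equal(100 - unname(stH1$cont$mSurf), lossFree / 2, tolerance = 1e-12)
  # brute-force two-pool oracle over many steps (instant re-equilibration)
  m <- 100
  for (i in 1:30) m <- m * (0.5 + 0.5 * exp(-k))
  stH30 <- stH
  for (i in 1:30) stH30 <- transformationLosses(stH30, geom, chemSorb)
  expect_equal(unname(stH30$cont$mSurf), m, tolerance = 1e-12)
})

test_that("settling and sediment exchange keep exact bookkeeping", {
  geom <- singleBoxGeometry(sedResuspension = 0, sedBurial = 0,
                            sedDiffVelocity = 0)
  chem <- d5Properties()
  params <- biogeoParams()
  # nothing particle-bound: no settling flux at all
  st0 <- initialState(geom, init = list(
    mSurf = 10, mDeep = 5,
    bioSurf = list(din = 0, dip = 0, phy = 0, det = 0, doc = 0),
    bioDeep = list(din = 0, dip = 0, det = 0, doc = 0)))
  st1 <- settleExchangeSediment(st0, geom, chem, params)
  expect_equal(st1$cont, st0$cont)
  # deposition-only: sediment gain equals the cumulative settling flux
  st <- initialState(geom, init = list(
    mSurf = 10, mDeep = 5,
    bioSurf = list(din = 0, dip = 0, phy = 100, det = 100, doc = 0),
    bioDeep = list(din = 0, dip = 0, det = 200, doc = 0)))
  for (i in 1:40) st <- settleExchangeSediment(st, geom, chem, params)
  expect_equal(unname(st$cont$mSed), st$budget[["contSettling"]])
  total <- st$cont$mSurf + st$cont$mDeep + st$cont$mSed
  expect_equal(unname(total), 15, tolerance = 1e-12)   # internal moves only
})

test_that("advection dilutes a single box toward the L/Q steady state", {
  geom <- singleBoxGeometry(area = 1e5, hSurf = 10, hDeep = 10)
  grid <- baltfate:::makeGrid(geom)
  hp <- hydroParams(vMix = 0)
  q <- 2e5                                   # m3/day, 20 %/day flushing
  load <- 4                                  # kg/day
  fd <- constForcingDay(geom, discharge = q, contRiverLoad = load)
  flows <- baltfate:::computeFlows(grid, fd, hp)
  st <- initialState(geom)
  for (i in 1:200) {
    st <- baltfate:::.advectContaminant(st, grid, fd, hp, flows, 1)
  }
  expect_equal(unname(st$cont$mSurf / grid$vSurf), load / q,
               tolerance = 5e-3)             # steady C = L/Q (kg/m3)
  # no flows, no loads: nothing moves
  fd0 <- constForcingDay(geom)
  flows0 <- baltfate:::computeFlows(grid, fd0, hp)
  st0 <- initialState(geom, init = list(mSurf = 3, mDeep = 2, mSed = 1))
  st1 <- baltfate:::.advectContaminant(st0, grid, fd0, hp, flows0, 1)
  expect_equal(st1$cont, st0$cont)
})

test_that("temperature corrections move partitioning the documented way", {
  chem <- d5Properties()
  # volatility falls as the water cools (dU_AW < 0 under this convention)
  expect_lt(kawT(chem, 0), kawT(chem, 25))
  expect_equal(kawT(chem, 25), 10^3.1)
  expect_equal(kocT(chem, 25), 10^5.2)
  expect_equal(kdocT(chem, 25), 0.1 * 10^5.2)
})
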