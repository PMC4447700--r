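# Water/salt balances, heat relaxation and degree-day ice.

test_that("no-flux configuration is a fixed point of the water/salt step", {
  geom <- singleBoxGeometry()
  st <- initialState(geom, init = list(sSurf = 6, sDeep = 8))
  fd <- constForcingDay(geom, precip = 0, discharge = 0)
  hp <- hydroParams(vMix = 0)
  res <- stepWaterSalt(st, geom, fd, hp)
  expect_equal(res$state$phys$sSurf, st$phys$sSurf)
  expect_equal(res$state$phys$sDeep, st$phys$sDeep)
  expect_equal(unname(res$flows$qOut), 0)
})

test_that("steady surface salinity matches the closed-form mixing balance", {
  # deep inflow Q_s at S_in plus freshwater Q_f: S* = S_in Q_s / (Q_s + Q_f)
  qs <- 2e6; qf <- 1e6; sin <- 10
  geom <- singleBoxGeometry(area = 1e6, hSurf = 10, hDeep = 10,
                            deepInflowRate = qs, deepInflowSalinity = sin)
  st <- initialState(geom, init = list(sSurf = 0, sDeep = 0))
  fd <- constForcingDay(geom, discharge = qf)
  grid <- baltfate:::makeGrid(geom)
  hp <- hydroParams()
  for (i in 1:400) {
    st <- baltfate:::.stepWaterSalt(st, grid, fd, hp, 1)$state
  }
  expect_equal(unname(st$phys$sSurf), sin * qs / (qs + qf), tolerance = 1e-3)
})

test_that("water volume is conserved exactly over many steps", {
  geom <- balticGeometry()
  grid <- baltfate:::makeGrid(geom)
  st <- initialState(geom)
  fd <- constForcingDay(geom, precip = 2e-3, discharge = 5e8)
  hp <- hydroParams()
  for (i in 1:200) st <- baltfate:::.stepWaterSalt(st, grid, fd, hp, 1)$state
  b <- st$budget
  expect_lt(abs(b[["waterIn"]] - b[["waterOut"]]) / b[["waterIn"]], 1e-12)
})

test_that("salt is conserved globally except for boundary fluxes", {
  geom <- balticGeometry()
  grid <- baltfate:::makeGrid(geom)
  st <- initialState(geom)
  init <- baltfate:::saltInventory(st, grid)
  fd <- constForcingDay(geom, precip = 1.6e-3, discharge = 4e8)
  hp <- hydroParams()
  for (i in 1:300) st <- baltfate:::.stepWaterSalt(st, grid, fd, hp, 1)$state
  final <- baltfate:::saltInventory(st, grid)
  resid <- init + st$budget[["saltIn"]] - st$budget[["saltOut"]] - final
  expect_lt(abs(resid) / st$budget[["saltIn"]], 1e-10)
})

test_that("temperature relaxation follows the exponential closed form", {
  geom <- singleBoxGeometry()
  hp <- hydroParams(tauSurf = 14, radHeating = 0, vMix = 0)
  # fixed point: air temperature equals water temperature, no radiation
  st <- initialState(geom, init = list(tSurf = 12, sSurf = 0))
  fd <- constForcingDay(geom, airTemp = 12, radiation = 0)
  expect_equal(stepHeatIce(st, geom, fd, hp)$phys$tSurf, st$phys$tSurf)
  # T(t) = Ta + (T0 - Ta) exp(-t/tau) for constant air temperature
  t0 <- 2; ta <- 15
  st <- initialState(geom, init = list(tSurf = t0, sSurf = 0))
  fd <- constForcingDay(geom, airTemp = ta, radiation = 0)
  for (n in 1:60) {
    st <- stepHeatIce(st, geom, fd, hp)
    expect_equal(unname(st$phys$tSurf), ta + (t0 - ta) * exp(-n / 14),
                 tolerance = 1e-12)
  }
})

test_that("degree-day ice grows under sustained frost and melts before warming", {
  geom <- singleBoxGeometry()
  hp <- hydroParams()
  st <- initialState(geom, init = list(tSurf = 0, tDeep = 0, sSurf = 3,
                                       sDeep = 3))
  cold <- constForcingDay(geom, airTemp = -10, radiation = 0)
  ice <- numeric(90)
  for (i in 1:90) {
    st <- stepHeatIce(st, geom, cold, hp)
    ice[i] <- st$phys$ice
  }
  expect_true(all(diff(ice) >= 0))          # monotone growth
  expect_equal(ice[90], 1)                  # full cover well before day 90
  expect_true(all(ice >= 0 & ice <= 1))
  # melting: water pinned at the freezing point until the ice is gone
  warm <- constForcingDay(geom, airTemp = 10, radiation = 0)
  tf <- -0.054 * 3
  seenIce <- TRUE
  for (i in 1:60) {
    st <- stepHeatIce(st, geom, warm, hp)
    if (st$phys$ice > 0) {
      expect_equal(unname(st$phys$tSurf), tf)
    }
  }
  expect_equal(unname(st$phys$ice), 0)      # melt-out complete
  expect_gt(st$phys$tSurf, tf)              # then the water warms
  # a never-freezing run keeps ice at zero throughout
  st2 <- initialState(geom, init = list(tSurf = 0, sSurf = 3, sDeep = 3))
  for (i in 1:90) {
    st2 <- stepHeatIce(st2, geom, warm, hp)
    expect_equal(unname(st2$phys$ice), 0)
  }
})

test_that("step functions reject non-positive dt", {
  geom <- singleBoxGeometry()
  st <- initialState(geom)
  fd <- constForcingDay(geom)
  expect_error(stepWaterSalt(st, geom, fd, dt = 0), "dt")
  expect_error(stepHeatIce(st, geom, fd, dt = -1), "dt")
})

test_that("geometry validity catches broken configurations", {
  b <- data.frame(id = c("a", "z"), area = 1e6, hSurf = 10, hDeep = 10,
                  boundary = c(FALSE, TRUE))
  cn <- data.frame(from = c("a", "z"), to = c("z", NA))
  expect_s4_class(basinGeometry(b, cn), "BasinGeometry")
  # two boundaries
  b2 <- b; b2$boundary <- TRUE
  expect_error(basinGeometry(b2, cn), "exactly one")
  # cycle
  cn2 <- data.frame(from = c("a", "z"), to = c("z", "a"))
  expect_error(basinGeometry(b, cn2), "acyclic|boundary")
  # disconnected
  cn3 <- data.frame(from = c("a", "z"), to = c(NA, NA))
  b3 <- b
  expect_error(basinGeometry(b3, cn3), "acyclic|boundary|exactly one")
})
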