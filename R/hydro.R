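# Hydro module: water/salt balances, surface heat exchange, degree-day ice.

# Daily flows (m3/day) under the rigid-lid simplification: volumes constant,
# so surface outflow = net freshwater + deep inflow (entrained upward) +
# upstream surface inflows, accumulated down the routing chain.
computeFlows <- function(grid, fd, hydro) {
  evap <- hydro$evapFraction * fd$precip
  qFw <- fd$discharge + (fd$precip - evap) * grid$area
  qOut <- qFw + grid$qDeep
  conn <- grid$conn
  for (i in grid$orderIdx) {               # upstream first
    rows <- which(conn$fromIdx == i & !is.na(conn$toIdx))
    for (k in rows) {
      qOut[conn$toIdx[k]] <- qOut[conn$toIdx[k]] + conn$fraction[k] * qOut[i]
    }
  }
  list(qFw = qFw, qOut = qOut, qDeep = grid$qDeep)
}

.stepWaterSalt <- function(state, grid, fd, hydro, dt) {
  flows <- computeFlows(grid, fd, hydro)
  mS <- state$phys$sSurf * grid$vSurf
  mD <- state$phys$sDeep * grid$vDeep
  adv <- advectTracer(mS, mD, grid, flows, grid$sIn, riverIn = 0,
                      vMix = hydro$vMix, dt = dt)
  sSurf <- adv$mS / grid$vSurf
  sDeep <- adv$mD / grid$vDeep
  if (any(sSurf < 0) || any(sDeep < 0)) {
    stop("numerical stability error: negative salinity; use a smaller dt ",
         "or weaker flows")
  }
  state$phys$sSurf <- sSurf
  state$phys$sDeep <- sDeep
  b <- state$budget
  b["saltIn"] <- b["saltIn"] + adv$boundaryIn
  b["saltOut"] <- b["saltOut"] + adv$boundaryOut
  b["waterIn"] <- b["waterIn"] + sum(flows$qFw + grid$qDeep) * dt
  b["waterOut"] <- b["waterOut"] + flows$qOut[grid$boundaryIdx] * dt
  state$budget <- b
  list(state = state, flows = flows)
}

#' Advance water and salt balances by one step
#'
#' Surface outflow toward the open boundary equals river discharge plus net
#' precipitation minus evaporation plus upstream inflows plus entrained deep
#' inflow, so layer volumes are conserved exactly (rigid lid). Deep salty
#' inflows enter at their configured rate and salinity and are balanced by
#' upward entrainment into the surface layer; a small diffusive exchange
#' (`vMix`) connects the layers. Salt mass is conserved globally except for
#' the declared boundary fluxes, which are accumulated in the state budget.
#'
#' @param state a state list from [initialState()].
#' @param geom a [BasinGeometry-class].
#' @param fd one day of forcing from [forcingDay()].
#' @param hydro parameters from [hydroParams()].
#' @param dt time step (days).
#' @return list with elements `state` (updated) and `flows` (list of qFw,
#'   qOut, qDeep per basin, m3/day), the latter needed by the tracer
#'   advection steps.
#' @export
stepWaterSalt <- function(state, geom, fd, hydro = hydroParams(), dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  .stepWaterSalt(state, makeGrid(geom), fd, hydro, dt)
}

# Salinity-dependent freezing point, standard linearization (degC).
freezingPoint <- function(salinity) -0.054 * salinity

.stepHeatIce <- function(state, grid, fd, hydro, dt) {
  p <- state$phys
  tf <- freezingPoint(p$sSurf)
  relax <- exp(-dt / hydro$tauSurf)
  tNew <- fd$airTemp + (p$tSurf - fd$airTemp) * relax +
    hydro$radHeating * fd$radiation * dt
  pinned <- (p$fdd > 0) | (tNew < tf)
  fdd <- p$fdd
  fdd[pinned] <- pmax(0, fdd[pinned] + (tf[pinned] - fd$airTemp[pinned]) * dt)
  fdd <- pmin(fdd, hydro$fddMemory * hydro$fddFull)
  tSurf <- ifelse(pinned, tf, tNew)
  ice <- if (isFALSE(hydro$iceEnabled)) 0 * fdd else pmin(1, fdd / hydro$fddFull)
  relaxD <- exp(-dt / hydro$tauDeep)
  tDeep <- pmax(p$tSurf + (p$tDeep - p$tSurf) * relaxD,
                freezingPoint(p$sDeep))
  state$phys$tSurf <- tSurf
  state$phys$tDeep <- tDeep
  state$phys$fdd <- fdd
  state$phys$ice <- ice
  state
}

#' Advance surface heat and sea ice by one step
#'
#' Surface water temperature relaxes exponentially toward air temperature
#' with time constant `tauSurf` (exact integrator, so a constant-air run
#' follows `T(t) = Ta + (T0 - Ta) exp(-t/tau)` to machine precision); the
#' deep layer relaxes toward the surface with `tauDeep`. Once the surface
#' reaches the salinity-dependent freezing point (`-0.054 x S` degC),
#' further cooling accumulates freezing-degree-days and the ice fraction
#' grows as `min(1, FDD / fddFull)`; warming first melts ice (consuming
#' positive-degree-days at the same scale, water pinned at the freezing
#' point) before the water warms again.
#'
#' @inheritParams stepWaterSalt
#' @return the updated state list.
#' @export
stepHeatIce <- function(state, geom, fd, hydro = hydroParams(), dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  .stepHeatIce(state, makeGrid(geom), fd, hydro, dt)
}
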