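# Contaminant module: three-phase partitioning, two-film air-water exchange
# with ice blocking, hydrolysis/biodegradation, settling, sediment exchange
# and inter-basin advection of a neutral organic chemical. Internal bookkeeping
# is in kg per compartment; concentrations are derived.

RGAS <- 8.314462618  # J/mol/K

# van't Hoff temperature correction of a partition coefficient.
vantHoff <- function(k25, dU, tempC) {
  k25 * exp((dU / RGAS) * (1 / (tempC + 273.15) - 1 / 298.15))
}

# Arrhenius temperature correction of a first-order rate.
arrhenius <- function(k25, ea, tempC) {
  k25 * exp((ea / RGAS) * (1 / 298.15 - 1 / (tempC + 273.15)))
}

#' Temperature-corrected partition coefficients
#'
#' @param chem a [ChemicalProperties-class].
#' @param tempC water temperature (degC), vectorized.
#' @return `kawT`: dimensionless air-water coefficient; `kocT`, `kdocT`:
#'   L/kg organic carbon.
#' @export
kawT <- function(chem, tempC) vantHoff(10^chem@logKaw, chem@dUaw, tempC)

#' @rdname kawT
#' @export
kocT <- function(chem, tempC) vantHoff(kocValue(chem), chem@dUow, tempC)

#' @rdname kawT
#' @export
kdocT <- function(chem, tempC) chem@kdocFraction * kocT(chem, tempC)

#' Three-phase partitioning of a neutral chemical in water
#'
#' Splits bulk-water chemical into truly dissolved, DOC-bound and POC-bound
#' fractions: `f_diss = 1 / (1 + K_DOC [DOC] + K_OC [POC])` with sorbent
#' concentrations in kg C/L and coefficients temperature-corrected via the
#' internal energy of organic-carbon-water transfer; the sorbed fractions
#' are proportional to their sorption terms and the three sum to one
#' exactly.
#'
#' @param chem a [ChemicalProperties-class].
#' @param doc,poc dissolved and particulate organic carbon (mg C/L),
#'   vectorized.
#' @param tempC water temperature (degC).
#' @return list with numeric `fDiss`, `fDoc`, `fPoc`.
#' @examples
#' # 1 mg C/L POC and K_OC = 1e5 L/kg: f_diss = 1/1.1
#' ch <- chemicalProperties("x", logKow = 6, logKaw = 0, logKoc = 5,
#'                          kdocFraction = 0, dUow = 0)
#' phasePartition(ch, doc = 0, poc = 1, tempC = 25)
#' @export
phasePartition <- function(chem, doc, poc, tempC = 25) {
  if (any(doc < 0) || any(poc < 0)) {
    stop("validation error: sorbent concentrations must be >= 0")
  }
  docKgL <- doc * 1e-6  # mg C/L -> kg C/L
  pocKgL <- poc * 1e-6
  termDoc <- kdocT(chem, tempC) * docKgL
  termPoc <- kocT(chem, tempC) * pocKgL
  denom <- 1 + termDoc + termPoc
  list(fDiss = 1 / denom, fDoc = termDoc / denom, fPoc = termPoc / denom)
}

#' Wind-dependent film transfer velocities (m/s)
#'
#' Air-side `k_a = 1e-3 (0.3 + 0.2 wind)` and water-side
#' `k_w = max(0.17e-6 wind^2, 1e-7)` m/s: standard two-film wind
#' parameterizations at box-model fidelity.
#'
#' @param wind wind speed at 10 m (m/s).
#' @return list with `kw` and `ka` (m/s).
#' @export
windTransferVelocities <- function(wind) {
  list(kw = pmax(0.17e-6 * wind^2, 1e-7), ka = 1e-3 * (0.3 + 0.2 * wind))
}

#' Overall air-water transfer velocity (two resistances in series)
#'
#' `k_OL = (1/k_w + 1/(k_a K_AW))^-1`.
#'
#' @param kw,ka water- and air-side transfer velocities (m/s).
#' @param kAw dimensionless air-water partition coefficient.
#' @return overall transfer velocity (m/s).
#' @export
overallTransferVelocity <- function(kw, ka, kAw) {
  1 / (1 / kw + 1 / (ka * kAw))
}

#' Diffusive air-water exchange flux density
#'
#' Two-film flux `k_OL (C_air / K_AW(T) - C_diss) (1 - ice)`, positive into
#' the water. With a volatile, water-supersaturated chemical the flux is
#' negative (net volatilization, sea to air); complete ice cover blocks the
#' exchange entirely.
#'
#' @param cDiss truly dissolved water concentration (ng/L).
#' @param cAir atmospheric gas-phase concentration (ng/m3).
#' @param tempC surface water temperature (degC).
#' @param wind wind speed (m/s).
#' @param iceFraction ice cover fraction in `[0, 1]`.
#' @param chem a [ChemicalProperties-class].
#' @return flux density (ng/m2/day), vectorized.
#' @export
airWaterFlux <- function(cDiss, cAir, tempC, wind, iceFraction, chem) {
  stopifnot(all(iceFraction >= 0 & iceFraction <= 1))
  kAw <- kawT(chem, tempC)
  tv <- windTransferVelocities(wind)
  kol <- overallTransferVelocity(tv$kw, tv$ka, kAw) * 86400  # m/day
  kol * (cAir / kAw - cDiss * 1000) * (1 - iceFraction)      # ng/L -> ng/m3
}

# Partition fractions of both water layers from the current biogeo state.
layerFractions <- function(state, chem) {
  surfDoc <- state$bio$surf[, "doc"] / 1000   # mg/m3 -> mg/L
  surfPoc <- (state$bio$surf[, "phy"] + state$bio$surf[, "det"]) / 1000
  deepDoc <- state$bio$deep[, "doc"] / 1000
  deepPoc <- state$bio$deep[, "det"] / 1000
  list(surf = phasePartition(chem, surfDoc, surfPoc, state$phys$tSurf),
       deep = phasePartition(chem, deepDoc, deepPoc, state$phys$tDeep))
}

.advectContaminant <- function(state, grid, fd, hydro, flows, dt) {
  cBound <- grid$cIn$contaminant * 1e-12  # ng/m3 -> kg/m3
  adv <- advectTracer(state$cont$mSurf, state$cont$mDeep, grid, flows,
                      cBound, riverIn = fd$contRiverLoad, vMix = hydro$vMix,
                      dt = dt)
  state$cont$mSurf <- adv$mS
  state$cont$mDeep <- adv$mD
  b <- state$budget
  b["contRiver"] <- b["contRiver"] + sum(fd$contRiverLoad) * dt
  b["contBoundaryIn"] <- b["contBoundaryIn"] + adv$boundaryIn
  b["contBoundaryOut"] <- b["contBoundaryOut"] + adv$boundaryOut
  state$budget <- b
  state
}

.airWaterExchange <- function(state, grid, fd, chem, frac, dt) {
  kAw <- kawT(chem, state$phys$tSurf)
  tv <- windTransferVelocities(fd$wind)
  kol <- overallTransferVelocity(tv$kw, tv$ka, kAw) * 86400  # m/day
  open <- 1 - state$phys$ice
  cDiss <- frac$surf$fDiss * state$cont$mSurf / grid$vSurf   # kg/m3
  cAir <- fd$contAirConc * 1e-12                              # kg/m3
  absorb <- kol * (cAir / kAw) * open * grid$area * dt        # kg
  volat <- kol * cDiss * open * grid$area * dt
  state$cont$mSurf <- state$cont$mSurf + absorb - volat
  b <- state$budget
  b["contAbsorb"] <- b["contAbsorb"] + sum(absorb)
  b["contVolat"] <- b["contVolat"] + sum(volat)
  state$budget <- b
  # net flux density diagnostic, ng/m2/day, positive into the water
  list(state = state, netFlux = (absorb - volat) / (grid$area * dt) * 1e12)
}

.transformationLosses <- function(state, grid, chem, frac, dt) {
  decayLayer <- function(m, fr, tempC) {
    kh <- arrhenius(chem@hydrolysisRate25, chem@hydrolysisEa, tempC)
    kb <- arrhenius(chem@biodegWater25, chem@biodegWaterEa, tempC)
    dissLoss <- fr$fDiss * m * (1 - exp(-(kh + kb) * dt))
    hydShare <- ifelse(kh + kb > 0, kh / (kh + kb), 0)
    docLoss <- fr$fDoc * m * (1 - exp(-kb * dt))
    list(m = m - dissLoss - docLoss,
         hyd = sum(dissLoss * hydShare),
         bio = sum(dissLoss * (1 - hydShare) + docLoss))
  }
  s <- decayLayer(state$cont$mSurf, frac$surf, state$phys$tSurf)
  d <- decayLayer(state$cont$mDeep, frac$deep, state$phys$tDeep)
  kSed <- arrhenius(chem@biodegSed25, chem@biodegSedEa, state$phys$tDeep)
  sedLoss <- state$cont$mSed * (1 - exp(-kSed * dt))
  state$cont$mSurf <- s$m
  state$cont$mDeep <- d$m
  state$cont$mSed <- state$cont$mSed - sedLoss
  b <- state$budget
  b["contHydrolysis"] <- b["contHydrolysis"] + s$hyd + d$hyd
  b["contBiodegWater"] <- b["contBiodegWater"] + s$bio + d$bio
  b["contBiodegSed"] <- b["contBiodegSed"] + sum(sedLoss)
  state$budget <- b
  state
}

.settleExchangeSediment <- function(state, grid, chem, params, frac, dt) {
  ws <- params$sinkingVelocity
  settleS <- frac$surf$fPoc * state$cont$mSurf * ws / grid$hSurf * dt
  settleD <- frac$deep$fPoc * state$cont$mDeep * ws / grid$hDeep * dt
  mSed <- state$cont$mSed
  resusp <- grid$sedResuspension * mSed * dt
  burial <- grid$sedBurial * mSed * dt
  # porewater concentration from sediment OC sorption equilibrium
  mOC <- state$bio$sedOC * grid$area / 1000                 # kg OC
  koc <- kocT(chem, state$phys$tDeep)                       # L/kg OC
  cPore <- ifelse(mOC > 0, mSed / mOC / koc * 1000, 0)      # kg/m3
  cDissDeep <- frac$deep$fDiss * state$cont$mDeep / grid$vDeep
  diff <- grid$sedDiffVelocity * grid$area * (cPore - cDissDeep) * dt  # kg
  # keep total sediment-side removals within the inventory
  lossSed <- resusp + burial + pmax(diff, 0)
  scale <- pmin(1, mSed / pmax(lossSed, .Machine$double.xmin))
  resusp <- resusp * scale
  burial <- burial * scale
  diff <- ifelse(diff > 0, diff * scale, diff)
  state$cont$mSurf <- state$cont$mSurf - settleS
  state$cont$mDeep <- state$cont$mDeep + settleS - settleD + resusp + diff
  state$cont$mSed <- mSed + settleD - resusp - burial - diff
  b <- state$budget
  b["contSettling"] <- b["contSettling"] + sum(settleD)
  b["contResuspension"] <- b["contResuspension"] + sum(resusp)
  b["contBurial"] <- b["contBurial"] + sum(burial)
  state$budget <- b
  state
}

#' Contaminant process steps
#'
#' The four process operators applied to the contaminant state each day, in
#' the engine's operator-splitting order: advection with the water flows,
#' air-water exchange, transformation losses, settling and sediment
#' exchange. Exposed individually for testing and for building custom
#' drivers; [runSimulation()] composes them.
#'
#' `advectContaminant` carries total (all-phase) concentration with every
#' water flow, adds the river contaminant load and removes mass permanently
#' through the open boundary. `transformationLosses` applies first-order
#' hydrolysis to the truly dissolved fraction only (particle-sorbed mass is
#' persistent), biodegradation to dissolved + DOC-bound mass, and sediment
#' degradation to the sediment pool, all Arrhenius-corrected.
#' `settleExchangeSediment` moves POC-bound mass downward with the detritus
#' sinking velocity, and exchanges sediment mass by resuspension, burial
#' (permanent) and porewater diffusion. `airWaterExchange` applies the
#' [airWaterFlux()] two-film flux, blocked by ice.
#'
#' @inheritParams stepBiogeo
#' @param chem a [ChemicalProperties-class].
#' @return the updated state list.
#' @name contaminantSteps
NULL

#' @rdname contaminantSteps
#' @export
advectContaminant <- function(state, geom, fd, hydro = hydroParams(),
                              flows = NULL, dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  grid <- makeGrid(geom)
  if (is.null(flows)) flows <- computeFlows(grid, fd, hydro)
  .advectContaminant(state, grid, fd, hydro, flows, dt)
}

#' @rdname contaminantSteps
#' @export
airWaterExchange <- function(state, geom, fd, chem, dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  grid <- makeGrid(geom)
  .airWaterExchange(state, grid, fd, chem, layerFractions(state, chem),
                    dt)$state
}

#' @rdname contaminantSteps
#' @export
transformationLosses <- function(state, geom, chem, dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  grid <- makeGrid(geom)
  .transformationLosses(state, grid, chem, layerFractions(state, chem), dt)
}

#' @rdname contaminantSteps
#' @export
settleExchangeSediment <- function(state, geom, chem,
                                   params = biogeoParams(), dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  grid <- makeGrid(geom)
  .settleExchangeSediment(state, grid, chem, params,
                          layerFractions(state, chem), dt)
}

#' Contaminant concentrations derived from a state
#'
#' @param state a state list.
#' @param geom a [BasinGeometry-class].
#' @param chem a [ChemicalProperties-class].
#' @return data.frame per basin with bulk-water totals (ng/L), the truly
#'   dissolved surface concentration `cwDissolved` (pg/L bulk water, the
#'   field-standard C_W), phase fractions and the sediment concentration
#'   (ng/g dry weight).
#' @export
contaminantConcentrations <- function(state, geom, chem) {
  grid <- makeGrid(geom)
  frac <- layerFractions(state, chem)
  cSurf <- state$cont$mSurf / grid$vSurf * 1e9    # kg/m3 -> ng/L
  cDeep <- state$cont$mDeep / grid$vDeep * 1e9
  sedMass <- grid$area * grid$sedThickness * grid$sedDensity * 1000  # g dw
  data.frame(basin = grid$ids,
             cwTotal = cSurf,
             cwDissolved = frac$surf$fDiss * cSurf * 1000,  # pg/L
             cDeepTotal = cDeep,
             fDiss = frac$surf$fDiss, fDoc = frac$surf$fDoc,
             fPoc = frac$surf$fPoc,
             sedConc = state$cont$mSed * 1e9 / sedMass,     # ng/g dw
             row.names = NULL)
}
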