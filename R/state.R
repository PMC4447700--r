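# System state: plain lists of per-basin vectors/matrices, kept lightweight
# because they are touched ~10^4 times per simulated century.

BIO_SURF_POOLS <- c("din", "dip", "phy", "det", "doc")
BIO_DEEP_POOLS <- c("din", "dip", "det", "doc")

# Precompute the loop-friendly view of a geometry.
makeGrid <- function(geom) {
  b <- geom@basins
  cn <- geom@connections
  ids <- b$id
  ord <- routingOrder(b, cn)
  conn <- data.frame(fromIdx = match(cn$from, ids),
                     toIdx = match(cn$to, ids), fraction = cn$fraction)
  qDeep <- setNames(numeric(length(ids)), ids)
  # flow-weighted properties of the deep inflow when several rows feed a basin
  wavg <- function(col) {
    tot <- setNames(numeric(length(ids)), ids)
    for (k in seq_len(nrow(cn))) {
      tot[cn$from[k]] <- tot[cn$from[k]] + cn$deepInflowRate[k] * col[k]
    }
    ifelse(qDeep > 0, tot / pmax(qDeep, .Machine$double.xmin), 0)
  }
  for (k in seq_len(nrow(cn))) {
    qDeep[cn$from[k]] <- qDeep[cn$from[k]] + cn$deepInflowRate[k]
  }
  sIn <- wavg(cn$deepInflowSalinity)
  cIn <- list(din = wavg(cn$deepInflowDin), dip = wavg(cn$deepInflowDip),
              det = wavg(cn$deepInflowDet), doc = wavg(cn$deepInflowDoc),
              contaminant = wavg(cn$deepInflowCont))
  list(ids = ids, nb = length(ids), area = setNames(b$area, ids),
       hSurf = setNames(b$hSurf, ids), hDeep = setNames(b$hDeep, ids),
       vSurf = setNames(b$area * b$hSurf, ids),
       vDeep = setNames(b$area * b$hDeep, ids),
       orderIdx = match(ord, ids), conn = conn,
       qDeep = qDeep, sIn = sIn, cIn = cIn, boundaryIdx = which(b$boundary),
       sedThickness = setNames(b$sedThickness, ids),
       sedDensity = setNames(b$sedDensity, ids),
       sedResuspension = setNames(b$sedResuspension, ids),
       sedBurial = setNames(b$sedBurial, ids),
       sedDiffVelocity = setNames(b$sedDiffVelocity, ids),
       boundaryConc = geom@boundaryConc)
}

BUDGET_FIELDS <- c(
  "waterIn", "waterOut", "saltIn", "saltOut",
  "nRiver", "nBoundaryIn", "nBoundaryOut", "nBurial",
  "pRiver", "pBoundaryIn", "pBoundaryOut", "pBurial",
  "contRiver", "contBoundaryIn", "contBoundaryOut", "contAbsorb",
  "contVolat", "contHydrolysis", "contBiodegWater", "contBiodegSed",
  "contBurial", "contSettling", "contResuspension")

#' Initial system state
#'
#' Builds the combined physical + biogeochemical + contaminant state of all
#' basins, layers and sediments at one time, as a plain list with elements
#' `phys` (tSurf, tDeep degC; sSurf, sDeep PSU; ice fraction 0-1; fdd
#' freezing-degree-day sum, degC day), `bio` (`surf`: basins x (din, dip,
#' phy, det, doc) in mg/m3; `deep`: basins x (din, dip, det, doc); `sedOC`:
#' g C/m2), `cont` (mSurf, mDeep, mSed: kg per basin) and `budget`
#' (cumulative process fluxes, kg or m3).
#'
#' @param geom a [BasinGeometry-class].
#' @param init named list of overrides for any state element, e.g.
#'   `list(sSurf = c(bothnian = 2, ...))` or `list(bioSurf =
#'   list(din = 30))`.
#' @return a state list as described.
#' @export
initialState <- function(geom, init = list()) {
  grid <- makeGrid(geom)
  ids <- grid$ids
  nb <- grid$nb
  vec <- function(x) {
    if (length(x) == 1) x <- rep(x, nb)
    setNames(as.numeric(x), ids)
  }
  phys <- list(tSurf = vec(4), tDeep = vec(3),
               sSurf = vec(0.6 * grid$sIn), sDeep = vec(grid$sIn),
               ice = vec(0), fdd = vec(0))
  surfDefaults <- c(din = 30, dip = 5, phy = 5, det = 5, doc = 500)
  deepDefaults <- c(din = 50, dip = 10, det = 5, doc = 500)
  bio <- list(
    surf = matrix(rep(surfDefaults, each = nb), nb,
                  dimnames = list(ids, BIO_SURF_POOLS)),
    deep = matrix(rep(deepDefaults, each = nb), nb,
                  dimnames = list(ids, BIO_DEEP_POOLS)),
    sedOC = vec(100))
  cont <- list(mSurf = vec(0), mDeep = vec(0), mSed = vec(0))
  st <- list(phys = phys, bio = bio, cont = cont,
             budget = setNames(numeric(length(BUDGET_FIELDS)), BUDGET_FIELDS))
  for (nm in intersect(names(init), names(st$phys))) st$phys[[nm]] <- vec(init[[nm]])
  for (nm in intersect(names(init), names(st$cont))) st$cont[[nm]] <- vec(init[[nm]])
  if (!is.null(init$bioSurf)) {
    for (p in names(init$bioSurf)) st$bio$surf[, p] <- init$bioSurf[[p]]
  }
  if (!is.null(init$bioDeep)) {
    for (p in names(init$bioDeep)) st$bio$deep[, p] <- init$bioDeep[[p]]
  }
  if (!is.null(init$sedOC)) st$bio$sedOC <- vec(init$sedOC)
  st
}

#' Extract one day of forcing
#'
#' @param fs a [ForcingSeries-class].
#' @param i day index (1-based).
#' @return named list of per-basin numeric vectors, one per forcing
#'   variable, plus `year` and `doy` scalars.
#' @export
forcingDay <- function(fs, i) {
  out <- lapply(fs@data, function(m) m[i, ])
  out$year <- fs@year[i]
  out$doy <- fs@doy[i]
  out
}

# --- conserved-quantity inventories (kg; water in m3) -----------------------

saltInventory <- function(state, grid) {
  sum(state$phys$sSurf * grid$vSurf + state$phys$sDeep * grid$vDeep)
}

nitrogenInventory <- function(state, grid, params) {
  bs <- state$bio$surf; bd <- state$bio$deep
  wat <- sum((bs[, "din"] + params$ncRatio * (bs[, "phy"] + bs[, "det"])) *
               grid$vSurf) +
    sum((bd[, "din"] + params$ncRatio * bd[, "det"]) * grid$vDeep)
  sed <- sum(params$ncRatio * state$bio$sedOC * grid$area / 1000)  # g -> kg
  wat * 1e-6 + sed  # mg -> kg for the water part
}

phosphorusInventory <- function(state, grid, params) {
  bs <- state$bio$surf; bd <- state$bio$deep
  wat <- sum((bs[, "dip"] + params$pcRatio * (bs[, "phy"] + bs[, "det"])) *
               grid$vSurf) +
    sum((bd[, "dip"] + params$pcRatio * bd[, "det"]) * grid$vDeep)
  sed <- sum(params$pcRatio * state$bio$sedOC * grid$area / 1000)
  wat * 1e-6 + sed
}

contaminantInventory <- function(state) {
  sum(state$cont$mSurf + state$cont$mDeep + state$cont$mSed)
}

# Advect one tracer's surface/deep masses with the day's flows.
# mS, mD: per-basin masses; cBound: per-basin concentration (mass/m3) of the
# deep-inflow water; riverIn: per-basin mass/day entering the surface layer.
# Returns updated masses plus the boundary exchange amounts.
advectTracer <- function(mS, mD, grid, flows, cBound, riverIn, vMix, dt) {
  cS <- mS / grid$vSurf
  cD <- mD / grid$vDeep
  inflow <- numeric(grid$nb)
  conn <- grid$conn
  for (k in seq_len(nrow(conn))) {
    to <- conn$toIdx[k]
    if (!is.na(to)) {
      inflow[to] <- inflow[to] +
        conn$fraction[k] * flows$qOut[conn$fromIdx[k]] * cS[conn$fromIdx[k]]
    }
  }
  mix <- vMix * grid$area * (cD - cS)
  boundaryIn <- sum(grid$qDeep * cBound) * dt
  bIdx <- grid$boundaryIdx
  boundaryOut <- flows$qOut[bIdx] * cS[bIdx] * dt
  mS2 <- mS + dt * (inflow + grid$qDeep * cD + riverIn - flows$qOut * cS + mix)
  mD2 <- mD + dt * (grid$qDeep * cBound - grid$qDeep * cD - mix)
  list(mS = mS2, mD = mD2, boundaryIn = boundaryIn, boundaryOut = boundaryOut)
}
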