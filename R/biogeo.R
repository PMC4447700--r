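# Biogeo module: nutrient-phytoplankton-detritus dynamics with DOC/POC,
# sediment organic carbon, and strict N/P bookkeeping. Concentrations in
# mg/m3 (N, P or C basis), sediment OC in g C/m2.

q10Factor <- function(q10, temp) q10^((temp - 20) / 10)

monod <- function(x, k) if (k <= 0) rep(1, length(x)) else x / (x + k)

.stepBiogeo <- function(state, grid, fd, params, hydro, flows, dt) {
  bs <- state$bio$surf
  bd <- state$bio$deep
  sedOC <- state$bio$sedOC
  nc <- params$ncRatio
  pc <- params$pcRatio

  # --- surface layer processes ---------------------------------------------
  tS <- state$phys$tSurf
  iEff <- fd$radiation * params$lightAttenuation *
    (1 - params$lightIceBlock * state$phys$ice)
  light <- monod(iEff, params$kI)
  lim <- pmin(monod(bs[, "din"], params$kN), monod(bs[, "dip"], params$kP))
  growth <- params$muMax * q10Factor(params$q10Growth, tS) * light * lim *
    bs[, "phy"] * dt
  growth <- pmin(growth, bs[, "din"] / nc, bs[, "dip"] / pc)  # hard supply cap
  mort <- pmin(params$mortality * dt, 1) * bs[, "phy"]
  toDoc <- params$docExudation * mort
  toDet <- mort - toDoc
  minerS <- params$rMin20 * q10Factor(params$q10Mineralization, tS) *
    bs[, "det"] * dt
  sinkS <- params$sinkingVelocity / grid$hSurf * bs[, "det"] * dt
  detScale <- pmin(1, bs[, "det"] / pmax(minerS + sinkS, .Machine$double.xmin))
  minerS <- minerS * detScale
  sinkS <- sinkS * detScale
  docLossS <- pmin(params$docDecay * dt, 1) * bs[, "doc"]

  bs[, "phy"] <- bs[, "phy"] + growth - mort
  bs[, "det"] <- bs[, "det"] + toDet - minerS - sinkS
  bs[, "din"] <- bs[, "din"] + nc * (minerS + toDoc - growth)
  bs[, "dip"] <- bs[, "dip"] + pc * (minerS + toDoc - growth)
  bs[, "doc"] <- bs[, "doc"] + toDoc - docLossS

  # --- deep layer ------------------------------------------------------------
  tD <- state$phys$tDeep
  minerD <- params$rMin20 * q10Factor(params$q10Mineralization, tD) *
    bd[, "det"] * dt
  sinkD <- params$sinkingVelocity / grid$hDeep * bd[, "det"] * dt
  detScaleD <- pmin(1, bd[, "det"] / pmax(minerD + sinkD, .Machine$double.xmin))
  minerD <- minerD * detScaleD
  sinkD <- sinkD * detScaleD
  docLossD <- pmin(params$docDecay * dt, 1) * bd[, "doc"]

  bd[, "det"] <- bd[, "det"] + sinkS * grid$vSurf / grid$vDeep - minerD - sinkD
  bd[, "doc"] <- bd[, "doc"] - docLossD
  bd[, "din"] <- bd[, "din"] + nc * minerD
  bd[, "dip"] <- bd[, "dip"] + pc * minerD

  # --- sediment organic carbon (g C/m2) --------------------------------------
  deposition <- sinkD * grid$hDeep / 1000           # mg C/m3 * m -> g C/m2
  sedMin <- params$sedMineralization * q10Factor(params$q10Mineralization, tD) *
    sedOC * dt
  sedBur <- grid$sedBurial * sedOC * dt
  sedScale <- pmin(1, sedOC / pmax(sedMin + sedBur, .Machine$double.xmin))
  sedMin <- sedMin * sedScale
  sedBur <- sedBur * sedScale
  sedOC <- sedOC + deposition - sedMin - sedBur
  # mineralized sediment OC returns nutrients to the deep layer
  bd[, "din"] <- bd[, "din"] + nc * sedMin * 1000 / grid$hDeep
  bd[, "dip"] <- bd[, "dip"] + pc * sedMin * 1000 / grid$hDeep

  # --- river loads (kg/day -> mg) --------------------------------------------
  bs[, "din"] <- bs[, "din"] + fd$dinLoad * 1e6 * dt / grid$vSurf
  bs[, "dip"] <- bs[, "dip"] + fd$dipLoad * 1e6 * dt / grid$vSurf
  bs[, "doc"] <- bs[, "doc"] + fd$discharge * fd$riverDoc * dt / grid$vSurf

  # --- advection --------------------------------------------------------------
  outN <- 0; outP <- 0
  for (p in BIO_DEEP_POOLS) {
    adv <- advectTracer(bs[, p] * grid$vSurf, bd[, p] * grid$vDeep, grid,
                        flows, grid$cIn[[p]], riverIn = 0,
                        vMix = hydro$vMix, dt = dt)
    bs[, p] <- adv$mS / grid$vSurf
    bd[, p] <- adv$mD / grid$vDeep
    nIn <- switch(p, din = adv$boundaryIn, det = nc * adv$boundaryIn, 0)
    nOut <- switch(p, din = adv$boundaryOut, det = nc * adv$boundaryOut, 0)
    pIn <- switch(p, dip = adv$boundaryIn, det = pc * adv$boundaryIn, 0)
    pOut <- switch(p, dip = adv$boundaryOut, det = pc * adv$boundaryOut, 0)
    state$budget["nBoundaryIn"] <- state$budget["nBoundaryIn"] + nIn * 1e-6
    state$budget["pBoundaryIn"] <- state$budget["pBoundaryIn"] + pIn * 1e-6
    outN <- outN + nOut
    outP <- outP + pOut
  }
  # phytoplankton lives in the surface chain only (no deep pool, no mixing)
  mPhy <- bs[, "phy"] * grid$vSurf
  cPhy <- bs[, "phy"]
  inflow <- numeric(grid$nb)
  conn <- grid$conn
  for (k in seq_len(nrow(conn))) {
    to <- conn$toIdx[k]
    if (!is.na(to)) {
      inflow[to] <- inflow[to] +
        conn$fraction[k] * flows$qOut[conn$fromIdx[k]] * cPhy[conn$fromIdx[k]]
    }
  }
  phyOut <- flows$qOut[grid$boundaryIdx] * cPhy[grid$boundaryIdx] * dt
  mPhy <- mPhy + dt * (inflow - flows$qOut * cPhy)
  bs[, "phy"] <- mPhy / grid$vSurf
  outN <- outN + nc * phyOut
  outP <- outP + pc * phyOut

  b <- state$budget
  b["nRiver"] <- b["nRiver"] + sum(fd$dinLoad) * dt
  b["pRiver"] <- b["pRiver"] + sum(fd$dipLoad) * dt
  b["nBoundaryOut"] <- b["nBoundaryOut"] + outN * 1e-6
  b["pBoundaryOut"] <- b["pBoundaryOut"] + outP * 1e-6
  b["nBurial"] <- b["nBurial"] + sum(nc * sedBur * grid$area) / 1000
  b["pBurial"] <- b["pBurial"] + sum(pc * sedBur * grid$area) / 1000
  state$budget <- b

  if (any(bs < 0) || any(bd < 0) || any(sedOC < 0)) {
    stop("numerical stability error: negative biogeochemical pool; ",
         "use a smaller dt")
  }
  state$bio$surf <- bs
  state$bio$deep <- bd
  state$bio$sedOC <- sedOC
  state
}

#' Advance nutrient-phytoplankton-detritus dynamics by one step
#'
#' Phytoplankton grow at `muMax` scaled by a Q10 temperature factor, a
#' light Monod term on ice-attenuated shortwave radiation and the minimum of
#' the DIN and DIP Monod terms, consuming nutrients in Redfield proportion
#' (growth is hard-capped at the available nutrient so pools stay
#' non-negative). Mortality routes carbon to detritus and, for the
#' exudation fraction, to DOC (exudate N and P are remineralized
#' immediately, keeping elemental budgets closed while DOC stays a
#' carbon-only pool). Detritus mineralizes back to DIN/DIP at a
#' temperature-dependent rate and sinks through the deep layer into the
#' sediment, whose organic carbon mineralizes (returning nutrients to the
#' deep layer) and buries (the permanent loss logged in the N/P budgets).
#' River loads enter the surface layer; all pools are advected with the
#' water flows; POC is the derived sum phytoplankton + detritus carbon and
#' is never stored separately.
#'
#' @inheritParams stepWaterSalt
#' @param params parameters from [biogeoParams()].
#' @param flows daily flows as returned by [stepWaterSalt()]; computed from
#'   the geometry and forcing day when omitted.
#' @return the updated state list.
#' @export
stepBiogeo <- function(state, geom, fd, params = biogeoParams(),
                       hydro = hydroParams(), flows = NULL, dt = 1) {
  if (dt <= 0) stop("dt must be > 0")
  grid <- makeGrid(geom)
  if (is.null(flows)) flows <- computeFlows(grid, fd, hydro)
  .stepBiogeo(state, grid, fd, params, hydro, flows, dt)
}

#' Particulate organic carbon of the surface layer
#'
#' POC is defined as phytoplankton plus detritus carbon; it is derived,
#' never stored.
#'
#' @param state a state list.
#' @param layer "surface" or "deep" (deep POC is detritus only, since
#'   phytoplankton live in the surface layer).
#' @return named numeric vector, mg C/m3 per basin.
#' @export
pocConcentration <- function(state, layer = "surface") {
  if (layer == "surface") {
    state$bio$surf[, "phy"] + state$bio$surf[, "det"]
  } else {
    state$bio$deep[, "det"]
  }
}
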