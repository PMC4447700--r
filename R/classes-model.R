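# Basin geometry, chemical property card and process-parameter lists.

#' Basin geometry and connectivity
#'
#' Static description of the basin chain: per-basin hypsography collapsed to
#' two layers of fixed thickness (rigid lid, constant volumes), an active
#' sediment layer, and the surface routing graph with parameterized deep
#' (salty) inflows. Exactly one basin is the open boundary toward the
#' outside sea; surface outflow from that basin leaves the model domain.
#'
#' @slot basins data.frame with columns id, area (m2), hSurf, hDeep (m),
#'   latitude (deg), sedThickness (m), sedDensity (kg/m3 dry bulk),
#'   sedResuspension (1/day), sedBurial (1/day), sedDiffVelocity (m/day),
#'   boundary (logical; exactly one TRUE).
#' @slot connections data.frame with columns from, to (downstream neighbour
#'   id; NA for the boundary basin, whose outflow leaves the domain),
#'   fraction (share of surface outflow routed to `to`; per-basin sums to 1),
#'   deepInflowRate (m3/day entering the deep layer of `from`),
#'   deepInflowSalinity (PSU of that inflow), and optionally per-connection
#'   tracer concentrations of the inflowing water: deepInflowDin,
#'   deepInflowDip (mg/m3), deepInflowDet, deepInflowDoc (mg C/m3),
#'   deepInflowCont (ng/m3). Missing values fall back to `boundaryConc`.
#' @slot boundaryConc named list of default tracer concentrations carried by
#'   deep inflow water: din, dip (mg/m3), det, doc (mg C/m3), contaminant
#'   (ng/m3).
#' @export
setClass("BasinGeometry",
  representation(basins = "data.frame", connections = "data.frame",
                 boundaryConc = "list"))

setValidity("BasinGeometry", function(object) {
  b <- object@basins
  cn <- object@connections
  msg <- character()
  need <- c("id", "area", "hSurf", "hDeep", "latitude", "sedThickness",
            "sedDensity", "sedResuspension", "sedBurial", "sedDiffVelocity",
            "boundary")
  if (!all(need %in% names(b))) {
    return(paste("basins must have columns", paste(need, collapse = ", ")))
  }
  if (any(b$area <= 0) || any(b$hSurf <= 0) || any(b$hDeep <= 0) ||
      any(b$sedThickness <= 0) || any(b$sedDensity <= 0)) {
    msg <- c(msg, "areas, layer thicknesses and sediment properties must be > 0")
  }
  if (sum(b$boundary) != 1L) {
    msg <- c(msg, "exactly one basin must be the open boundary")
  }
  if (anyDuplicated(b$id)) msg <- c(msg, "basin ids must be unique")
  cneed <- c("from", "to", "fraction", "deepInflowRate", "deepInflowSalinity")
  if (!all(cneed %in% names(cn))) {
    return(paste("connections must have columns", paste(cneed, collapse = ", ")))
  }
  if (!all(cn$from %in% b$id)) msg <- c(msg, "unknown basin in connections$from")
  if (!all(is.na(cn$to) | cn$to %in% b$id)) {
    msg <- c(msg, "unknown basin in connections$to")
  }
  if (any(cn$deepInflowRate < 0) || any(cn$deepInflowSalinity < 0)) {
    msg <- c(msg, "deep inflow rate and salinity must be >= 0")
  }
  for (id in b$id) {
    rows <- cn$from == id
    if (!any(rows)) {
      msg <- c(msg, paste0("basin ", id, " has no connection row"))
    } else if (abs(sum(cn$fraction[rows]) - 1) > 1e-12) {
      msg <- c(msg, paste0("outflow fractions of ", id, " must sum to 1"))
    }
  }
  # routing must reach the boundary from every basin (no cycles, connected)
  if (!length(msg)) {
    ord <- tryCatch(routingOrder(b, cn), error = function(e) NULL)
    if (is.null(ord)) {
      msg <- c(msg, "surface routing must form an acyclic graph draining to the boundary basin")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

# Topological order of the surface routing graph, upstream first.
routingOrder <- function(basins, connections) {
  ids <- basins$id
  depth <- setNames(rep(NA_real_, length(ids)), ids)
  bnd <- ids[basins$boundary]
  depth[bnd] <- 0
  for (i in seq_len(length(ids) + 1L)) {
    done <- TRUE
    for (k in seq_len(nrow(connections))) {
      fr <- connections$from[k]; to <- connections$to[k]
      if (is.na(to)) next
      if (!is.na(depth[to]) && (is.na(depth[fr]) || depth[fr] < depth[to] + 1)) {
        if (i > length(ids)) stop("cycle in routing graph")
        depth[fr] <- depth[to] + 1
        done <- FALSE
      }
    }
    if (done) break
  }
  if (any(is.na(depth))) stop("basins disconnected from the boundary")
  ids[order(depth, decreasing = TRUE)]
}

#' Construct a basin geometry
#'
#' @param basins,connections,boundaryConc see [BasinGeometry-class]. Columns
#'   `fraction` (default 1), sediment rate columns and `boundaryConc`
#'   entries get sensible defaults when omitted.
#' @return A [BasinGeometry-class] object.
#' @seealso [balticGeometry()] for the default four-basin Baltic-like chain.
#' @export
basinGeometry <- function(basins, connections,
                          boundaryConc = list(din = 80, dip = 25, det = 0,
                                              doc = 3000, contaminant = 0)) {
  basins <- as.data.frame(basins)
  connections <- as.data.frame(connections)
  defaults <- list(latitude = 60, sedThickness = 0.03, sedDensity = 400,
                   sedResuspension = 1e-4, sedBurial = 5e-5,
                   sedDiffVelocity = 0.01, boundary = FALSE)
  for (nm in names(defaults)) {
    if (is.null(basins[[nm]])) basins[[nm]] <- defaults[[nm]]
  }
  if (is.null(connections$fraction)) connections$fraction <- 1
  if (is.null(connections$deepInflowRate)) connections$deepInflowRate <- 0
  if (is.null(connections$deepInflowSalinity)) connections$deepInflowSalinity <- 0
  bc <- modifyList(list(din = 0, dip = 0, det = 0, doc = 0, contaminant = 0),
                   boundaryConc)
  tracerCols <- c(deepInflowDin = "din", deepInflowDip = "dip",
                  deepInflowDet = "det", deepInflowDoc = "doc",
                  deepInflowCont = "contaminant")
  for (col in names(tracerCols)) {
    if (is.null(connections[[col]])) {
      connections[[col]] <- bc[[tracerCols[[col]]]]
    } else {
      connections[[col]][is.na(connections[[col]])] <- bc[[tracerCols[[col]]]]
    }
  }
  new("BasinGeometry", basins = basins, connections = connections,
      boundaryConc = bc)
}

#' @rdname basinIds
#' @export
setMethod("basinIds", "BasinGeometry", function(x) x@basins$id)

#' Layer volumes of a basin geometry
#'
#' @param geom a [BasinGeometry-class].
#' @return list with numeric vectors `surface` and `deep` (m3, named by
#'   basin id).
#' @export
layerVolumes <- function(geom) {
  b <- geom@basins
  list(surface = setNames(b$area * b$hSurf, b$id),
       deep = setNames(b$area * b$hDeep, b$id))
}

setMethod("show", "BasinGeometry", function(object) {
  b <- object@basins
  cat(sprintf("BasinGeometry: %d basins (boundary: %s)\n", nrow(b),
              b$id[b$boundary]))
  print(b[, c("id", "area", "hSurf", "hDeep", "latitude")], row.names = FALSE)
})

#' Chemical property card
#'
#' Partitioning and transformation properties of one neutral organic
#' chemical. Partition coefficients are given at 25 degC and corrected to
#' ambient temperature by van't Hoff using internal energies of phase
#' transfer, `K(T) = K25 * exp((dU/R) * (1/T - 1/298.15))`; degradation
#' rates by Arrhenius, `k(T) = k25 * exp((Ea/R) * (1/298.15 - 1/T))`.
#'
#' @slot name chemical name.
#' @slot logKow,logKaw log10 octanol-water and air-water partition
#'   coefficients at 25 degC (dimensionless).
#' @slot logKoc log10 organic-carbon-water partition coefficient (L/kg);
#'   NA when `kocMode = "fromKow"`, in which case K_OC = 0.41 * K_OW.
#' @slot kocMode "direct" or "fromKow".
#' @slot kdocFraction K_DOC as a fraction of K_OC.
#' @slot dUaw,dUow internal energies of air-water and organic-carbon-water
#'   phase transfer (J/mol).
#' @slot hydrolysisRate25 first-order hydrolysis rate of the truly
#'   dissolved phase at 25 degC (1/day), with activation energy
#'   `hydrolysisEa` (J/mol).
#' @slot biodegWater25,biodegWaterEa biodegradation of dissolved + DOC-bound
#'   chemical in water (1/day at 25 degC; J/mol).
#' @slot biodegSed25,biodegSedEa degradation in sediment (1/day at 25 degC;
#'   J/mol).
#' @export
setClass("ChemicalProperties",
  representation(name = "character", logKow = "numeric", logKaw = "numeric",
                 logKoc = "numeric", kocMode = "character",
                 kdocFraction = "numeric", dUaw = "numeric", dUow = "numeric",
                 hydrolysisRate25 = "numeric", hydrolysisEa = "numeric",
                 biodegWater25 = "numeric", biodegWaterEa = "numeric",
                 biodegSed25 = "numeric", biodegSedEa = "numeric"))

setValidity("ChemicalProperties", function(object) {
  msg <- character()
  rates <- c(object@hydrolysisRate25, object@biodegWater25, object@biodegSed25)
  if (any(rates < 0)) msg <- c(msg, "transformation rates must be >= 0")
  if (!object@kocMode %in% c("direct", "fromKow")) {
    msg <- c(msg, "kocMode must be 'direct' or 'fromKow'")
  }
  if (object@kocMode == "direct" && !is.finite(object@logKoc)) {
    msg <- c(msg, "logKoc required when kocMode = 'direct'")
  }
  if (object@kdocFraction < 0) msg <- c(msg, "kdocFraction must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a chemical property card
#'
#' @param name chemical name.
#' @param logKow,logKaw,logKoc log10 partition coefficients at 25 degC.
#' @param kocMode "direct" (use `logKoc`) or "fromKow" (Karickhoff-type
#'   K_OC = 0.41 K_OW).
#' @param kdocFraction K_DOC / K_OC ratio.
#' @param dUaw,dUow internal energies of phase transfer (J/mol).
#' @param hydrolysisRate25,hydrolysisEa hydrolysis rate (1/day at 25 degC)
#'   and activation energy (J/mol).
#' @param biodegWater25,biodegWaterEa,biodegSed25,biodegSedEa biodegradation
#'   rates (1/day at 25 degC) and activation energies (J/mol).
#' @return A [ChemicalProperties-class] object.
#' @seealso [d5Properties()] for the decamethylcyclopentasiloxane defaults.
#' @export
chemicalProperties <- function(name, logKow, logKaw, logKoc = NA_real_,
                               kocMode = "direct", kdocFraction = 0.1,
                               dUaw = -30000, dUow = -20000,
                               hydrolysisRate25 = 0, hydrolysisEa = 90000,
                               biodegWater25 = 0, biodegWaterEa = 50000,
                               biodegSed25 = 0, biodegSedEa = 50000) {
  new("ChemicalProperties", name = name, logKow = logKow, logKaw = logKaw,
      logKoc = logKoc, kocMode = kocMode, kdocFraction = kdocFraction,
      dUaw = dUaw, dUow = dUow, hydrolysisRate25 = hydrolysisRate25,
      hydrolysisEa = hydrolysisEa, biodegWater25 = biodegWater25,
      biodegWaterEa = biodegWaterEa, biodegSed25 = biodegSed25,
      biodegSedEa = biodegSedEa)
}

setMethod("show", "ChemicalProperties", function(object) {
  cat(sprintf(
    "ChemicalProperties: %s  logKow=%.2f logKaw=%.2f logKoc=%.2f (%s)\n",
    object@name, object@logKow, object@logKaw, log10(kocValue(object)),
    object@kocMode))
  cat(sprintf("  hydrolysis %.3g/day, biodeg water %.3g/day, sediment %.3g/day (25 degC)\n",
              object@hydrolysisRate25, object@biodegWater25,
              object@biodegSed25))
})

#' K_OC of a chemical card (L/kg at 25 degC)
#'
#' @param chem a [ChemicalProperties-class].
#' @return numeric K_OC in L/kg.
#' @export
kocValue <- function(chem) {
  if (chem@kocMode == "direct") 10^chem@logKoc else 0.41 * 10^chem@logKow
}

#' Physical process parameters
#'
#' Tunables of the heat/ice and water-balance model, returned as a named
#' list: `tauSurf`, `tauDeep` (days; relaxation of surface temperature
#' toward air temperature and of deep toward surface), `fddFull` (degC day
#' of accumulated freezing-degree-days giving complete ice cover),
#' `fddMemory` (the degree-day sum saturates at `fddMemory x fddFull`, a
#' thickness memory bounding how much spring warming the melt-out consumes;
#' the default 1 makes ice cover respond to warming as soon as it starts),
#' `iceEnabled` (FALSE zeroes the ice *fraction* while leaving the thermal
#' freezing-point dynamics untouched, isolating the gas-exchange blocking
#' mechanism in paired runs), `evapFraction` (evaporation as a fraction of
#' precipitation),
#' `radHeating` (degC per (W/m2 day) of shortwave heating; 0 by default so
#' water temperature tracks air temperature alone), `vMix` (m/day diffusive
#' surface-deep exchange velocity applied to salt, nutrients, organic
#' carbon and contaminant).
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
hydroParams <- function(...) {
  p <- modifyList(list(tauSurf = 14, tauDeep = 120, fddFull = 100,
                       fddMemory = 1, iceEnabled = TRUE, evapFraction = 0.8,
                       radHeating = 0, vMix = 0.05),
                  list(...))
  stopifnot(p$tauSurf > 0, p$tauDeep > 0, p$fddFull > 0, p$fddMemory >= 1,
            p$evapFraction >= 0, p$evapFraction <= 1, p$vMix >= 0)
  p
}

#' Biogeochemical parameters
#'
#' Named list of NPD/organic-carbon parameters: `muMax` (1/day at 20 degC),
#' `q10Growth`, `q10Mineralization` (dimensionless, >= 1), `kN`, `kP`
#' (half-saturation, mg N/m3 and mg P/m3; 0 disables that limitation),
#' `kI` (light half-saturation, W/m2 effective; 0 disables), `mortality`
#' (1/day), `rMin20` (detritus mineralization, 1/day at 20 degC),
#' `sinkingVelocity` (m/day), `ncRatio`, `pcRatio` (g N resp. g P per g C;
#' Redfield mass ratios C:N:P = 41:7.2:1), `docExudation` (fraction of
#' mortality routed to DOC), `docDecay` (1/day), `sedMineralization`,
#' (1/day at 20 degC), `lightAttenuation` (fraction of surface shortwave
#' available as mean water-column light), `lightIceBlock` (fraction of
#' light blocked by full ice cover).
#'
#' Sediment organic-carbon burial shares the per-basin `sedBurial` rate of
#' the geometry so that contaminant and carbon burial stay consistent.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
biogeoParams <- function(...) {
  p <- modifyList(list(muMax = 1.2, q10Growth = 2, q10Mineralization = 2,
                       kN = 10, kP = 3, kI = 25, mortality = 0.08,
                       rMin20 = 0.03, sinkingVelocity = 1.5,
                       ncRatio = 7.2 / 41, pcRatio = 1 / 41,
                       docExudation = 0.2, docDecay = 0.002,
                       sedMineralization = 2e-4, lightAttenuation = 0.25,
                       lightIceBlock = 0.9),
                  list(...))
  rates <- c(p$muMax, p$kN, p$kP, p$kI, p$mortality, p$rMin20,
             p$sinkingVelocity, p$docExudation, p$docDecay,
             p$sedMineralization)
  stopifnot(all(rates >= 0), p$q10Growth >= 1, p$q10Mineralization >= 1,
            p$docExudation <= 1)
  p
}
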