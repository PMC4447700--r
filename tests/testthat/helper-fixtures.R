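# Small programmatic fixtures shared across tests.

# One basin that is itself the open boundary.
singleBoxGeometry <- function(area = 1e6, hSurf = 10, hDeep = 10,
                              deepInflowRate = 0, deepInflowSalinity = 0,
                              sedResuspension = 1e-4, sedBurial = 5e-5,
                              sedDiffVelocity = 0.01,
                              boundaryConc = list(din = 0, dip = 0, det = 0,
                                                  doc = 0, contaminant = 0)) {
  basinGeometry(
    data.frame(id = "box", area = area, hSurf = hSurf, hDeep = hDeep,
               latitude = 58, sedThickness = 0.03, sedDensity = 400,
               sedResuspension = sedResuspension, sedBurial = sedBurial,
               sedDiffVelocity = sedDiffVelocity, boundary = TRUE),
    data.frame(from = "box", to = NA_character_, fraction = 1,
               deepInflowRate = deepInflowRate,
               deepInflowSalinity = deepInflowSalinity),
    boundaryConc = boundaryConc)
}

# Constant climatology (zero amplitude, zero noise) for any basin set.
constClimatology <- function(basins = "box", airTemp = 10, wind = 5,
                             precip = 0, radiation = 100, discharge = 0,
                             dinLoad = 0, dipLoad = 0, contRiverLoad = 0,
                             contAirConc = 0, riverDoc = 0, seed = 1L) {
  nb <- length(basins)
  rowset <- function(variable, mean) {
    data.frame(basin = basins, variable = variable,
               mean = rep(mean, length.out = nb), amplitude = 0,
               peakDoy = 200, noiseSd = 0)
  }
  met <- rbind(rowset("airTemp", airTemp), rowset("wind", wind),
               rowset("precip", precip), rowset("radiation", radiation),
               rowset("discharge", discharge))
  loads <- data.frame(basin = basins,
                      dinLoad = rep(dinLoad, length.out = nb),
                      dipLoad = rep(dipLoad, length.out = nb),
                      contRiverLoad = rep(contRiverLoad, length.out = nb),
                      contAirConc = rep(contAirConc, length.out = nb),
                      riverDoc = rep(riverDoc, length.out = nb))
  climatologyParams(basins, met, loads, seed = seed)
}

# One constant day of forcing for a geometry.
constForcingDay <- function(geom, airTemp = 10, wind = 5, precip = 0,
                            radiation = 100, discharge = 0, dinLoad = 0,
                            dipLoad = 0, contRiverLoad = 0, contAirConc = 0,
                            riverDoc = 0) {
  ids <- basinIds(geom)
  rep1 <- function(x) setNames(rep(x, length.out = length(ids)), ids)
  list(airTemp = rep1(airTemp), wind = rep1(wind), precip = rep1(precip),
       radiation = rep1(radiation), discharge = rep1(discharge),
       dinLoad = rep1(dinLoad), dipLoad = rep1(dipLoad),
       contRiverLoad = rep1(contRiverLoad), contAirConc = rep1(contAirConc),
       riverDoc = rep1(riverDoc), year = 2000L, doy = 1L)
}

# A chemical with negligible sorption and no degradation.
inertChemical <- function(...) {
  args <- modifyList(
    list(name = "inert", logKow = 4, logKaw = 0, logKoc = -6,
         kocMode = "direct", kdocFraction = 0, dUaw = 0, dUow = 0,
         hydrolysisRate25 = 0, hydrolysisEa = 0, biodegWater25 = 0,
         biodegWaterEa = 0, biodegSed25 = 0, biodegSedEa = 0),
    list(...))
  do.call(chemicalProperties, args)
}

# Total nitrogen / phosphorus (kg) currently in the model domain, plus
# cumulative burial, for conservation checks. Mirrors the engine's
# accounting but is recomputed here from the raw pools.
totalNitrogenKg <- function(state, geom, params) {
  grid <- baltfate:::makeGrid(geom)
  bs <- state$bio$surf
  bd <- state$bio$deep
  nc <- params$ncRatio
  wat <- sum((bs[, "din"] + nc * (bs[, "phy"] + bs[, "det"])) * grid$vSurf) +
    sum((bd[, "din"] + nc * bd[, "det"]) * grid$vDeep)
  wat * 1e-6 + sum(nc * state$bio$sedOC * grid$area) / 1000
}
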