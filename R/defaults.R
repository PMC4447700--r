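# Ready-made Baltic-like default configuration: a four-basin chain
# (Bothnian Bay analogue -> Gotland Sea analogue -> Fehmarn Belt analogue ->
# Kattegat-like open boundary) with magnitudes typical of the Baltic Sea at
# box-model fidelity. Synthetic stand-ins, not a calibrated Baltic setup.

#' Default Baltic-like basin geometry
#'
#' Four basins in a chain draining to an open boundary: `bothnian`
#' (northern, fresh, seasonally ice covered), `gotland` (central, largest),
#' `fehmarn` (southern strait) and `kattegat` (open boundary toward the
#' outside sea). Deep salty inflows enter each basin's deep layer and are
#' entrained upward, yielding a surface salinity gradient from about 2 PSU
#' in the north to about 13 PSU at the boundary.
#'
#' @param ... overrides forwarded to nothing; present so future knobs can be
#'   added without breaking callers.
#' @return A [BasinGeometry-class].
#' @export
balticGeometry <- function(...) {
  basins <- data.frame(
    id = c("bothnian", "gotland", "fehmarn", "kattegat"),
    area = c(3.6e10, 2.1e11, 5e9, 2e10),          # m2
    hSurf = c(20, 20, 10, 15),                    # m
    hDeep = c(20, 40, 10, 15),
    latitude = c(65, 57.5, 54.5, 57),
    sedThickness = 0.03, sedDensity = 400,
    sedResuspension = 1e-4, sedBurial = 5e-5, sedDiffVelocity = 0.01,
    boundary = c(FALSE, FALSE, FALSE, TRUE))
  connections <- data.frame(
    from = c("bothnian", "gotland", "fehmarn", "kattegat"),
    to = c("gotland", "fehmarn", "kattegat", NA),
    fraction = 1,
    deepInflowRate = c(3e8, 1.2e9, 1e9, 1e9),     # m3/day
    deepInflowSalinity = c(4, 12.5, 18, 28),      # PSU
    # nutrient-poor inflow to the oligotrophic north, richer in the south
    deepInflowDin = c(30, 80, 100, 100),          # mg N/m3
    deepInflowDip = c(4, 25, 30, 30),             # mg P/m3
    deepInflowDet = 0,
    deepInflowDoc = c(3500, 3000, 3000, 3000),    # mg C/m3
    deepInflowCont = 0)
  basinGeometry(basins, connections,
                boundaryConc = list(din = 80, dip = 25, det = 0, doc = 3000,
                                    contaminant = 0))
}

#' Default Baltic-like climatology and loads
#'
#' Sinusoidal seasonal cycles (day-of-year of the maximum in `peakDoy`) plus
#' interannual Gaussian anomalies, with annual means and amplitudes typical
#' of the Baltic: mild maritime south, cold north with sub-zero winters;
#' winter-peaking wind; spring-peaking river discharge. Nutrient and
#' contaminant loads are constant baselines: the central basin carries most
#' of the riverine nitrogen, phosphorus and contaminant input, the northern
#' basin is nutrient-poor (oligotrophic). The default contaminant loading is
#' strongly river-dominated (atmospheric concentration 0.5 ng/m3).
#'
#' @param seed integer seed of the weather generator.
#' @param nutrientScale multiplier applied to the baseline DIN and DIP
#'   loads (for load-response experiments).
#' @return A [ClimatologyParams-class].
#' @export
balticClimatology <- function(seed = 1L, nutrientScale = 1) {
  ids <- c("bothnian", "gotland", "fehmarn", "kattegat")
  met <- rbind(
    data.frame(basin = ids, variable = "airTemp",
               mean = c(2, 7, 8.5, 8), amplitude = c(11, 9, 8.5, 8),
               peakDoy = 200, noiseSd = 1.0),
    data.frame(basin = ids, variable = "wind",
               mean = 7, amplitude = 1.5, peakDoy = 15, noiseSd = 0.5),
    data.frame(basin = ids, variable = "precip",
               mean = 1.6e-3, amplitude = 4e-4, peakDoy = 270,
               noiseSd = 2e-4),
    data.frame(basin = ids, variable = "radiation",
               mean = c(95, 110, 115, 115), amplitude = c(95, 100, 100, 100),
               peakDoy = 172, noiseSd = 6),
    data.frame(basin = ids, variable = "discharge",
               mean = c(3e8, 6e8, 2e7, 1e8),
               amplitude = c(1.2e8, 1.8e8, 6e6, 3e7), peakDoy = 120,
               noiseSd = c(4e7, 6e7, 3e6, 1.2e7)))
  loads <- data.frame(
    basin = ids,
    dinLoad = nutrientScale * c(1.5e5, 6e5, 5e4, 1e5),   # kg N/day
    dipLoad = nutrientScale * c(1e3, 3e4, 2.5e3, 5e3),   # kg P/day
    contRiverLoad = c(5, 30, 1, 2),                      # kg/day
    contAirConc = 0.5,                                   # ng/m3
    riverDoc = 12000)                                    # mg C/m3
  climatologyParams(ids, met, loads, seed = seed)
}

#' Decamethylcyclopentasiloxane (D5) property card
#'
#' Default properties of the cyclic volatile methylsiloxane D5: highly
#' volatile (log K_AW 3.1), highly hydrophobic (log K_OW 8.1, log K_OC 5.2),
#' hydrolyzed in the truly dissolved phase (half-life 65 days at 25 degC,
#' Ea 90 kJ/mol) but persistent when sorbed to particles (POC-bound mass is
#' exempt from hydrolysis), negligible biodegradation in water and slow
#' degradation in sediment (half-life 1200 days at 25 degC). Values follow
#' the EU risk-assessment property profile for D5 at box-model fidelity;
#' every field is overridable.
#'
#' @param ... overrides passed to [chemicalProperties()].
#' @return A [ChemicalProperties-class].
#' @export
d5Properties <- function(...) {
  args <- modifyList(
    list(name = "D5", logKow = 8.1, logKaw = 3.1, logKoc = 5.2,
         kocMode = "direct", kdocFraction = 0.1, dUaw = -30000,
         dUow = -20000, hydrolysisRate25 = log(2) / 65,
         hydrolysisEa = 90000, biodegWater25 = 0, biodegWaterEa = 50000,
         biodegSed25 = log(2) / 1200, biodegSedEa = 50000),
    list(...))
  do.call(chemicalProperties, args)
}
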