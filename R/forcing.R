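# Scenario module: synthetic weather generation and scenario transforms.

# Run code with a local, seeded RNG stream without disturbing the caller's.
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random-weather (RW) forcing series
#'
#' Builds daily forcing on a 365-day calendar as a sinusoidal seasonal cycle
#' plus seeded Gaussian *annual* anomalies (one independent draw per basin,
#' variable and year; no interannual autocorrelation, so the series is
#' stationary with no trend). Non-negative variables (wind, precipitation,
#' radiation, discharge) are truncated at zero. River nutrient/contaminant
#' loads, river DOC and the atmospheric contaminant concentration are
#' constant baselines taken from the climatology, ready for the scenario
#' transforms. Identical parameters and seed give a bit-identical series;
#' the caller's RNG state is untouched.
#'
#' @param params a [ClimatologyParams-class].
#' @param startYear first simulated calendar year.
#' @param nYears number of years (>= 1).
#' @return A [ForcingSeries-class].
#' @examples
#' fs <- generateRWForcing(balticClimatology(seed = 7), 2000, 2)
#' dim(forcingVariable(fs, "airTemp"))
#' @export
generateRWForcing <- function(params, startYear, nYears) {
  if (!is(params, "ClimatologyParams")) stop("params must be ClimatologyParams")
  validObject(params)
  if (length(nYears) != 1 || is.na(nYears) || nYears < 1 ||
      nYears != round(nYears)) {
    stop("invalid argument: nYears must be a positive whole number")
  }
  nYears <- as.integer(nYears)
  basins <- params@basins
  nb <- length(basins)
  nd <- 365L * nYears
  doy <- rep.int(seq_len(365L), nYears)
  year <- rep(seq.int(startYear, length.out = nYears), each = 365L)
  data <- vector("list", length(FORCING_VARIABLES))
  names(data) <- FORCING_VARIABLES
  withLocalSeed(params@seed, {
    for (v in MET_VARIABLES) {
      m <- matrix(0, nd, nb)
      for (j in seq_len(nb)) {
        row <- params@met[params@met$basin == basins[j] &
                            params@met$variable == v, ]
        cyc <- row$mean + row$amplitude * cos(2 * pi * (doy - row$peakDoy) / 365)
        anom <- rep(rnorm(nYears, 0, row$noiseSd), each = 365L)
        m[, j] <- cyc + anom
      }
      if (v != "airTemp") m <- pmax(m, 0)
      data[[v]] <- m
    }
  })
  ld <- params@loads[match(basins, params@loads$basin), ]
  for (v in c("dinLoad", "dipLoad", "contRiverLoad", "contAirConc",
              "riverDoc")) {
    data[[v]] <- matrix(rep(ld[[v]], each = nd), nd, nb)
  }
  newForcingSeries(year, doy, basins, data)
}

a1bFactorSeries <- function(factor, n, ramp) {
  if (!ramp || n == 1L) return(rep(factor, n))
  1 + (factor - 1) * (seq_len(n) - 1) / (n - 1)
}

#' Apply the a1b climate-change transform to a forcing series
#'
#' Wind and precipitation are multiplied pointwise by their factors. Air
#' temperature is, by default (`a1bTempMode = "offset"`), shifted uniformly
#' per basin by `(factor - 1) x period-mean temperature`, so that the
#' period-mean degC ratio equals the factor exactly while every day (winters
#' included) gets warmer; `"multiplicative"` scales each degC value instead.
#' All other fields are unchanged. With `a1bRamp = TRUE` the factors grow
#' linearly from 1 at the series start to their full value at the end.
#'
#' @param base an RW [ForcingSeries-class].
#' @param spec a [ScenarioSpec-class] carrying the factors (defaults 1.07
#'   wind, 1.60 temperature, 1.20 precipitation).
#' @return A transformed [ForcingSeries-class].
#' @export
applyA1bTransform <- function(base, spec = scenarioSpec(climate = "a1b")) {
  validObject(spec)
  if (any(c(spec@a1bWindFactor, spec@a1bTempFactor, spec@a1bPrecipFactor) <= 0)) {
    stop("a1b factors must be > 0")
  }
  n <- length(base@year)
  data <- base@data
  wf <- a1bFactorSeries(spec@a1bWindFactor, n, spec@a1bRamp)
  pf <- a1bFactorSeries(spec@a1bPrecipFactor, n, spec@a1bRamp)
  tf <- a1bFactorSeries(spec@a1bTempFactor, n, spec@a1bRamp)
  data$wind <- data$wind * wf
  data$precip <- data$precip * pf
  if (spec@a1bTempMode == "multiplicative") {
    data$airTemp <- data$airTemp * tf
  } else {
    offset <- outer(tf - 1, colMeans(data$airTemp))
    data$airTemp <- data$airTemp + offset
  }
  newForcingSeries(base@year, base@doy, base@basins, data)
}

nutrientMultiplier <- function(spec, tFrac, startYear) {
  start <- if (is.na(spec@rampStartYear)) startYear else spec@rampStartYear
  ramp <- function(targetFactor, targetYear) {
    if (targetYear <= start) return(rep(targetFactor, length(tFrac)))
    frac <- pmin(pmax((tFrac - start) / (targetYear - start), 0), 1)
    1 + (targetFactor - 1) * frac
  }
  switch(spec@nutrients,
         CL = rep(1, length(tFrac)),
         IL = ramp(spec@ilTargetFactor, spec@ilTargetYear),
         BSAP = ramp(spec@bsapTargetFactor, spec@bsapTargetYear))
}

#' Apply a nutrient-load scenario to a forcing series
#'
#' `CL` holds river DIN/DIP loads at the baseline; `IL` scales them up a
#' linear ramp reaching `ilTargetFactor` at `ilTargetYear`; `BSAP` scales
#' them down a linear ramp reaching `bsapTargetFactor` at `bsapTargetYear`
#' and holds constant after. Ramps start at `rampStartYear` (series start by
#' default) and are evaluated in fractional years, so the midpoint of a ramp
#' carries exactly the midpoint multiplier. Meteorology and contaminant
#' fields are untouched.
#'
#' @param scenario a [ScenarioSpec-class].
#' @param base a [ForcingSeries-class] of baseline loads.
#' @return A [ForcingSeries-class].
#' @export
buildNutrientLoads <- function(scenario, base) {
  validObject(scenario)
  if (scenario@ilTargetFactor < 0 || scenario@bsapTargetFactor < 0) {
    stop("nutrient ramp target fraction must be >= 0")
  }
  if (scenario@nutrients == "CL") return(base)
  tFrac <- base@year + (base@doy - 1) / 365
  m <- nutrientMultiplier(scenario, tFrac, base@year[1])
  data <- base@data
  data$dinLoad <- data$dinLoad * m
  data$dipLoad <- data$dipLoad * m
  newForcingSeries(base@year, base@doy, base@basins, data)
}

#' Apply an emission-reduction scenario to a forcing series
#'
#' `current` leaves the series unchanged. `red_river` multiplies the river
#' contaminant load by `1 - reductionFraction` from January 1 of
#' `reductionYear` onward; `red_air` does the same to the atmospheric
#' contaminant concentration. The respective other contaminant channel, and
#' all meteorology and nutrient loads, are untouched, so emission and
#' nutrient transforms commute.
#'
#' @param scenario a [ScenarioSpec-class].
#' @param base a [ForcingSeries-class].
#' @return A [ForcingSeries-class].
#' @export
buildEmissionScenario <- function(scenario, base) {
  validObject(scenario)
  if (scenario@emissions == "current") return(base)
  yr <- scenario@reductionYear
  if (yr < base@year[1] || yr > base@year[length(base@year)]) {
    stop("range error: reductionYear ", yr, " is outside the series (",
         base@year[1], "-", base@year[length(base@year)], ")")
  }
  keep <- ifelse(base@year >= yr, 1 - scenario@reductionFraction, 1)
  data <- base@data
  field <- if (scenario@emissions == "red_river") "contRiverLoad" else "contAirConc"
  data[[field]] <- data[[field]] * keep
  newForcingSeries(base@year, base@doy, base@basins, data)
}

#' Build the fully transformed forcing for a scenario
#'
#' Convenience composition used by the engine: start from a base RW series
#' (generated from the climatology unless supplied), then apply climate,
#' nutrient and emission transforms of the scenario in that order (the
#' nutrient and emission transforms commute; climate precedes them only to
#' define the reference weather).
#'
#' @param config a [SimulationConfig-class].
#' @return A [ForcingSeries-class].
#' @export
scenarioForcing <- function(config) {
  nYears <- as.integer(config@endYear - config@startYear + 1)
  base <- config@forcing
  if (is.null(base)) {
    clim <- config@climatology
    clim@seed <- config@seed
    base <- generateRWForcing(clim, config@startYear, nYears)
  }
  fs <- base
  if (config@scenario@climate == "a1b") {
    fs <- applyA1bTransform(fs, config@scenario)
  }
  fs <- buildNutrientLoads(config@scenario, fs)
  buildEmissionScenario(config@scenario, fs)
}
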