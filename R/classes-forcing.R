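# Configuration and forcing containers for the scenario module.

FORCING_VARIABLES <- c(
  "airTemp",       # degC
  "wind",          # m/s at 10 m
  "precip",        # m/day
  "radiation",     # W/m2 shortwave
  "discharge",     # m3/day river flow
  "dinLoad",       # kg N/day river load
  "dipLoad",       # kg P/day river load
  "contRiverLoad", # kg/day river contaminant load
  "contAirConc",   # ng/m3 atmospheric gas-phase contaminant
  "riverDoc"       # mg C/m3 DOC concentration in river water
)

MET_VARIABLES <- c("airTemp", "wind", "precip", "radiation", "discharge")

#' Climatology parameters for the synthetic weather generator
#'
#' Describes, per basin, the annual mean, seasonal amplitude, phase (day of
#' year of the seasonal maximum) and interannual noise standard deviation of
#' each meteorological/hydrological variable, plus constant baseline river
#' nutrient and contaminant loads and the atmospheric contaminant
#' concentration. The seed makes generated weather reproducible.
#'
#' @slot basins character vector of basin ids.
#' @slot met data.frame with columns basin, variable, mean, amplitude,
#'   peakDoy, noiseSd. Variables: airTemp (degC), wind (m/s), precip (m/day),
#'   radiation (W/m2), discharge (m3/day).
#' @slot loads data.frame with columns basin, dinLoad, dipLoad,
#'   contRiverLoad (kg/day), contAirConc (ng/m3), riverDoc (mg C/m3).
#' @slot seed integer random seed.
#' @export
setClass("ClimatologyParams",
  representation(basins = "character", met = "data.frame",
                 loads = "data.frame", seed = "integer"))

setValidity("ClimatologyParams", function(object) {
  msg <- character()
  met <- object@met
  need <- c("basin", "variable", "mean", "amplitude", "peakDoy", "noiseSd")
  if (!all(need %in% names(met))) {
    return(paste("met must have columns", paste(need, collapse = ", ")))
  }
  if (!setequal(unique(met$basin), object@basins)) {
    msg <- c(msg, "met basins must match the basins slot")
  }
  if (!all(MET_VARIABLES %in% met$variable)) {
    msg <- c(msg, paste("met must cover variables:",
                        paste(MET_VARIABLES, collapse = ", ")))
  }
  if (any(met$amplitude < 0)) msg <- c(msg, "seasonal amplitudes must be >= 0")
  if (any(met$noiseSd < 0)) msg <- c(msg, "noise scales must be >= 0")
  nonneg <- met$variable != "airTemp"
  if (any(met$mean[nonneg] < 0)) {
    msg <- c(msg, "wind, precip, radiation and discharge means must be >= 0")
  }
  ld <- object@loads
  ldneed <- c("basin", "dinLoad", "dipLoad", "contRiverLoad", "contAirConc",
              "riverDoc")
  if (!all(ldneed %in% names(ld))) {
    return(paste("loads must have columns", paste(ldneed, collapse = ", ")))
  }
  if (any(as.matrix(ld[, ldneed[-1]]) < 0)) msg <- c(msg, "loads must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "seed must be a single non-missing integer")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct climatology parameters
#'
#' @param basins character vector of basin ids.
#' @param met data.frame(basin, variable, mean, amplitude, peakDoy, noiseSd);
#'   one row per basin x variable for airTemp, wind, precip, radiation,
#'   discharge.
#' @param loads data.frame(basin, dinLoad, dipLoad, contRiverLoad,
#'   contAirConc, riverDoc) of constant baseline loads.
#' @param seed integer seed for the weather generator.
#' @return A [ClimatologyParams-class] object.
#' @seealso [balticClimatology()] for ready-made Baltic-like defaults.
#' @export
climatologyParams <- function(basins, met, loads, seed = 1L) {
  new("ClimatologyParams", basins = as.character(basins),
      met = as.data.frame(met), loads = as.data.frame(loads),
      seed = as.integer(seed))
}

setMethod("show", "ClimatologyParams", function(object) {
  cat("ClimatologyParams:", length(object@basins), "basins (",
      paste(object@basins, collapse = ", "), "), seed", object@seed, "\n")
})

#' Scenario specification
#'
#' A (climate, nutrients, emissions) scenario triple with its numerical
#' knobs: the year and fraction of a step emission reduction, the warming
#' scenario factors, and the shapes of the nutrient-load ramps.
#'
#' Climate: `"RW"` (random weather, stationary present-day climate) or
#' `"a1b"` (on average 7 % higher wind, 60 % higher air temperature on the
#' degC scale, 20 % more precipitation). Nutrients: `"CL"` (constant loads),
#' `"IL"` (linear increase to `ilTargetFactor` by `ilTargetYear`), `"BSAP"`
#' (linear decrease to `bsapTargetFactor` by `bsapTargetYear`, constant
#' after). Emissions: `"current"`, `"red_river"` or `"red_air"` (multiply
#' river contaminant load resp. atmospheric concentration by
#' `1 - reductionFraction` from `reductionYear` onward).
#'
#' @slot climate,nutrients,emissions scenario labels (see Description).
#' @slot reductionYear calendar year the emission cut takes effect.
#' @slot reductionFraction fraction removed, in `[0, 1]`.
#' @slot a1bWindFactor,a1bTempFactor,a1bPrecipFactor warming multipliers.
#' @slot a1bTempMode `"offset"` (default: uniform shift of
#'   `(factor - 1) * period-mean` degC, so the period-mean ratio equals the
#'   factor exactly while winters warm) or `"multiplicative"` (pointwise
#'   scaling of the degC value).
#' @slot a1bRamp if TRUE, factors ramp linearly from 1 at the series start
#'   to their full value at the series end (off by default so "on average"
#'   holds exactly).
#' @slot ilTargetFactor,ilTargetYear,bsapTargetFactor,bsapTargetYear
#'   nutrient ramp endpoints.
#' @slot rampStartYear year the nutrient ramps start (NA = series start).
#' @export
setClass("ScenarioSpec",
  representation(climate = "character", nutrients = "character",
                 emissions = "character", reductionYear = "numeric",
                 reductionFraction = "numeric", a1bWindFactor = "numeric",
                 a1bTempFactor = "numeric", a1bPrecipFactor = "numeric",
                 a1bTempMode = "character", a1bRamp = "logical",
                 ilTargetFactor = "numeric", ilTargetYear = "numeric",
                 bsapTargetFactor = "numeric", bsapTargetYear = "numeric",
                 rampStartYear = "numeric"))

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (!object@climate %in% c("RW", "a1b")) {
    msg <- c(msg, "climate must be 'RW' or 'a1b'")
  }
  if (!object@nutrients %in% c("CL", "IL", "BSAP")) {
    msg <- c(msg, "nutrients must be 'CL', 'IL' or 'BSAP'")
  }
  if (!object@emissions %in% c("current", "red_river", "red_air")) {
    msg <- c(msg, "emissions must be 'current', 'red_river' or 'red_air'")
  }
  if (object@reductionFraction < 0 || object@reductionFraction > 1) {
    msg <- c(msg, "reductionFraction must be in [0, 1]")
  }
  f <- c(object@a1bWindFactor, object@a1bTempFactor, object@a1bPrecipFactor)
  if (any(f <= 0)) msg <- c(msg, "a1b multipliers must be > 0")
  if (!object@a1bTempMode %in% c("offset", "multiplicative")) {
    msg <- c(msg, "a1bTempMode must be 'offset' or 'multiplicative'")
  }
  if (object@ilTargetFactor < 0 || object@bsapTargetFactor < 0) {
    msg <- c(msg, "nutrient ramp target fractions must be >= 0")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a scenario specification
#'
#' @param climate "RW" or "a1b".
#' @param nutrients "CL", "IL" or "BSAP".
#' @param emissions "current", "red_river" or "red_air".
#' @param reductionYear calendar year of the emission step cut.
#' @param reductionFraction fraction of the load/concentration removed.
#' @param a1bWindFactor,a1bTempFactor,a1bPrecipFactor warming multipliers
#'   (defaults 1.07, 1.60, 1.20).
#' @param a1bTempMode "offset" or "multiplicative", see
#'   [ScenarioSpec-class].
#' @param a1bRamp ramp the warming factors linearly over the series.
#' @param ilTargetFactor,ilTargetYear increasing-load ramp endpoint.
#' @param bsapTargetFactor,bsapTargetYear load-reduction ramp endpoint.
#' @param rampStartYear first year of the nutrient ramps (NA = series start).
#' @return A [ScenarioSpec-class] object.
#' @examples
#' scenarioSpec(emissions = "red_river")  # 90 % river-load cut in 2006
#' @export
scenarioSpec <- function(climate = "RW", nutrients = "CL",
                         emissions = "current", reductionYear = 2006,
                         reductionFraction = 0.9, a1bWindFactor = 1.07,
                         a1bTempFactor = 1.60, a1bPrecipFactor = 1.20,
                         a1bTempMode = "offset", a1bRamp = FALSE,
                         ilTargetFactor = 1.5, ilTargetYear = 2100,
                         bsapTargetFactor = 0.6, bsapTargetYear = 2021,
                         rampStartYear = NA_real_) {
  new("ScenarioSpec", climate = climate, nutrients = nutrients,
      emissions = emissions, reductionYear = as.numeric(reductionYear),
      reductionFraction = reductionFraction, a1bWindFactor = a1bWindFactor,
      a1bTempFactor = a1bTempFactor, a1bPrecipFactor = a1bPrecipFactor,
      a1bTempMode = a1bTempMode, a1bRamp = a1bRamp,
      ilTargetFactor = ilTargetFactor, ilTargetYear = ilTargetYear,
      bsapTargetFactor = bsapTargetFactor, bsapTargetYear = bsapTargetYear,
      rampStartYear = as.numeric(rampStartYear))
}

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec: climate=%s nutrients=%s emissions=%s",
              object@climate, object@nutrients, object@emissions))
  if (object@emissions != "current") {
    cat(sprintf(" (%.0f%% cut in %d)", 100 * object@reductionFraction,
                as.integer(object@reductionYear)))
  }
  cat("\n")
})

#' Daily forcing series for all basins
#'
#' Uniformly daily-spaced forcing on a 365-day calendar (no leap days).
#' Each element of `data` is an nDays x nBasins matrix; see
#' [climatologyParams()] for units.
#'
#' @slot year,doy integer vectors (length nDays) of calendar year and
#'   day-of-year (1..365).
#' @slot basins character vector of basin ids (matrix columns).
#' @slot data named list of nDays x nBasins matrices, one per forcing
#'   variable (airTemp, wind, precip, radiation, discharge, dinLoad,
#'   dipLoad, contRiverLoad, contAirConc, riverDoc).
#' @export
setClass("ForcingSeries",
  representation(year = "integer", doy = "integer", basins = "character",
                 data = "list"))

setValidity("ForcingSeries", function(object) {
  n <- length(object@year)
  msg <- character()
  if (length(object@doy) != n) msg <- c(msg, "year and doy lengths differ")
  if (any(diff(object@year * 365L + object@doy) != 1L)) {
    msg <- c(msg, "series must be daily with no gaps")
  }
  if (!all(FORCING_VARIABLES %in% names(object@data))) {
    msg <- c(msg, paste("data must contain:",
                        paste(FORCING_VARIABLES, collapse = ", ")))
  }
  for (v in intersect(FORCING_VARIABLES, names(object@data))) {
    m <- object@data[[v]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != length(object@basins)) {
      msg <- c(msg, paste0(v, " matrix has wrong dimensions"))
      next
    }
    if (v != "airTemp" && any(m < 0)) {
      msg <- c(msg, paste0(v, " must be non-negative"))
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

newForcingSeries <- function(year, doy, basins, data) {
  data <- lapply(data, function(m) {
    colnames(m) <- basins
    m
  })
  new("ForcingSeries", year = as.integer(year), doy = as.integer(doy),
      basins = basins, data = data)
}

setMethod("show", "ForcingSeries", function(object) {
  cat(sprintf("ForcingSeries: %d days (%d-%d), %d basins: %s\n",
              length(object@year), object@year[1],
              object@year[length(object@year)], length(object@basins),
              paste(object@basins, collapse = ", ")))
})

#' @describeIn forcingVariable extract one forcing variable as a matrix
#'   (days x basins).
#' @export
setGeneric("forcingVariable", function(x, variable) {
  standardGeneric("forcingVariable")
})

#' Access forcing series contents
#'
#' @param x a [ForcingSeries-class].
#' @param variable one of the forcing variable names (see
#'   [ForcingSeries-class]).
#' @return `forcingVariable`: numeric matrix days x basins;
#'   `forcingYears`: integer vector of calendar years, one per day.
#' @name forcingVariable
#' @export
setMethod("forcingVariable", "ForcingSeries", function(x, variable) {
  variable <- match.arg(variable, FORCING_VARIABLES)
  x@data[[variable]]
})

#' @rdname forcingVariable
#' @export
forcingYears <- function(x) x@year

#' @rdname forcingVariable
#' @export
forcingDoy <- function(x) x@doy

#' Basin identifiers of an object
#'
#' @param x a [ForcingSeries-class], [BasinGeometry-class] or
#'   [ClimatologyParams-class].
#' @return character vector of basin ids.
#' @export
setGeneric("basinIds", function(x) standardGeneric("basinIds"))

#' @rdname basinIds
#' @export
setMethod("basinIds", "ForcingSeries", function(x) x@basins)

#' @rdname basinIds
#' @export
setMethod("basinIds", "ClimatologyParams", function(x) x@basins)
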