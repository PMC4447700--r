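# Analysis module: post-processing metrics on simulation outputs.

#' Windowed means of dissolved surface-water concentration
#'
#' Arithmetic mean of the monthly-mean dissolved surface C_W over each
#' requested window of calendar years (decades in typical use).
#'
#' @param output a [SimulationOutput-class].
#' @param basin basin id.
#' @param windows list of `c(firstYear, lastYear)` spans (inclusive).
#' @return numeric vector of means (pg/L), named `first-last`.
#' @export
decadalMeanCw <- function(output, basin, windows) {
  s <- cwSeries(output, basin)
  means <- vapply(windows, function(w) {
    sel <- s$year >= w[1] & s$year <= w[2]
    if (!any(sel)) {
      stop("validation error: window ", w[1], "-", w[2],
           " is empty within the run span")
    }
    mean(s$value[sel])
  }, numeric(1))
  names(means) <- vapply(windows, function(w) paste0(w[1], "-", w[2]),
                         character(1))
  means
}

#' Effectiveness of an emission-reduction measure
#'
#' Percent reduction in mean dissolved surface C_W attributable to a
#' measure: `100 (1 - mean(treated) / mean(control))` over the horizon
#' window. The two runs must be paired (shared weather realization) for the
#' contrast to be purely scenario-driven. Invariant to the units of C_W.
#'
#' @param control,treated [SimulationOutput-class] objects from paired runs.
#' @param basin basin id.
#' @param horizon `c(firstYear, lastYear)` evaluation window.
#' @return percent reduction (positive = the measure lowers concentrations).
#' @export
measureEffectiveness <- function(control, treated, basin,
                                 horizon = c(2015, 2025)) {
  mc <- unname(decadalMeanCw(control, basin, list(horizon)))
  mt <- unname(decadalMeanCw(treated, basin, list(horizon)))
  if (mc == 0) stop("undefined ratio: control mean concentration is zero")
  100 * (1 - mt / mc)
}

#' Winter peak statistics of the seasonal C_W cycle
#'
#' For each calendar year with complete monthly output, the month of the
#' maximum monthly-mean dissolved surface C_W (ties broken toward the
#' earliest month) and the peak amplitude, max/min of the year's monthly
#' means. An all-zero year gets `NA` amplitude (undefined), not an error.
#'
#' @param output a monthly-cadence [SimulationOutput-class].
#' @param basin basin id.
#' @return data.frame(year, peakMonth, amplitude).
#' @export
winterPeakStats <- function(output, basin) {
  if (output@cadence != "monthly") {
    stop("winterPeakStats needs monthly-cadence output")
  }
  s <- cwSeries(output, basin)
  years <- sort(unique(s$year))
  res <- lapply(years, function(y) {
    v <- s$value[s$year == y][order(s$month[s$year == y])]
    if (length(v) < 12) return(NULL)
    if (all(v == 0)) {
      return(data.frame(year = y, peakMonth = 1L, amplitude = NA_real_))
    }
    data.frame(year = y, peakMonth = which.max(v),
               amplitude = if (min(v) > 0) max(v) / min(v) else Inf)
  })
  do.call(rbind, res)
}

#' Annual ice-day counts
#'
#' Number of days per calendar year with any ice cover, reconstructed
#' exactly from the monthly means of the ice-day indicator.
#'
#' @param output a [SimulationOutput-class].
#' @param basin basin id.
#' @return data.frame(year, iceDays).
#' @export
annualIceDays <- function(output, basin) {
  s <- variableSeries(output, basin, "iceDay")
  if (output@cadence == "monthly") {
    days <- MONTH_LENGTHS[s$month] * s$value
  } else {
    days <- s$value
  }
  agg <- tapply(days, s$year, sum)
  data.frame(year = as.integer(names(agg)), iceDays = as.numeric(agg),
             row.names = NULL)
}

#' Scenario metrics bundle
#'
#' Convenience wrapper computing, per basin, the decadal-mean C_W series,
#' winter-peak statistics and annual ice days of one run.
#'
#' @param output a [SimulationOutput-class].
#' @param decades list of year spans; defaults to the run's full decades.
#' @return named list per basin with elements `decadalMeans`, `winterPeaks`,
#'   `iceDays`.
#' @export
scenarioMetrics <- function(output, decades = NULL) {
  if (is.null(decades)) {
    y0 <- ceiling(output@startYear / 10) * 10
    starts <- seq(y0, output@endYear - 9, by = 10)
    decades <- lapply(starts, function(s) c(s, s + 9))
  }
  ids <- unique(output@table$basin)
  setNames(lapply(ids, function(b) {
    list(decadalMeans = decadalMeanCw(output, b, decades),
         winterPeaks = winterPeakStats(output, b),
         iceDays = annualIceDays(output, b))
  }), ids)
}
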