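# Simulation configuration and output containers (engine module surface).

setClassUnion("ForcingSeriesOrNULL", c("ForcingSeries", "NULL"))

#' Simulation configuration
#'
#' Bundles everything one run needs: geometry, climatology, chemical card,
#' scenario, process parameters, the simulated period and output/budget
#' settings. When `forcing` is supplied it is used as the *base* random
#' weather realization and only the scenario transforms are applied to it;
#' this is how paired scenario comparisons share a weather draw.
#'
#' @slot geometry a [BasinGeometry-class].
#' @slot climatology a [ClimatologyParams-class].
#' @slot chemical a [ChemicalProperties-class].
#' @slot scenario a [ScenarioSpec-class].
#' @slot biogeo,hydro parameter lists from [biogeoParams()] / [hydroParams()].
#' @slot startYear,endYear simulated period (inclusive).
#' @slot cadence "monthly" (default) or "daily" output.
#' @slot seed integer seed for the weather generator (overrides the
#'   climatology seed so scenario sets can share one draw).
#' @slot budgetTolerance maximum relative budget-closure error before the
#'   run aborts.
#' @slot debugLeak test hook: fraction of surface-water contaminant mass
#'   silently destroyed each day, to exercise the conservation abort.
#' @slot forcing optional precomputed base [ForcingSeries-class].
#' @export
setClass("SimulationConfig",
  representation(geometry = "BasinGeometry",
                 climatology = "ClimatologyParams",
                 chemical = "ChemicalProperties", scenario = "ScenarioSpec",
                 biogeo = "list", hydro = "list", startYear = "numeric",
                 endYear = "numeric", cadence = "character",
                 seed = "integer", budgetTolerance = "numeric",
                 debugLeak = "numeric", forcing = "ForcingSeriesOrNULL"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@endYear <= object@startYear) {
    msg <- c(msg, "endYear must be greater than startYear")
  }
  if (!object@cadence %in% c("monthly", "daily")) {
    msg <- c(msg, "cadence must be 'monthly' or 'daily'")
  }
  if (object@budgetTolerance <= 0) {
    msg <- c(msg, "budgetTolerance must be > 0")
  }
  gids <- object@geometry@basins$id
  if (!setequal(gids, object@climatology@basins)) {
    msg <- c(msg, "climatology basins must match geometry basins")
  }
  if (!is.null(object@forcing) && !setequal(object@forcing@basins, gids)) {
    msg <- c(msg, "forcing basins must match geometry basins")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a simulation configuration
#'
#' All arguments default to the Baltic-like D5 setup, so
#' `runSimulation(simulationConfig())` works out of the box.
#'
#' @param geometry,climatology,chemical,scenario,biogeo,hydro see
#'   [SimulationConfig-class].
#' @param startYear,endYear simulated period (inclusive calendar years).
#' @param cadence "monthly" or "daily" output.
#' @param seed weather seed.
#' @param budgetTolerance relative mass-budget closure tolerance.
#' @param debugLeak conservation-abort test hook (leave at 0).
#' @param forcing optional shared base weather realization.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(geometry = balticGeometry(),
                             climatology = balticClimatology(),
                             chemical = d5Properties(),
                             scenario = scenarioSpec(),
                             biogeo = biogeoParams(), hydro = hydroParams(),
                             startYear = 1990, endYear = 2030,
                             cadence = "monthly", seed = 1L,
                             budgetTolerance = 1e-3, debugLeak = 0,
                             forcing = NULL) {
  new("SimulationConfig", geometry = geometry, climatology = climatology,
      chemical = chemical, scenario = scenario, biogeo = biogeo,
      hydro = hydro, startYear = startYear, endYear = endYear,
      cadence = cadence, seed = as.integer(seed),
      budgetTolerance = budgetTolerance, debugLeak = debugLeak,
      forcing = forcing)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %s, %d-%d, %s output, seed %d\n",
              object@chemical@name, as.integer(object@startYear),
              as.integer(object@endYear), object@cadence, object@seed))
  show(object@scenario)
})

#' Simulation output
#'
#' @slot table tidy long data.frame: year, month (NA for daily cadence),
#'   doy (NA for monthly), date (ISO string of the period start), basin,
#'   layer ("surface", "deep", "sediment"), variable, value.
#' @slot budget named list of per-quantity budgets (water, salt, nitrogen,
#'   phosphorus, contaminant), each a list with `initial`, `final`
#'   inventories and named `inputs` / `outputs` cumulative fluxes. Units:
#'   m3 (water), kg otherwise.
#' @slot closure named numeric of relative closure errors
#'   (initial + inputs - outputs - final, over max(inputs, initial)).
#' @slot provenance list(seed, scenario labels, period, package version).
#' @slot cadence "monthly" or "daily".
#' @slot startYear,endYear simulated period.
#' @export
setClass("SimulationOutput",
  representation(table = "data.frame", budget = "list", closure = "numeric",
                 provenance = "list", cadence = "character",
                 startYear = "numeric", endYear = "numeric"))

setMethod("show", "SimulationOutput", function(object) {
  cat(sprintf("SimulationOutput: %d-%d (%s), %d rows\n",
              as.integer(object@startYear), as.integer(object@endYear),
              object@cadence, nrow(object@table)))
  cat("  budget closure:",
      paste(sprintf("%s %.2e", names(object@closure), object@closure),
            collapse = ", "), "\n")
})

#' Access simulation output
#'
#' @param x a [SimulationOutput-class].
#' @param basin basin id.
#' @param variable output variable name (e.g. "cwDissolved", "detritus",
#'   "iceFraction").
#' @param layer "surface", "deep" or "sediment".
#' @return `outputTable`: the full tidy table; `variableSeries`: the
#'   filtered subset ordered in time; `cwSeries`: dissolved surface-water
#'   contaminant concentration (pg/L bulk water); `massBudget`: the budget
#'   list; `budgetClosure`: named numeric of relative closure errors.
#' @export
outputTable <- function(x) x@table

#' @rdname outputTable
#' @export
variableSeries <- function(x, basin, variable, layer = "surface") {
  tb <- x@table
  out <- tb[tb$basin == basin & tb$variable == variable & tb$layer == layer, ]
  out[order(out$year, if (x@cadence == "monthly") out$month else out$doy), ]
}

#' @rdname outputTable
#' @export
cwSeries <- function(x, basin) variableSeries(x, basin, "cwDissolved")

#' @rdname outputTable
#' @export
massBudget <- function(x) x@budget

#' @rdname outputTable
#' @export
budgetClosure <- function(x) x@closure
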