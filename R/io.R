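# External interfaces: YAML configuration files and CSV time series.

dfToYamlList <- function(df) lapply(as.list(df), function(col) {
  if (is.factor(col)) as.character(col) else col
})

yamlListToDf <- function(lst) {
  lst <- lapply(lst, function(col) {
    unlist(lapply(col, function(x) if (is.null(x)) NA else x))
  })
  as.data.frame(lst, stringsAsFactors = FALSE)
}

#' Read and write model configuration as YAML
#'
#' Basin geometry, climatology, chemical cards and scenario specifications
#' round-trip through plain YAML files; a full simulation configuration can
#' reference them inline or by relative path.
#'
#' @param x the object to write.
#' @param path file path.
#' @return the read functions return the corresponding object; the write
#'   functions return `path` invisibly.
#' @name yamlConfig
NULL

#' @rdname yamlConfig
#' @export
writeGeometryYaml <- function(x, path) {
  yaml::write_yaml(list(basins = dfToYamlList(x@basins),
                        connections = dfToYamlList(x@connections),
                        boundaryConc = x@boundaryConc), path, precision = 15)
  invisible(path)
}

#' @rdname yamlConfig
#' @export
readGeometryYaml <- function(path) {
  y <- yaml::read_yaml(path)
  cn <- yamlListToDf(y$connections)
  cn$to <- as.character(cn$to)
  basinGeometry(yamlListToDf(y$basins), cn, boundaryConc = y$boundaryConc)
}

#' @rdname yamlConfig
#' @export
writeClimatologyYaml <- function(x, path) {
  yaml::write_yaml(list(basins = x@basins, met = dfToYamlList(x@met),
                        loads = dfToYamlList(x@loads), seed = x@seed), path, precision = 15)
  invisible(path)
}

#' @rdname yamlConfig
#' @export
readClimatologyYaml <- function(path) {
  y <- yaml::read_yaml(path)
  climatologyParams(y$basins, yamlListToDf(y$met), yamlListToDf(y$loads),
                    seed = y$seed)
}

chemicalSlots <- c("name", "logKow", "logKaw", "logKoc", "kocMode",
                   "kdocFraction", "dUaw", "dUow", "hydrolysisRate25",
                   "hydrolysisEa", "biodegWater25", "biodegWaterEa",
                   "biodegSed25", "biodegSedEa")

#' @rdname yamlConfig
#' @export
writeChemicalYaml <- function(x, path) {
  yaml::write_yaml(setNames(lapply(chemicalSlots, function(s) slot(x, s)),
                            chemicalSlots), path, precision = 15)
  invisible(path)
}

#' @rdname yamlConfig
#' @export
readChemicalYaml <- function(path) {
  do.call(chemicalProperties, yaml::read_yaml(path))
}

scenarioSlots <- c("climate", "nutrients", "emissions", "reductionYear",
                   "reductionFraction", "a1bWindFactor", "a1bTempFactor",
                   "a1bPrecipFactor", "a1bTempMode", "a1bRamp",
                   "ilTargetFactor", "ilTargetYear", "bsapTargetFactor",
                   "bsapTargetYear", "rampStartYear")

#' @rdname yamlConfig
#' @export
writeScenarioYaml <- function(x, path) {
  yaml::write_yaml(setNames(lapply(scenarioSlots, function(s) slot(x, s)),
                            scenarioSlots), path, precision = 15)
  invisible(path)
}

#' @rdname yamlConfig
#' @export
readScenarioYaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$rampStartYear)) y$rampStartYear <- NA_real_
  do.call(scenarioSpec, y)
}

#' @rdname yamlConfig
#' @export
readSimulationConfigYaml <- function(path) {
  y <- yaml::read_yaml(path)
  dir <- dirname(path)
  resolve <- function(section, reader, inline) {
    if (is.null(section)) return(NULL)
    if (is.character(section) && length(section) == 1) {
      reader(file.path(dir, section))
    } else {
      inline(section)
    }
  }
  args <- list(
    geometry = resolve(y$geometry, readGeometryYaml, function(s) {
      cn <- yamlListToDf(s$connections)
      cn$to <- as.character(cn$to)
      basinGeometry(yamlListToDf(s$basins), cn, boundaryConc = s$boundaryConc)
    }),
    climatology = resolve(y$climatology, readClimatologyYaml, function(s) {
      climatologyParams(s$basins, yamlListToDf(s$met), yamlListToDf(s$loads),
                        seed = s$seed)
    }),
    chemical = resolve(y$chemical, readChemicalYaml, function(s) {
      do.call(chemicalProperties, s)
    }),
    scenario = resolve(y$scenario, readScenarioYaml, function(s) {
      if (is.null(s$rampStartYear)) s$rampStartYear <- NA_real_
      do.call(scenarioSpec, s)
    }))
  args <- args[!vapply(args, is.null, logical(1))]
  for (nm in c("startYear", "endYear", "cadence", "seed",
               "budgetTolerance")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(simulationConfig, args)
}

#' Read and write daily forcing as CSV
#'
#' Long layout, one row per basin-day with ISO dates (nominal: the model
#' runs a 365-day calendar, so February 29 never occurs) and one column per
#' forcing variable.
#'
#' @param x a [ForcingSeries-class].
#' @param path file path.
#' @return `readForcingCsv` returns a [ForcingSeries-class];
#'   `writeForcingCsv` returns `path` invisibly.
#' @export
writeForcingCsv <- function(x, path) {
  nd <- length(x@year)
  date <- format(as.Date(x@doy - 1, origin = sprintf("%04d-01-01", x@year)))
  df <- data.frame(date = rep(date, length(x@basins)),
                   year = rep(x@year, length(x@basins)),
                   doy = rep(x@doy, length(x@basins)),
                   basin = rep(x@basins, each = nd))
  for (v in FORCING_VARIABLES) df[[v]] <- as.vector(x@data[[v]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeForcingCsv
#' @export
readForcingCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  basins <- unique(df$basin)
  sub1 <- df[df$basin == basins[1], ]
  nd <- nrow(sub1)
  data <- lapply(setNames(FORCING_VARIABLES, FORCING_VARIABLES),
                 function(v) {
                   matrix(df[[v]], nd, length(basins))
                 })
  newForcingSeries(sub1$year, sub1$doy, basins, data)
}

#' Write a simulation output table as tidy CSV
#'
#' Columns: year, month, doy, date, basin, layer, variable, value.
#'
#' @param x a [SimulationOutput-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeOutputCsv <- function(x, path) {
  write.csv(x@table, path, row.names = FALSE)
  invisible(path)
}
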