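## End-to-end pipeline: read or simulate spectra, split, reconstruct with
## scale and factor selection, optionally run repeated UVE, and write the
## report artifacts. All decisions (selected scale, factor count, retained
## variable count) are logged via message().

#' RunConfig: pipeline configuration
#'
#' @slot input Path of the input spectra (CSV/MAT) or `NA` for synthetic.
#' @slot format,orientation,variable,yColumn Input options, see
#'   [readSpectra()].
#' @slot y Reference property: column name/index or MAT variable name.
#' @slot wavelet Mother wavelet name.
#' @slot scaleGrid Candidate upper scale endpoints.
#' @slot aMin Fixed lower scale endpoint.
#' @slot layout Feature layout.
#' @slot ratioThreshold,kMax PRESS ratio rule settings.
#' @slot uveRepetitions UVE repetitions (0 disables UVE).
#' @slot noiseAmplitude UVE artificial-noise amplitude (NA: the 1e-10 rule).
#' @slot splitPolicy,calFraction Calibration/prediction split.
#' @slot seed Master seed.
#' @slot outDir Output directory for artifacts.
#' @export
setClass("RunConfig",
  representation(input = "character", format = "character",
                 orientation = "character", variable = "character",
                 yColumn = "integer", y = "character", wavelet = "character",
                 scaleGrid = "integer", aMin = "integer", layout = "character",
                 ratioThreshold = "numeric", kMax = "integer",
                 uveRepetitions = "integer", noiseAmplitude = "numeric",
                 splitPolicy = "character", calFraction = "numeric",
                 seed = "integer", outDir = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@wavelet %in% supportedWavelets())
      msg <- c(msg, "unknown wavelet")
    if (any(object@scaleGrid < object@aMin))
      msg <- c(msg, "scale grid below aMin")
    if (object@ratioThreshold <= 0 || object@ratioThreshold >= 1)
      msg <- c(msg, "ratioThreshold must be in (0, 1)")
    if (object@kMax < 1L) msg <- c(msg, "kMax must be >= 1")
    if (object@uveRepetitions < 0L) msg <- c(msg, "uveRepetitions must be >= 0")
    if (object@calFraction <= 0 || object@calFraction > 1)
      msg <- c(msg, "calFraction must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn RunConfig-class Constructor with defaults.
#' @param input,format,orientation,variable,yColumn,y Input options.
#' @param wavelet,scaleGrid,aMin,layout Reconstruction options.
#' @param ratioThreshold,kMax Factor selection options.
#' @param uveRepetitions,noiseAmplitude UVE options.
#' @param splitPolicy,calFraction Split options.
#' @param seed,outDir Run options.
#' @return A validated `RunConfig`.
#' @export
runConfig <- function(input = NA_character_, format = "csv",
                      orientation = "rows", variable = NA_character_,
                      yColumn = NA_integer_, y = NA_character_,
                      wavelet = "mexh", scaleGrid = seq(10L, 40L, 5L),
                      aMin = 1L, layout = "concatenated",
                      ratioThreshold = 0.9, kMax = 20L,
                      uveRepetitions = 0L, noiseAmplitude = NA_real_,
                      splitPolicy = "kennard-stone", calFraction = 0.8,
                      seed = 1L, outDir = tempfile("nirwave-run-")) {
  new("RunConfig", input = as.character(input), format = format,
      orientation = orientation, variable = as.character(variable),
      yColumn = as.integer(yColumn), y = as.character(y), wavelet = wavelet,
      scaleGrid = as.integer(scaleGrid), aMin = as.integer(aMin),
      layout = layout, ratioThreshold = ratioThreshold,
      kMax = as.integer(kMax), uveRepetitions = as.integer(uveRepetitions),
      noiseAmplitude = as.numeric(noiseAmplitude), splitPolicy = splitPolicy,
      calFraction = calFraction, seed = as.integer(seed),
      outDir = as.character(outDir))
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: wavelet %s, scales %s, layout %s, UVE x%d, seed %d\n",
              object@wavelet, paste(range(object@scaleGrid), collapse = ".."),
              object@layout, object@uveRepetitions, object@seed))
})

#' Run the full pipeline
#'
#' Reads (or accepts) a dataset, assigns the calibration/prediction split,
#' selects the scale range and factor count, fits the final calibration,
#' optionally runs repeated UVE on the winning feature matrix, and writes
#' the artifacts to `config@outDir`: `report.csv` (per-scale regression
#' report), `press_curves.csv`, and with UVE `stability.csv` plus
#' `uve_summary.csv`. On any stage error the partial output directory is
#' removed and a stage-tagged error is raised.
#'
#' @param config A [RunConfig-class].
#' @param dataset Optional [SpectralDataset-class]; when missing it is read
#'   from `config@input`. An input of `NA` raises an error.
#' @return Invisible list: `report`, `scale`, `calibration`, `curves`,
#'   `uve` (or NULL), `paths` of written artifacts.
#' @export
runPipeline <- function(config, dataset = NULL) {
  stopifnot(is(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(config@outDir, recursive = TRUE)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  set.seed(config@seed)
  if (is.null(dataset)) {
    if (is.na(config@input)) stop("[input] no dataset and no input path")
    dataset <- stage("input", readSpectra(
      config@input, config@format, config@orientation,
      y = if (is.na(config@y)) NULL else config@y,
      yColumn = if (is.na(config@yColumn)) NULL else config@yColumn,
      variable = if (is.na(config@variable)) NULL else config@variable))
  }
  dataset <- stage("split", {
    if (all(is.na(dataset@split)) && config@splitPolicy != "none")
      splitDataset(dataset, config@splitPolicy, config@calFraction)
    else dataset
  })
  message("pipeline: ", nrow(dataset@X), " samples, wavelet ", config@wavelet)
  sel <- stage("calibration", selectScale(
    dataset, config@wavelet, config@scaleGrid, config@layout, config@aMin,
    config@ratioThreshold, config@kMax))
  message("selected scale a = ", sel$scale, ", ",
          nFactors(sel$calibration), " factors, RMSEC = ",
          format(min(sel$report$RMSEC), digits = 4))
  uve <- NULL
  if (config@uveRepetitions > 0L) {
    uve <- stage("uve", {
      calRows <- which(splitLabels(dataset) == "calibration")
      if (length(calRows) == 0L) calRows <- seq_along(dataset@y)
      amp <- if (is.na(config@noiseAmplitude))
        1e-10 * max(abs(sel$features)) else config@noiseAmplitude
      uveRepeat(sel$features[calRows, , drop = FALSE],
                dataset@y[calRows], nFactors(sel$calibration),
                repetitions = config@uveRepetitions, seed = config@seed,
                noiseAmplitude = amp)
    })
    message("UVE retained ", length(retainedIndices(uve)), " of ",
            ncol(sel$features), " variables (",
            length(alwaysSelected(uve)), " in every repetition)")
  }
  paths <- stage("report", {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    p <- c(report = file.path(config@outDir, "report.csv"),
           press = file.path(config@outDir, "press_curves.csv"))
    writeReportTable(sel$report, p[["report"]])
    pc <- do.call(rbind, lapply(names(sel$curves), function(a)
      data.frame(SelectedA = as.integer(a),
                 Factor = sel$curves[[a]]@factors,
                 PRESS = sel$curves[[a]]@press)))
    write.csv(format(pc, digits = 12, trim = TRUE), p[["press"]],
              row.names = FALSE, quote = FALSE)
    if (!is.null(uve)) {
      p[["stability"]] <- file.path(config@outDir, "stability.csv")
      fa <- featureAxis(new("ReconstructedSignal",
                            maxChannel = numeric(ncol(dataset@X)),
                            minChannel = numeric(ncol(dataset@X)),
                            scaleRange = c(config@aMin, sel$scale),
                            layout = config@layout, wavelet = config@wavelet,
                            axis = dataset@axis))
      write.csv(format(uveReportTable(uve, fa), digits = 12, trim = TRUE),
                p[["stability"]], row.names = FALSE, quote = FALSE)
      p[["uve"]] <- file.path(config@outDir, "uve_summary.csv")
      write.csv(format(uve@repetitions, digits = 12, trim = TRUE),
                p[["uve"]], row.names = FALSE, quote = FALSE)
    }
    p
  })
  invisible(list(report = sel$report, scale = sel$scale,
                 calibration = sel$calibration, curves = sel$curves,
                 uve = uve, paths = paths))
}
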