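## Central S4 containers. One class per stage of the pipeline:
## MotherWavelet -> Scalogram -> ReconstructedSignal -> SpectralDataset /
## PLSCalibration / PressCurve -> StabilityProfile / UveSelection.

#' MotherWavelet: a sampled mother wavelet
#'
#' Wraps the unit-scale wavelet function \eqn{\psi(x)} of one of the fourteen
#' supported families together with its effective support. All wavelets are
#' centred so that the support straddles zero, and are normalised to unit
#' L2 norm; `psi` evaluates \eqn{\psi} at arbitrary positions and returns 0
#' outside the effective support.
#'
#' @slot name Character, one of [supportedWavelets()].
#' @slot support Numeric length-2: effective support of the unit-scale
#'   wavelet (where \eqn{|\psi|} exceeds 1e-8 of its maximum).
#' @slot psi Function mapping a numeric vector of positions to wavelet values.
#' @export
setClass("MotherWavelet",
  representation(name = "character", support = "numeric", psi = "function"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
    if (length(object@support) != 2L || object@support[1] >= object@support[2])
      msg <- c(msg, "'support' must be an increasing length-2 interval")
    if (is.null(msg)) TRUE else msg
  })

#' SignalVector: one spectrum
#'
#' An ordered channel axis plus intensity values, the discrete \eqn{f(x)}
#' that the continuous wavelet transform operates on.
#'
#' @slot axis Strictly increasing numeric channel positions (wavelength nm or
#'   dimensionless 0-based index).
#' @slot values Numeric intensities, same length as `axis`.
#' @export
setClass("SignalVector",
  representation(axis = "numeric", values = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) < 2L) msg <- c(msg, "signal must have length >= 2")
    if (length(object@axis) != length(object@values))
      msg <- c(msg, "'axis' and 'values' lengths differ")
    if (anyNA(object@values) || anyNA(object@axis))
      msg <- c(msg, "missing values are not allowed")
    else if (any(diff(object@axis) <= 0))
      msg <- c(msg, "'axis' must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn SignalVector-class Constructor.
#' @param values Numeric intensities.
#' @param axis Channel positions; defaults to the 0-based index.
#' @return A `SignalVector`.
#' @export
#' @examples
#' s <- signalVector(sin(seq(0, 6, length.out = 64)))
#' channelAxis(s)[1:3]
signalVector <- function(values, axis = seq_along(values) - 1) {
  new("SignalVector", axis = as.numeric(axis), values = as.numeric(values))
}

#' Scalogram: CWT coefficients on a scales-by-positions grid
#'
#' @slot scales Strictly increasing positive integer scales \eqn{a}.
#' @slot coefficients Numeric matrix \eqn{W(a,b)}: one row per scale, one
#'   column per channel of the transformed signal.
#' @slot wavelet Character, name of the mother wavelet used.
#' @slot axis Channel axis of the transformed signal.
#' @export
setClass("Scalogram",
  representation(scales = "integer", coefficients = "matrix",
                 wavelet = "character", axis = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@scales) < 1L) msg <- c(msg, "at least one scale required")
    if (any(object@scales < 1L)) msg <- c(msg, "scales must be positive integers")
    if (length(object@scales) > 1L && any(diff(object@scales) <= 0L))
      msg <- c(msg, "scales must be strictly increasing")
    if (nrow(object@coefficients) != length(object@scales))
      msg <- c(msg, "one coefficient row per scale required")
    if (ncol(object@coefficients) != length(object@axis))
      msg <- c(msg, "coefficient columns must match the channel axis")
    if (is.null(msg)) TRUE else msg
  })

#' ReconstructedSignal: per-channel scalogram extremes
#'
#' The collapse of a scalogram over a scale range: at every channel the
#' maximum and the minimum CWT coefficient observed across the scales. This
#' pair of channels is the reconstructed signal used for modelling.
#'
#' @slot maxChannel,minChannel Numeric vectors, one value per channel.
#' @slot scaleRange Integer length-2, the `[a_min, a_max]` collapsed.
#' @slot layout `"concatenated"`, `"max_only"` or `"min_only"`: how
#'   [featureVector()] assembles the channels into a modelling vector.
#' @slot wavelet Mother wavelet name.
#' @slot axis Channel axis.
#' @export
setClass("ReconstructedSignal",
  representation(maxChannel = "numeric", minChannel = "numeric",
                 scaleRange = "integer", layout = "character",
                 wavelet = "character", axis = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@maxChannel) != length(object@minChannel))
      msg <- c(msg, "max and min channels must have equal length")
    if (any(object@maxChannel < object@minChannel))
      msg <- c(msg, "maxChannel must dominate minChannel everywhere")
    if (!object@layout %in% c("concatenated", "max_only", "min_only"))
      msg <- c(msg, "unknown layout")
    if (is.null(msg)) TRUE else msg
  })

#' SpectralDataset: a samples-by-channels matrix with a reference property
#'
#' @slot X Numeric matrix, n samples by p features (channels, or
#'   reconstructed max/min features).
#' @slot y Numeric reference values, length n (e.g. protein content in %).
#' @slot axis Feature positions, length p.
#' @slot split Character length n: `"calibration"`, `"prediction"` or `NA`.
#' @slot metadata List of provenance (ground truth for synthetic sets,
#'   source file for read ones).
#' @export
setClass("SpectralDataset",
  representation(X = "matrix", y = "numeric", axis = "numeric",
                 split = "character", metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@X) < 1L) msg <- c(msg, "need at least 1 sample")
    if (nrow(object@X) != length(object@y))
      msg <- c(msg, "row count of X must equal length of y")
    if (ncol(object@X) != length(object@axis))
      msg <- c(msg, "column count of X must equal length of axis")
    if (length(object@split) != nrow(object@X))
      msg <- c(msg, "one split label per sample required")
    if (anyNA(object@X) || anyNA(object@y))
      msg <- c(msg, "missing values are not allowed")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn SpectralDataset-class Constructor.
#' @param X Samples-by-features numeric matrix.
#' @param y Reference property vector.
#' @param axis Feature positions (default 0-based index).
#' @param split Optional per-sample `"calibration"`/`"prediction"` labels.
#' @param metadata Optional provenance list.
#' @return A `SpectralDataset`.
#' @export
spectralDataset <- function(X, y, axis = seq_len(ncol(X)) - 1,
                            split = rep(NA_character_, nrow(X)),
                            metadata = list()) {
  new("SpectralDataset", X = as.matrix(X), y = as.numeric(y),
      axis = as.numeric(axis), split = as.character(split),
      metadata = metadata)
}

#' PLSCalibration: a fitted PLS1 regression
#'
#' Mean-centred NIPALS partial least squares with a fixed number of latent
#' variables, stored as a single coefficient vector plus centring statistics
#' so that prediction is `(x - xMeans) %*% coefficients + yMean`.
#'
#' @slot nFactors Number of latent variables used.
#' @slot coefficients Length-p regression vector (centred scale).
#' @slot xMeans,yMean Centring statistics from the training set.
#' @slot fitted In-sample predictions for the training rows.
#' @slot metadata List: wavelet name, selected scale, layout, if known.
#' @export
setClass("PLSCalibration",
  representation(nFactors = "integer", coefficients = "numeric",
                 xMeans = "numeric", yMean = "numeric", fitted = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (object@nFactors < 1L) msg <- c(msg, "nFactors must be >= 1")
    if (length(object@coefficients) != length(object@xMeans))
      msg <- c(msg, "coefficients and xMeans lengths differ")
    if (is.null(msg)) TRUE else msg
  })

#' PressCurve: leave-one-out PRESS per factor count
#'
#' @slot factors Integer vector `1..K`.
#' @slot press Numeric PRESS values (sums over left-out samples of squared
#'   prediction error), all nonnegative.
#' @export
setClass("PressCurve",
  representation(factors = "integer", press = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(object@factors, seq_len(length(object@factors))))
      msg <- c(msg, "factor grid must be consecutive 1..K")
    if (length(object@press) != length(object@factors))
      msg <- c(msg, "one PRESS value per factor required")
    if (any(object@press < 0)) msg <- c(msg, "PRESS values must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn PressCurve-class Constructor.
#' @param press Numeric PRESS values for factors `1..length(press)`.
#' @return A `PressCurve`.
#' @export
pressCurve <- function(press) {
  new("PressCurve", factors = seq_along(press), press = as.numeric(press))
}

#' StabilityProfile: per-variable UVE stability statistics
#'
#' For each variable, the mean of its leave-one-out PLS regression
#' coefficients divided by their standard deviation, computed on a matrix
#' augmented with an equal-width block of small-amplitude artificial noise
#' variables.
#'
#' @slot stability Per-real-variable statistic.
#' @slot noiseStability Same statistic for the artificial block (same width).
#' @slot flagged Logical per real variable: zero-variance coefficient guard.
#' @slot nFactors,noiseAmplitude Settings used.
#' @export
setClass("StabilityProfile",
  representation(stability = "numeric", noiseStability = "numeric",
                 flagged = "logical", nFactors = "integer",
                 noiseAmplitude = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@stability) != length(object@noiseStability))
      msg <- c(msg, "noise block must have the width of the real block")
    if (length(object@flagged) != length(object@stability))
      msg <- c(msg, "one flag per real variable required")
    if (is.null(msg)) TRUE else msg
  })

#' UveSelection: result of repeated uninformative variable elimination
#'
#' @slot cutoff Stability cutoff of the winning repetition (max absolute
#'   noise-block stability by default).
#' @slot retained Column indices kept by the repetition with minimum PRESS.
#' @slot alwaysSelected Indices retained in every successful repetition.
#' @slot repetitions Data frame: one row per repetition (seed, cutoff,
#'   number retained, PRESS, cross-validated RMSE).
#' @slot profile The `StabilityProfile` of the winning repetition.
#' @export
setClass("UveSelection",
  representation(cutoff = "numeric", retained = "integer",
                 alwaysSelected = "integer", repetitions = "data.frame",
                 profile = "StabilityProfile"),
  validity = function(object) {
    if (length(object@retained) < 1L) "retained set must be nonempty" else TRUE
  })

#' SyntheticSpec: recipe for a composite NIR-like signal
#'
#' Describes a composite signal formed from overlapping Gaussian or
#' Lorentzian sub-bands sitting on a smooth polynomial baseline with optional
#' white noise — the stand-in world for heavily overlapped NIR spectra.
#'
#' @slot bands Data frame with columns `center`, `width`, `amplitude`,
#'   `shape` (`"gaussian"` or `"lorentzian"`).
#' @slot baseline Polynomial coefficients (intercept first) evaluated on the
#'   0-based channel index scaled to `[0, 1]`.
#' @slot noiseSd Standard deviation of additive white noise (>= 0).
#' @slot channels Number of channels (>= 32).
#' @slot seed Optional integer seed used when noise is drawn.
#' @export
setClass("SyntheticSpec",
  representation(bands = "data.frame", baseline = "numeric",
                 noiseSd = "numeric", channels = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("center", "width", "amplitude", "shape")
    if (!all(need %in% names(object@bands)))
      msg <- c(msg, "bands must have center/width/amplitude/shape columns")
    else {
      if (any(object@bands$width <= 0)) msg <- c(msg, "band widths must be > 0")
      if (!all(object@bands$shape %in% c("gaussian", "lorentzian")))
        msg <- c(msg, "band shape must be gaussian or lorentzian")
    }
    if (object@channels < 32L) msg <- c(msg, "need at least 32 channels")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

## ---- accessors ----

#' @rdname channelAxis
#' @export
setMethod("channelAxis", "SignalVector", function(x) x@axis)
#' @rdname channelAxis
#' @export
setMethod("channelAxis", "Scalogram", function(x) x@axis)
#' @rdname channelAxis
#' @export
setMethod("channelAxis", "ReconstructedSignal", function(x) x@axis)
#' @rdname channelAxis
#' @export
setMethod("channelAxis", "SpectralDataset", function(x) x@axis)

#' @rdname channelAxis
#' @export
setMethod("intensities", "SignalVector", function(x) x@values)

#' @rdname scales
#' @export
setMethod("scales", "Scalogram", function(x) x@scales)
#' @rdname scales
#' @export
setMethod("scales", "ReconstructedSignal", function(x) x@scaleRange)

#' @rdname waveletName
#' @export
setMethod("waveletName", "MotherWavelet", function(x) x@name)
#' @rdname waveletName
#' @export
setMethod("waveletName", "Scalogram", function(x) x@wavelet)

#' @rdname cwtCoefficients
#' @export
setMethod("cwtCoefficients", "Scalogram", function(x) x@coefficients)

#' @rdname maxChannel
#' @export
setMethod("maxChannel", "ReconstructedSignal", function(x) x@maxChannel)
#' @rdname maxChannel
#' @export
setMethod("minChannel", "ReconstructedSignal", function(x) x@minChannel)

#' @rdname spectra
#' @export
setMethod("spectra", "SpectralDataset", function(x) x@X)
#' @rdname spectra
#' @export
setMethod("reference", "SpectralDataset", function(x) x@y)
#' @rdname spectra
#' @export
setMethod("splitLabels", "SpectralDataset", function(x) x@split)

#' @rdname nFactors
#' @export
setMethod("nFactors", "PLSCalibration", function(x) x@nFactors)

#' Regression coefficients of a PLS calibration
#'
#' @param object A `PLSCalibration`.
#' @param ... Ignored.
#' @return Numeric coefficient vector on the centred scale.
#' @export
setMethod("coef", "PLSCalibration", function(object, ...) object@coefficients)

#' @rdname pressValues
#' @export
setMethod("pressValues", "PressCurve", function(x) x@press)

#' @rdname stabilityValues
#' @export
setMethod("stabilityValues", "StabilityProfile", function(x) x@stability)
#' @rdname stabilityValues
#' @export
setMethod("noiseStability", "StabilityProfile", function(x) x@noiseStability)
#' @rdname stabilityValues
#' @export
setMethod("stabilityValues", "UveSelection", function(x) x@profile@stability)

#' @rdname retainedIndices
#' @export
setMethod("retainedIndices", "UveSelection", function(x) x@retained)
#' @rdname retainedIndices
#' @export
setMethod("alwaysSelected", "UveSelection", function(x) x@alwaysSelected)

## ---- show methods ----

setMethod("show", "MotherWavelet", function(object) {
  cat(sprintf("MotherWavelet '%s', effective support [%.3f, %.3f]\n",
              object@name, object@support[1], object@support[2]))
})

setMethod("show", "SignalVector", function(object) {
  cat(sprintf("SignalVector with %d channels, axis [%g, %g]\n",
              length(object@values), min(object@axis), max(object@axis)))
})

setMethod("show", "Scalogram", function(object) {
  cat(sprintf("Scalogram (%s): %d scales (%d..%d) x %d channels\n",
              object@wavelet, length(object@scales), min(object@scales),
              max(object@scales), ncol(object@coefficients)))
})

setMethod("show", "ReconstructedSignal", function(object) {
  cat(sprintf(
    "ReconstructedSignal (%s, scales %d..%d, layout %s): %d channels\n",
    object@wavelet, object@scaleRange[1], object@scaleRange[2],
    object@layout, length(object@maxChannel)))
})

setMethod("show", "SpectralDataset", function(object) {
  ncal <- sum(object@split == "calibration", na.rm = TRUE)
  npred <- sum(object@split == "prediction", na.rm = TRUE)
  cat(sprintf("SpectralDataset: %d samples x %d features", nrow(object@X),
              ncol(object@X)))
  if (ncal + npred > 0) cat(sprintf(" (%d calibration / %d prediction)", ncal, npred))
  cat("\n")
})

setMethod("show", "PLSCalibration", function(object) {
  cat(sprintf("PLSCalibration: %d factors, %d features\n",
              object@nFactors, length(object@coefficients)))
  if (length(object@metadata))
    cat("  ", paste(names(object@metadata), unlist(lapply(object@metadata, format)),
                    sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PressCurve", function(object) {
  cat(sprintf("PressCurve over factors 1..%d; min PRESS %.4g at k=%d\n",
              max(object@factors), min(object@press), which.min(object@press)))
})

setMethod("show", "StabilityProfile", function(object) {
  cat(sprintf(
    "StabilityProfile: %d variables (+%d noise), %d factors, max |noise| = %.3g\n",
    length(object@stability), length(object@noiseStability), object@nFactors,
    max(abs(object@noiseStability))))
})

setMethod("show", "UveSelection", function(object) {
  cat(sprintf(
    "UveSelection: %d retained (best of %d repetitions), %d always selected\n",
    length(object@retained), nrow(object@repetitions),
    length(object@alwaysSelected)))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d sub-bands on %d channels, noise sd %g\n",
              nrow(object@bands), object@channels, object@noiseSd))
})
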