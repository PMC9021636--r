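#' @import methods
#' @importFrom stats approx coef fft nextn predict rnorm runif sd var
#' @importFrom utils head read.csv tail write.csv write.table
NULL

#' Channel axis of a spectral object
#'
#' Returns the channel positions (wavelength in nm, or a dimensionless
#' 0-based index) attached to a spectral object.
#'
#' @param x A `SignalVector`, `Scalogram`, `ReconstructedSignal` or
#'   `SpectralDataset`.
#' @return Numeric vector of channel positions.
#' @export
setGeneric("channelAxis", function(x) standardGeneric("channelAxis"))

#' @rdname channelAxis
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Scales of a scalogram
#'
#' @param x A `Scalogram` or `ReconstructedSignal`.
#' @return Integer vector of scales (for a `ReconstructedSignal`, the
#'   two-element scale range actually collapsed).
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' Wavelet name carried by an object
#'
#' @param x A `MotherWavelet`, `Scalogram` or `PLSCalibration`.
#' @return Character scalar.
#' @export
setGeneric("waveletName", function(x) standardGeneric("waveletName"))

#' Coefficient matrix of a scalogram
#'
#' @param x A `Scalogram`.
#' @return Numeric matrix, one row per scale, one column per channel.
#' @export
setGeneric("cwtCoefficients", function(x) standardGeneric("cwtCoefficients"))

#' Max/min channels of a reconstructed signal
#'
#' @param x A `ReconstructedSignal`.
#' @return Numeric vector with one value per original channel.
#' @export
setGeneric("maxChannel", function(x) standardGeneric("maxChannel"))

#' @rdname maxChannel
#' @export
setGeneric("minChannel", function(x) standardGeneric("minChannel"))

#' Spectra matrix and reference values of a dataset
#'
#' @param x A `SpectralDataset`.
#' @return `spectra()` returns the samples-by-channels matrix, `reference()`
#'   the numeric reference property (e.g. protein content in %),
#'   `splitLabels()` the per-sample `"calibration"`/`"prediction"`
#'   assignment (possibly `NA`).
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname spectra
#' @export
setGeneric("reference", function(x) standardGeneric("reference"))

#' @rdname spectra
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))

#' Number of PLS latent variables
#'
#' @param x A `PLSCalibration`.
#' @return Positive integer.
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' PRESS values of a cross-validation curve
#'
#' @param x A `PressCurve`.
#' @return Numeric vector of PRESS values for factors `1..K`.
#' @export
setGeneric("pressValues", function(x) standardGeneric("pressValues"))

#' Stability statistics from a UVE pass
#'
#' @param x A `StabilityProfile` or `UveSelection`.
#' @return `stabilityValues()`: per-real-variable mean/sd coefficient ratio;
#'   `noiseStability()`: the same statistic for the appended artificial
#'   variables.
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))

#' @rdname stabilityValues
#' @export
setGeneric("noiseStability", function(x) standardGeneric("noiseStability"))

#' Retained variables of a UVE selection
#'
#' @param x A `UveSelection`.
#' @return `retainedIndices()`: column indices retained by the best
#'   repetition; `alwaysSelected()`: indices retained in every repetition.
#' @export
setGeneric("retainedIndices", function(x) standardGeneric("retainedIndices"))

#' @rdname retainedIndices
#' @export
setGeneric("alwaysSelected", function(x) standardGeneric("alwaysSelected"))
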