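## Max/min reconstruction: collapse a scalogram over a scale range into the
## per-channel maximum and minimum CWT coefficient. At a fixed scale the
## wavelet cannot overlap every feature optimally; across a range of scales
## every channel gets the coefficient of its best-matched wavelet, so the
## extremes carry the maximum information per channel (troughs live in the
## minimum channel).

#' Collapse a scalogram into per-channel extremes
#'
#' @param scalogram A [Scalogram-class] with at least one scale row.
#' @param layout How [featureVector()] will assemble the two channels:
#'   `"concatenated"` (default), `"max_only"` or `"min_only"`.
#' @return A [ReconstructedSignal-class].
#' @export
#' @examples
#' s <- signalVector(exp(-(seq(-30, 30))^2 / 32))
#' r <- maxminChannels(cwtScalogram(s, "mexh", 1:10))
#' all(maxChannel(r) >= minChannel(r))
maxminChannels <- function(scalogram, layout = "concatenated") {
  if (!is(scalogram, "Scalogram")) stop("'scalogram' must be a Scalogram")
  cf <- scalogram@coefficients
  if (nrow(cf) < 1L) stop("scalogram has no scale rows")
  new("ReconstructedSignal",
      maxChannel = as.numeric(do.call(pmax, asplit(cf, 1))),
      minChannel = as.numeric(do.call(pmin, asplit(cf, 1))),
      scaleRange = range(scalogram@scales),
      layout = layout, wavelet = scalogram@wavelet, axis = scalogram@axis)
}

#' Feature vector of a reconstructed signal
#'
#' @param x A [ReconstructedSignal-class].
#' @param layout Overrides the layout stored in `x` if given.
#' @return Numeric vector: `[maxChannel, minChannel]` of length `2p` for
#'   `"concatenated"`, else the single channel of length `p`.
#' @export
featureVector <- function(x, layout = NULL) {
  stopifnot(is(x, "ReconstructedSignal"))
  layout <- if (is.null(layout)) x@layout else
    match.arg(layout, c("concatenated", "max_only", "min_only"))
  switch(layout,
         concatenated = c(x@maxChannel, x@minChannel),
         max_only = x@maxChannel,
         min_only = x@minChannel)
}

#' Channel positions of the assembled features
#'
#' Maps feature indices back to channels: for the concatenated layout the
#' axis is repeated (max block then min block).
#'
#' @inheritParams featureVector
#' @return Numeric vector of channel positions, parallel to [featureVector()].
#' @export
featureAxis <- function(x, layout = NULL) {
  stopifnot(is(x, "ReconstructedSignal"))
  layout <- if (is.null(layout)) x@layout else
    match.arg(layout, c("concatenated", "max_only", "min_only"))
  if (layout == "concatenated") c(x@axis, x@axis) else x@axis
}

#' Reconstruct a signal from its scalogram extremes
#'
#' Runs the full reconstruction for one signal: CWT over the consecutive
#' integer scales `aMin..aMax`, collapse to per-channel max/min, and assembly
#' into a modelling feature vector.
#'
#' @inheritParams cwtRow
#' @param aMin,aMax Scale range endpoints, `1 <= aMin <= aMax`.
#' @param layout Feature assembly, see [featureVector()].
#' @return Numeric feature vector (length `2p` for `"concatenated"`, else `p`).
#' @export
#' @examples
#' s <- exp(-(seq(-30, 30))^2 / 32)
#' length(reconstructSignal(s, "mexh", 1, 10))  # 2 * 61
reconstructSignal <- function(signal, wavelet, aMin = 1L, aMax = 40L,
                              layout = c("concatenated", "max_only", "min_only"),
                              mode = "symmetric") {
  layout <- match.arg(layout)
  aMin <- as.integer(aMin); aMax <- as.integer(aMax)
  if (aMin < 1L || aMax < aMin) stop("need 1 <= aMin <= aMax")
  sg <- cwtScalogram(signal, wavelet, seq.int(aMin, aMax), mode)
  featureVector(maxminChannels(sg, layout))
}

#' Reconstruct every row of a spectra matrix
#'
#' Applies [reconstructSignal()] to each sample of a samples-by-channels
#' matrix. When several nested scale ranges are needed (the scale-selection
#' loop), pass the full vector of `aMax` values: the scalogram is computed
#' once per sample up to `max(aMax)` and the nested extremes are obtained by
#' running cumulative max/min, which is exactly equivalent to recomputing
#' per range.
#'
#' @param X Samples-by-channels numeric matrix.
#' @inheritParams reconstructSignal
#' @param aMax Integer vector of upper scale endpoints (one feature matrix is
#'   returned per value).
#' @return A list of feature matrices, one per `aMax`, named by the value.
#' @export
reconstructMatrix <- function(X, wavelet, aMin = 1L, aMax = 40L,
                              layout = c("concatenated", "max_only", "min_only"),
                              mode = "symmetric") {
  layout <- match.arg(layout)
  if (is.character(wavelet)) wavelet <- motherWavelet(wavelet)
  X <- as.matrix(X)
  aMin <- as.integer(aMin)
  aMaxGrid <- sort(unique(as.integer(aMax)))
  if (aMin < 1L || any(aMaxGrid < aMin)) stop("need 1 <= aMin <= aMax")
  allScales <- seq.int(aMin, max(aMaxGrid))
  p <- ncol(X)
  width <- if (layout == "concatenated") 2L * p else p
  out <- lapply(aMaxGrid, function(a) matrix(0, nrow(X), width))
  names(out) <- as.character(aMaxGrid)
  rowsAt <- match(aMaxGrid, allScales)
  suppress <- function(expr) withCallingHandlers(expr, warning = function(w)
    invokeRestart("muffleWarning"))
  for (i in seq_len(nrow(X))) {
    cf <- suppress(cwtCoefficients(cwtScalogram(X[i, ], wavelet, allScales, mode)))
    cmax <- apply(cf, 2, cummax)
    cmin <- apply(cf, 2, cummin)
    if (length(allScales) == 1L) { cmax <- t(cmax); cmin <- t(cmin) }
    for (j in seq_along(aMaxGrid)) {
      r <- rowsAt[j]
      out[[j]][i, ] <- switch(layout,
                              concatenated = c(cmax[r, ], cmin[r, ]),
                              max_only = cmax[r, ],
                              min_only = cmin[r, ])
    }
  }
  out
}
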