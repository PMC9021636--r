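## Continuous wavelet transform of discrete signals.
##
## W(a, b) = (1 / sqrt(a)) sum_i f(x_i) psi((x_i - b) / a) dx, with dx = 1
## channel, evaluated on a boundary-extended copy of the signal and cropped
## back to the original length. The convolution runs over the dilated
## wavelet's effective support.

.EXTENSION_MODES <- c("symmetric", "whole", "zero")

.asValues <- function(signal) {
  if (is(signal, "SignalVector")) signal@values else as.numeric(signal)
}
.asAxis <- function(signal) {
  if (is(signal, "SignalVector")) signal@axis else seq_along(signal) - 1
}

## reflection index map for arbitrarily long extensions (numpy-pad style)
.reflectIndex <- function(i, n, whole = FALSE) {
  if (n == 1L) return(rep(1L, length(i)))
  if (whole) {                 # reflect about the edge samples: period 2n - 2
    p <- 2L * n - 2L
    j <- ((i - 1L) %% p + p) %% p
    ifelse(j < n, j + 1L, p - j + 1L)
  } else {                     # half-point reflection: period 2n
    p <- 2L * n
    j <- ((i - 1L) %% p + p) %% p
    ifelse(j < n, j + 1L, p - j)
  }
}

#' Extend a signal beyond its boundaries
#'
#' Pads both ends of a signal before convolution so that the transform does
#' not wrap or truncate at the edges. Modes: `"symmetric"` (half-point
#' reflection, default; `[1,2,3]` with half-width 2 becomes
#' `[2,1,1,2,3,3,2]`), `"whole"` (whole-point reflection, edge sample not
#' repeated) and `"zero"` (zero padding). Reflections tile, so the half-width
#' may exceed the signal length.
#'
#' @param signal A [SignalVector-class] or numeric vector.
#' @param halfWidth Positive integer, number of samples added on each side.
#' @param mode Extension mode.
#' @return A `SignalVector` of length `length(signal) + 2 * halfWidth`; the
#'   axis is extrapolated with the median channel spacing.
#' @export
#' @examples
#' intensities(boundaryExtend(c(1, 2, 3), 2))
boundaryExtend <- function(signal, halfWidth, mode = c("symmetric", "whole", "zero")) {
  mode <- match.arg(mode)
  x <- .asValues(signal)
  axis <- .asAxis(signal)
  n <- length(x)
  halfWidth <- as.integer(halfWidth)
  if (length(halfWidth) != 1L || is.na(halfWidth) || halfWidth < 1L)
    stop("'halfWidth' must be a positive integer")
  idx <- seq.int(1L - halfWidth, n + halfWidth)
  ext <- if (mode == "zero") {
    out <- numeric(length(idx))
    inside <- idx >= 1L & idx <= n
    out[inside] <- x[idx[inside]]
    out
  } else {
    x[.reflectIndex(idx, n, whole = (mode == "whole"))]
  }
  step <- stats::median(diff(axis))
  extAxis <- axis[1] + (idx - 1L) * step
  new("SignalVector", axis = extAxis, values = ext)
}

## dilated wavelet sampled at integer channel offsets, with the 1/sqrt(a)
## prefactor folded in; returns weights plus the offset range
.dilatedWeights <- function(wavelet, scale) {
  kmin <- ceiling(scale * wavelet@support[1])
  kmax <- floor(scale * wavelet@support[2])
  if (kmax < kmin) { # degenerate at very small scales; keep the centre tap
    kmin <- kmax <- 0
  }
  k <- seq.int(kmin, kmax)
  list(k = k, w = wavelet@psi(k / scale) / sqrt(scale))
}

#' Continuous wavelet transform at one scale
#'
#' Computes one row of the scalogram: the correlation of the
#' boundary-extended signal with the dilated wavelet, cropped to the
#' original length.
#'
#' @param signal A [SignalVector-class] or numeric vector.
#' @param wavelet A [MotherWavelet-class] or wavelet name.
#' @param scale Positive integer scale \eqn{a}.
#' @param mode Boundary extension mode, see [boundaryExtend()].
#' @return Numeric coefficient vector, same length as the input.
#' @export
#' @examples
#' s <- exp(-(seq(-20, 20))^2 / 18)
#' w <- cwtRow(s, "mexh", 3)
#' which.max(w)  # the Gaussian peak channel
cwtRow <- function(signal, wavelet, scale, mode = "symmetric") {
  if (is.character(wavelet)) wavelet <- motherWavelet(wavelet)
  x <- .asValues(signal)
  n <- length(x)
  scale <- as.integer(scale)
  if (length(scale) != 1L || is.na(scale) || scale < 1L)
    stop("'scale' must be a positive integer")
  dw <- .dilatedWeights(wavelet, scale)
  m <- length(dw$w)
  if (m > 10L * n)
    stop("scale ", scale, " dilates the wavelet (", m,
         " taps) far beyond the extended signal (length ", n, ")")
  if (m > n)
    warning("signal length ", n, " is shorter than the dilated wavelet (",
            m, " taps) at scale ", scale, "; coefficients lean on the ",
            "boundary extension", call. = FALSE)
  halfWidth <- max(abs(dw$k), 1L)
  ext <- intensities(boundaryExtend(x, halfWidth, mode))
  # result[b] = sum_j ext[b + halfWidth + kmin + j - 1] * w[j]
  # = full convolution of ext with rev(w) at index b + halfWidth + kmin + m - 1
  cf <- .convFull(ext, rev(dw$w))
  cf[seq_len(n) + halfWidth + dw$k[1] + m - 1L]
}

#' Continuous wavelet transform over a set of scales
#'
#' Stacks [cwtRow()] results for an increasing set of integer scales into a
#' [Scalogram-class], spreading the signal into the (scale, position) plane.
#'
#' @inheritParams cwtRow
#' @param scales Strictly increasing positive integer scales.
#' @return A [Scalogram-class].
#' @export
#' @examples
#' s <- signalVector(exp(-(seq(-30, 30))^2 / 32))
#' sg <- cwtScalogram(s, "mexh", 1:10)
#' dim(cwtCoefficients(sg))
cwtScalogram <- function(signal, wavelet, scales, mode = "symmetric") {
  if (is.character(wavelet)) wavelet <- motherWavelet(wavelet)
  scales <- as.integer(scales)
  if (length(scales) < 1L || anyNA(scales) || any(scales < 1L))
    stop("'scales' must be nonempty positive integers")
  if (length(scales) > 1L && any(diff(scales) <= 0L))
    stop("'scales' must be strictly increasing")
  x <- .asValues(signal)
  shortScales <- integer(0)
  rows <- vapply(scales, function(a) {
    withCallingHandlers(
      tryCatch(cwtRow(x, wavelet, a, mode),
               error = function(e) stop("scale ", a, ": ", conditionMessage(e),
                                        call. = FALSE)),
      warning = function(w) {
        shortScales <<- c(shortScales, a)
        invokeRestart("muffleWarning")
      })
  }, numeric(length(x)))
  if (length(shortScales))
    warning("dilated wavelet exceeds the signal length at scale(s) ",
            paste(range(shortScales), collapse = "-"),
            "; coefficients there lean on the boundary extension",
            call. = FALSE)
  new("Scalogram", scales = scales, coefficients = t(rows),
      wavelet = wavelet@name, axis = .asAxis(signal))
}
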