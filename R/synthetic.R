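## Synthetic composite signals: several overlapping Gaussian (or Lorentzian)
## sub-bands on a smooth polynomial baseline with optional white noise --
## the stand-in for heavily overlapped NIR spectra, with the sub-bands kept
## as ground truth. A paired generator draws per-sample band amplitudes and
## builds regression datasets with a known linear y.

#' Build a synthetic signal specification
#'
#' @param bands Data frame with columns `center` (channel), `width` (> 0),
#'   `amplitude`, `shape` (`"gaussian"` or `"lorentzian"`).
#' @param baseline Polynomial coefficients, intercept first, evaluated on the
#'   channel index rescaled to `[0, 1]` (default: no baseline).
#' @param noiseSd Additive white-noise standard deviation (default 0).
#' @param channels Number of channels (>= 32, default 500).
#' @param seed Optional seed used when noise is drawn.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(bands, baseline = 0, noiseSd = 0, channels = 500L,
                          seed = NA_integer_) {
  bands <- as.data.frame(bands)
  if (is.null(bands$shape)) bands$shape <- "gaussian"
  new("SyntheticSpec", bands = bands, baseline = as.numeric(baseline),
      noiseSd = as.numeric(noiseSd), channels = as.integer(channels),
      seed = as.integer(seed))
}

#' The canonical seven-band fixture
#'
#' A fixed composite of seven Gaussian sub-bands on a gentle quadratic
#' baseline, emulating a heavily overlapped NIR absorbance region. Bands 2/3
#' and 5/6 form overlapped pairs in which a weak narrow band rides on the
#' flank of a broad host, well inside the host's footprint: the raw
#' composite shows no separate maximum for the hidden bands, while the
#' scalogram max channel resolves all seven centres. Constants are
#' documented package fixtures, not fitted to any dataset.
#'
#' @param noiseSd Optional white noise (default 0: the deterministic fixture).
#' @param seed Seed used only when `noiseSd > 0`.
#' @return A [SyntheticSpec-class] with 500 channels.
#' @export
sevenBandSpec <- function(noiseSd = 0, seed = NA_integer_) {
  bands <- data.frame(
    center    = c(60, 150, 200, 280, 360, 405, 450),
    width     = c(10, 20, 4, 12, 18, 3.5, 10),
    amplitude = c(1.00, 0.90, 0.030, 1.05, 1.00, 0.030, 0.85),
    shape     = "gaussian")
  syntheticSpec(bands, baseline = c(0.10, 0.05, -0.04), noiseSd = noiseSd,
                channels = 500L, seed = seed)
}

.bandCurve <- function(x, center, width, amplitude, shape) {
  if (shape == "gaussian") amplitude * exp(-(x - center)^2 / (2 * width^2))
  else amplitude * width^2 / ((x - center)^2 + width^2)
}

.baselineCurve <- function(coefs, channels) {
  t <- (seq_len(channels) - 1) / (channels - 1)
  drop(outer(t, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Compose a synthetic signal
#'
#' Sums the sub-band curves, adds the baseline and optional white noise, and
#' returns both the composite and the individual sub-band curves as ground
#' truth. With `noiseSd = 0` the result is deterministic and no random draw
#' is made.
#'
#' @param spec A [SyntheticSpec-class].
#' @param seed Overrides the seed stored in `spec`.
#' @return List: `signal` (composite [SignalVector-class]), `bands`
#'   (channels-by-bands matrix of sub-band curves), `baseline` (numeric).
#' @export
#' @examples
#' cs <- composeSignal(sevenBandSpec())
#' length(intensities(cs$signal))
composeSignal <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "SyntheticSpec"))
  x <- seq_len(spec@channels) - 1
  nb <- nrow(spec@bands)
  bands <- matrix(0, spec@channels, max(nb, 1L))
  for (j in seq_len(nb))
    bands[, j] <- .bandCurve(x, spec@bands$center[j], spec@bands$width[j],
                             spec@bands$amplitude[j], spec@bands$shape[j])
  base <- .baselineCurve(spec@baseline, spec@channels)
  comp <- rowSums(bands) + base
  if (spec@noiseSd > 0) {
    if (!is.na(seed)) set.seed(as.integer(seed))
    comp <- comp + rnorm(spec@channels, 0, spec@noiseSd)
  }
  list(signal = signalVector(comp, x), bands = bands[, seq_len(nb), drop = FALSE],
       baseline = base)
}

#' Count strict local maxima
#'
#' @param values Numeric vector.
#' @return Integer indices `i` with `values[i] > values[i-1]` and
#'   `values[i] > values[i+1]`.
#' @export
localMaxima <- function(values) {
  n <- length(values)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[values[i] > values[i - 1L] & values[i] > values[i + 1L]]
}

#' Generate a regression dataset with known latent structure
#'
#' Each sample perturbs the sub-band amplitudes of `spec` with independent
#' Gaussian variation; the reference value is a stated linear combination of
#' the drawn amplitudes plus Gaussian noise, and each spectrum is composed
#' from its own amplitudes (plus the spec's spectral noise). The ground
#' truth (amplitude draws, y-coefficients, noise levels) is stored in the
#' dataset's metadata.
#'
#' @param spec A [SyntheticSpec-class]; the default world is the canonical
#'   [sevenBandSpec()].
#' @param nSamples Number of samples (>= 6, default 30).
#' @param coefficients Numeric vector over sub-bands: the linear map from
#'   band amplitudes to y. Default: bands 1, 4 and 7 are informative with
#'   weights `1.0, -0.8, 1.2`; all other bands are inert decoys.
#' @param amplitudeSd Standard deviation of the per-sample amplitude
#'   variation (default 0.2, i.e. ~20% of a unit band amplitude).
#' @param ySd Standard deviation of the reference-value noise (default 0.02,
#'   the "noise floor" a calibration can at best reach).
#' @param seed Seed for all draws (default 1).
#' @return A [SpectralDataset-class]; `metadata(x)$groundTruth` holds the
#'   coefficients, amplitude matrix, informative band indices and `ySd`.
#' @export
makeRegressionDataset <- function(spec = sevenBandSpec(), nSamples = 30L,
                                  coefficients = NULL, amplitudeSd = 0.2,
                                  ySd = 0.02, seed = 1L) {
  stopifnot(is(spec, "SyntheticSpec"))
  nSamples <- as.integer(nSamples)
  if (nSamples < 6L) stop("need at least 6 samples")
  nb <- nrow(spec@bands)
  if (is.null(coefficients)) {
    coefficients <- numeric(nb)
    inf <- intersect(c(1L, 4L, 7L), seq_len(nb))
    coefficients[inf] <- c(1.0, -0.8, 1.2)[seq_along(inf)]
  }
  if (length(coefficients) != nb)
    stop("'coefficients' must have one entry per sub-band")
  set.seed(as.integer(seed))
  amps <- matrix(rnorm(nSamples * nb, 0, amplitudeSd), nSamples, nb)
  amps <- sweep(amps, 2L, spec@bands$amplitude, `+`)
  x <- seq_len(spec@channels) - 1
  base <- .baselineCurve(spec@baseline, spec@channels)
  X <- matrix(0, nSamples, spec@channels)
  for (i in seq_len(nSamples)) {
    s <- base
    for (j in seq_len(nb))
      s <- s + .bandCurve(x, spec@bands$center[j], spec@bands$width[j],
                          amps[i, j], spec@bands$shape[j])
    X[i, ] <- s
  }
  if (spec@noiseSd > 0)
    X <- X + matrix(rnorm(length(X), 0, spec@noiseSd), nrow(X))
  y <- drop(amps %*% coefficients) + rnorm(nSamples, 0, ySd)
  spectralDataset(X, y, axis = x,
                  metadata = list(groundTruth = list(
                    coefficients = coefficients, amplitudes = amps,
                    informative = which(coefficients != 0), ySd = ySd,
                    bands = spec@bands)))
}

#' Write a composed signal as CSV
#'
#' Two columns (`channel`, `value`), plus one column per sub-band when
#' `groundTruth = TRUE`.
#'
#' @param composed Result of [composeSignal()].
#' @param path Output path.
#' @param groundTruth Include the sub-band curves (default FALSE).
#' @return `path`, invisibly.
#' @export
writeSignalCsv <- function(composed, path, groundTruth = FALSE) {
  df <- data.frame(channel = channelAxis(composed$signal),
                   value = intensities(composed$signal))
  if (groundTruth && ncol(composed$bands) > 0) {
    bd <- as.data.frame(composed$bands)
    names(bd) <- paste0("band", seq_len(ncol(bd)))
    df <- cbind(df, bd)
  }
  write.csv(format(df, digits = 12, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
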