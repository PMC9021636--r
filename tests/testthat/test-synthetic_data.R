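# Composite-signal generator and regression dataset factory.

test_that("composeSignal assembles bands, baseline and noise as stated", {
  # no bands, no baseline, no noise: all-zero composite
  empty <- syntheticSpec(data.frame(center = numeric(0), width = numeric(0),
                                    amplitude = numeric(0),
                                    shape = character(0)),
                         baseline = 0, channels = 64L)
  expect_equal(intensities(composeSignal(empty)$signal), numeric(64))
  # one Gaussian band: maximum at its centre with the stated amplitude
  one <- syntheticSpec(data.frame(center = 30, width = 5, amplitude = 0.7,
                                  shape = "gaussian"), channels = 64L)
  cs <- composeSignal(one)
  v <- intensities(cs$signal)
  expect_identical(which.max(v) - 1L, 30L)
  expect_equal(max(v), 0.7)
  # parts sum exactly to the whole when noise is off
  seven <- composeSignal(sevenBandSpec())
  expect_equal(rowSums(seven$bands) + seven$baseline,
               intensities(seven$signal))
})

test_that("noise-free composition ignores the seed, noisy draws honour it", {
  a <- composeSignal(sevenBandSpec(), seed = 1)
  b <- composeSignal(sevenBandSpec(), seed = 999)
  expect_identical(intensities(a$signal), intensities(b$signal))
  n1 <- composeSignal(sevenBandSpec(noiseSd = 0.01, seed = 5))
  n2 <- composeSignal(sevenBandSpec(noiseSd = 0.01, seed = 5))
  n3 <- composeSignal(sevenBandSpec(noiseSd = 0.01, seed = 6))
  expect_identical(intensities(n1$signal), intensities(n2$signal))
  expect_false(identical(intensities(n1$signal), intensities(n3$signal)))
})

test_that("the seven-band composite merges its hidden bands", {
  cs <- composeSignal(sevenBandSpec())
  expect_lt(length(localMaxima(intensities(cs$signal))), 7)
})

test_that("spec validity guards reject malformed worlds", {
  bands <- data.frame(center = 10, width = -1, amplitude = 1,
                      shape = "gaussian")
  expect_error(syntheticSpec(bands, channels = 64L), "width")
  good <- data.frame(center = 10, width = 2, amplitude = 1, shape = "gaussian")
  expect_error(syntheticSpec(good, channels = 8L), "32")
  expect_error(syntheticSpec(good, noiseSd = -1, channels = 64L), "noiseSd")
})

test_that("makeRegressionDataset carries a consistent ground truth", {
  ds <- makeRegressionDataset(nSamples = 8, seed = 21)
  gt <- ds@metadata$groundTruth
  expect_identical(gt$informative, c(1L, 4L, 7L))
  # spectra re-composed from the stored amplitudes match the stored X
  spec <- sevenBandSpec()
  x <- channelAxis(ds)
  base <- nirwave:::.baselineCurve(spec@baseline, spec@channels)
  for (i in c(1, 5)) {
    s <- base
    for (j in seq_len(nrow(spec@bands)))
      s <- s + gt$amplitudes[i, j] *
        exp(-(x - spec@bands$center[j])^2 / (2 * spec@bands$width[j]^2))
    expect_equal(spectra(ds)[i, ], s)
  }
  # y reproduced from amplitudes up to the stated noise level
  resid <- reference(ds) - drop(gt$amplitudes %*% gt$coefficients)
  expect_lt(max(abs(resid)), 5 * gt$ySd)
})

test_that("degenerate generators behave as stated", {
  ds <- makeRegressionDataset(nSamples = 6, amplitudeSd = 0, ySd = 0,
                              seed = 22)
  expect_equal(max(apply(spectra(ds), 2, sd)), 0)
  expect_equal(sd(reference(ds)), 0)
  # two varying amplitudes, noise-free y: two factors fit exactly
  bands <- data.frame(center = c(100, 250), width = c(12, 15),
                      amplitude = c(1, 0.8), shape = "gaussian")
  sp <- syntheticSpec(bands, baseline = 0, channels = 400L)
  d2 <- makeRegressionDataset(sp, nSamples = 10, coefficients = c(1, -0.6),
                              amplitudeSd = 0.25, ySd = 0, seed = 23)
  f <- suppressWarnings(fitPls(spectra(d2), reference(d2), 2))
  expect_lt(rmse(reference(d2), f@fitted), 1e-6 * sd(reference(d2)))
})

test_that("signal CSV export round-trips", {
  cs <- composeSignal(sevenBandSpec())
  path <- tempfile(fileext = ".csv")
  writeSignalCsv(cs, path, groundTruth = TRUE)
  df <- read.csv(path)
  expect_identical(nrow(df), 500L)
  expect_identical(ncol(df), 9L)        # channel, value, 7 bands
  expect_equal(df$value, intensities(cs$signal), tolerance = 1e-10)
})
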