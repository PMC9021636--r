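# Collapse of the scalogram into per-channel max/min and feature assembly.

test_that("maxminChannels takes elementwise extremes over scales", {
  sg <- new("Scalogram", scales = c(1L, 2L),
            coefficients = rbind(c(1, 2), c(3, 0)),
            wavelet = "mexh", axis = c(0, 1))
  r <- maxminChannels(sg)
  expect_equal(maxChannel(r), c(3, 2))
  expect_equal(minChannel(r), c(1, 0))
  one <- new("Scalogram", scales = 3L, coefficients = rbind(c(-1, 4, 2)),
             wavelet = "mexh", axis = 0:2)
  rr <- maxminChannels(one)
  expect_equal(maxChannel(rr), minChannel(rr))
  expect_equal(maxChannel(rr), c(-1, 4, 2))
  expect_error(maxminChannels("not a scalogram"), "Scalogram")
})

test_that("max channel dominates min channel for arbitrary scalograms", {
  set.seed(5)
  for (rep in 1:5) {
    x <- rnorm(50)
    r <- maxminChannels(suppressWarnings(cwtScalogram(x, "bior2.2", 1:12)))
    expect_true(all(maxChannel(r) >= minChannel(r)))
    expect_length(maxChannel(r), 50)
  }
})

test_that("reconstructSignal degenerates to cwtRow at a single scale", {
  x <- exp(-(0:79 - 40)^2 / 50)
  expect_equal(suppressWarnings(reconstructSignal(x, "mexh", 5, 5,
                                                  layout = "max_only")),
               suppressWarnings(cwtRow(x, "mexh", 5L)))
  expect_equal(suppressWarnings(reconstructSignal(numeric(64), "mexh", 1, 8)),
               numeric(128))
  expect_error(reconstructSignal(x, "mexh", 3, 2), "aMin <= aMax")
})

test_that("widening the scale range is monotone for the extremes", {
  x <- intensities(composeSignal(sevenBandSpec())$signal)
  ranges <- c(5L, 10L, 20L, 40L)
  prevMax <- rep(-Inf, length(x)); prevMin <- rep(Inf, length(x))
  for (aMax in ranges) {
    r <- maxminChannels(suppressWarnings(cwtScalogram(x, "mexh", 1:aMax)))
    expect_true(all(maxChannel(r) >= prevMax - 1e-12))
    expect_true(all(minChannel(r) <= prevMin + 1e-12))
    prevMax <- maxChannel(r); prevMin <- minChannel(r)
  }
})

test_that("a hidden narrow band becomes a max-channel maximum", {
  # broad host plus a weak narrow band on its flank: the composite shows a
  # single apparent band, the scalogram max channel shows both
  x <- 0:399
  s <- exp(-(x - 170)^2 / (2 * 20^2)) + 0.033 * exp(-(x - 220)^2 / (2 * 4^2))
  expect_equal(localMaxima(s) - 1, 170)
  cf <- suppressWarnings(cwtCoefficients(cwtScalogram(s, "mexh", 1:40)))
  # brute-force scan over all scales and positions
  mx <- vapply(seq_len(ncol(cf)), function(b) max(cf[, b]), numeric(1))
  r <- maxminChannels(suppressWarnings(cwtScalogram(s, "mexh", 1:40)))
  expect_equal(maxChannel(r), mx)
  pk <- localMaxima(mx) - 1
  expect_lte(min(abs(pk - 170)), 2)
  expect_lte(min(abs(pk - 220)), 2)
})

test_that("the seven-band fixture gains resolution under reconstruction", {
  cs <- composeSignal(sevenBandSpec())
  raw <- localMaxima(intensities(cs$signal))
  r <- maxminChannels(suppressWarnings(cwtScalogram(cs$signal, "mexh", 1:40)))
  expect_gte(length(localMaxima(maxChannel(r))), length(raw))
})

test_that("feature layouts assemble max and min channels as declared", {
  x <- rnorm(40)
  r <- maxminChannels(suppressWarnings(cwtScalogram(x, "mexh", 1:6)))
  expect_equal(featureVector(r, "concatenated"),
               c(maxChannel(r), minChannel(r)))
  expect_equal(featureVector(r, "max_only"), maxChannel(r))
  expect_equal(featureVector(r, "min_only"), minChannel(r))
  expect_length(featureAxis(r, "concatenated"), 80)
  expect_equal(featureAxis(r, "min_only"), channelAxis(r))
})

test_that("reconstructMatrix reproduces per-sample reconstruction on a grid", {
  set.seed(6)
  X <- matrix(rnorm(3 * 60), 3, 60)
  feats <- reconstructMatrix(X, "mexh", 1, c(5L, 12L))
  expect_named(feats, c("5", "12"))
  for (i in 1:3) {
    expect_equal(feats[["5"]][i, ],
                 suppressWarnings(reconstructSignal(X[i, ], "mexh", 1, 5)))
    expect_equal(feats[["12"]][i, ],
                 suppressWarnings(reconstructSignal(X[i, ], "mexh", 1, 12)))
  }
})
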