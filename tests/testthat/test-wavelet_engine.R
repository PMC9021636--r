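# Mother wavelet construction and the CWT engine.

test_that("every supported wavelet is admissible, unit-norm and centred", {
  for (nm in supportedWavelets()) {
    w <- motherWavelet(nm)
    dx <- 1 / 64
    # sample at cell midpoints so jump discontinuities (Haar) are not hit
    g <- seq(w@support[1] + dx / 2, w@support[2], by = dx)
    v <- evaluateWavelet(w, 1, g)
    expect_lt(abs(sum(v) * dx), 1e-6 * sum(abs(v)) * dx)   # zero mean
    expect_equal(sum(v^2) * dx, 1, tolerance = 5e-3)       # unit L2 norm
    expect_lt(w@support[1], 0)
    expect_gt(w@support[2], 0)
  }
})

test_that("dilation stretches the support by the scale factor", {
  g <- seq(-3, 3, by = 0.05)
  for (nm in c("mexh", "db2", "bior2.4")) {
    w <- motherWavelet(nm)
    for (a in c(2, 5, 11)) {
      expect_equal(evaluateWavelet(w, a, a * g), evaluateWavelet(w, 1, g))
      # far outside a * base support the dilated wavelet vanishes
      far <- a * w@support[2] * c(1.5, 3)
      expect_equal(evaluateWavelet(w, a, far), c(0, 0))
    }
  }
})

test_that("closed-form wavelet values are reproduced", {
  # Mexican hat at the origin: 2 / (sqrt(3) pi^(1/4)); zeros at +-1
  expect_equal(evaluateWavelet("mexh", 1, 0), 2 / (sqrt(3) * pi^0.25))
  expect_equal(evaluateWavelet("mexh", 1, c(-1, 1)), c(0, 0))
  # centred Haar with the midpoint convention at its jumps
  expect_equal(evaluateWavelet("haar", 1, c(-0.25, 0.25)), c(1, -1))
  expect_equal(evaluateWavelet("haar", 1, 0), 0)
  expect_equal(evaluateWavelet("haar", 1, c(-0.5, 0.5)), c(0.5, -0.5))
  expect_equal(evaluateWavelet("haar", 1, c(-0.75, 0.75)), c(0, 0))
})

test_that("bad wavelet names and scales raise errors", {
  expect_error(motherWavelet("db97"), "unsupported wavelet")
  expect_error(evaluateWavelet("mexh", -1, 0), "positive")
  expect_error(evaluateWavelet("mexh", 0, 0), "positive")
  expect_error(evaluateWavelet("mexh", 1, c(0, Inf)), "finite")
})

test_that("boundary extension obeys its definitions and round-trips", {
  expect_equal(intensities(boundaryExtend(c(1, 2, 3), 2, "symmetric")),
               c(2, 1, 1, 2, 3, 3, 2))
  expect_equal(intensities(boundaryExtend(c(1, 2, 3), 2, "whole")),
               c(3, 2, 1, 2, 3, 2, 1))
  expect_equal(intensities(boundaryExtend(c(1, 2, 3), 2, "zero")),
               c(0, 0, 1, 2, 3, 0, 0))
  for (mode in c("symmetric", "whole"))
    expect_equal(intensities(boundaryExtend(rep(4, 6), 9, mode)), rep(4, 24))
  x <- rnorm(10)
  for (mode in c("symmetric", "whole", "zero")) {
    ext <- intensities(boundaryExtend(x, 7, mode))
    expect_length(ext, 24)
    expect_equal(ext[8:17], x)           # central crop recovers the input
  }
  expect_error(boundaryExtend(1:5, 0), "positive integer")
})

test_that("cwtRow is linear and zero on the zero signal", {
  expect_equal(cwtRow(numeric(64), "mexh", 4), numeric(64))
  set.seed(1)
  for (rep in 1:4) {
    f <- rnorm(40); g <- rnorm(40)
    al <- runif(1, -2, 2); be <- runif(1, -2, 2)
    expect_equal(cwtRow(al * f + be * g, "db2", 3),
                 al * cwtRow(f, "db2", 3) + be * cwtRow(g, "db2", 3),
                 tolerance = 1e-12)
  }
})

test_that("cwtRow matches the direct O(n^2) discretisation", {
  set.seed(2)
  x <- rnorm(48)
  for (nm in c("haar", "mexh", "meyr", "sym2", "rbio2.6")) {
    for (a in c(1L, 3L, 8L)) {
      eng <- suppressWarnings(cwtRow(x, nm, a))
      ora <- suppressWarnings(oracleCwtRow(x, nm, a))
      expect_equal(eng, ora, tolerance = 1e-10)
    }
  }
})

test_that("a Gaussian peak transforms to a mexh maximum at its centre", {
  x <- 0:149
  s <- exp(-(x - 70)^2 / (2 * 6^2))
  r <- cwtRow(s, "mexh", 6L)
  expect_equal(which.max(r), 71L)                 # channel 70, 1-based index
  expect_equal(r, oracleCwtRow(s, "mexh", 6L), tolerance = 1e-10)
  # closed form at the centre: C A sqrt(2 pi) sigma a^(5/2) / (sigma^2+a^2)^(3/2)
  C <- 2 / (sqrt(3) * pi^0.25)
  expect_equal(r[71], C * sqrt(2 * pi) * 6 * 6^2.5 / (36 + 36)^1.5,
               tolerance = 1e-8)
})

test_that("oversized scales error and short signals warn", {
  expect_error(cwtRow(rnorm(16), "mexh", 200L), "dilates the wavelet")
  expect_warning(cwtRow(rnorm(40), "mexh", 8L), "shorter than the dilated")
})

test_that("cwtScalogram stacks rows in scale order and validates input", {
  set.seed(3)
  x <- rnorm(60)
  sg <- suppressWarnings(cwtScalogram(x, "gaus2", c(2L, 5L, 9L)))
  expect_s4_class(sg, "Scalogram")
  expect_identical(dim(cwtCoefficients(sg)), c(3L, 60L))
  expect_equal(cwtCoefficients(sg)[2, ], cwtRow(x, "gaus2", 5L))
  one <- cwtScalogram(x, "gaus2", 1L)
  expect_equal(drop(cwtCoefficients(one)), cwtRow(x, "gaus2", 1L))
  expect_error(cwtScalogram(x, "gaus2", c(3L, 2L)), "strictly increasing")
  expect_error(cwtScalogram(x, "gaus2", integer(0)), "nonempty")
  err <- tryCatch(cwtScalogram(rnorm(16), "mexh", c(1L, 200L)),
                  error = conditionMessage)
  expect_match(err, "scale 200")
})

test_that("a Haar scalogram of a ramp has constant sign per row", {
  ramp <- seq(0, 5, length.out = 80)
  cf <- cwtCoefficients(cwtScalogram(ramp, "haar", c(2L, 4L, 8L)))
  margin <- 10                         # exclude boundary-affected channels
  interior <- cf[, (margin + 1):(80 - margin)]
  for (i in 1:3) expect_true(all(interior[i, ] > 0) || all(interior[i, ] < 0))
})

test_that("Haar coefficients vanish at the extrema of a smooth peak", {
  x <- 0:99
  peak <- exp(-(x - 50)^2 / 72)
  trough <- 1 - peak
  for (a in c(2L, 4L, 8L, 15L)) {
    rp <- cwtRow(peak, "haar", a)
    rt <- cwtRow(trough, "haar", a)
    expect_lt(abs(rp[51]), 1e-6 * max(abs(rp)))
    expect_lt(abs(rt[51]), 1e-6 * max(abs(rt)))
  }
})

test_that("Haar CWT equals a scaled difference of adjacent moving sums", {
  x <- 0:99
  s <- exp(-(x - 50)^2 / 72) + 0.3 * sin(x / 9)
  a <- 8L
  r <- cwtRow(s, "haar", a)
  ext <- intensities(boundaryExtend(s, a, "symmetric"))
  ma <- vapply(1:100, function(b) {
    i <- b + a
    left <- sum(ext[(i - a / 2 + 1):(i - 1)]) + 0.5 * ext[i - a / 2]
    right <- sum(ext[(i + 1):(i + a / 2 - 1)]) + 0.5 * ext[i + a / 2]
    (left - right) / sqrt(a)
  }, numeric(1))
  expect_equal(r, ma, tolerance = 1e-12)
})

test_that("mexh rows carry negated-second-derivative character", {
  x <- 0:199
  s <- exp(-(x - 100)^2 / (2 * 10^2))
  r <- cwtRow(s, "mexh", 4L)
  # positive lobe at the peak flanked by negative lobes
  expect_gt(r[101], 0)
  expect_lt(r[70], 0)
  expect_lt(r[132], 0)
  # proportional to the analytic second derivative of the Gaussian-smoothed
  # Gaussian at the centre: effective width sqrt(sigma^2 + a^2)
  C <- 2 / (sqrt(3) * pi^0.25)
  for (a in c(3L, 6L)) {
    w <- cwtRow(s, "mexh", a)[101]
    expect_equal(w, C * sqrt(2 * pi) * 10 * a^2.5 / (100 + a^2)^1.5,
                 tolerance = 1e-8)
  }
})

test_that("interior coefficients are translation covariant", {
  set.seed(4)
  base <- rnorm(60)
  x <- c(base, numeric(40))
  xs <- c(numeric(10), base, numeric(30))   # shifted by 10 channels
  for (nm in c("mexh", "coif1")) {
    r1 <- cwtRow(x, nm, 4L)
    r2 <- cwtRow(xs, nm, 4L)
    # margins wide enough that no wavelet window touches a boundary or the
    # region where the two signals stop being shifted copies
    expect_equal(r1[31:60], r2[41:70], tolerance = 1e-10)
  }
})
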