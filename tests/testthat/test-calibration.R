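# PLS fitting, PRESS cross-validation, the 0.9 factor rule, error metrics,
# Kennard-Stone splitting and scale selection.

test_that("fitPls reproduces exact one-component and degenerate fits", {
  set.seed(7)
  x1 <- matrix(rnorm(8), 8, 1)
  f <- fitPls(x1, 2 * x1[, 1] + 5, 1)
  expect_lt(rmse(2 * x1[, 1] + 5, f@fitted), 1e-10)
  X <- matrix(rnorm(24), 8, 3)
  y <- 2 * X[, 1] + 5
  fc <- suppressWarnings(fitPls(X, rep(3, 8), 2))
  expect_equal(coef(fc), numeric(3))
  expect_equal(unique(round(predict(fc, X), 10)), 3)
  expect_error(fitPls(X[1:2, ], y[1:2], 1), "at least 3")
  expect_error(fitPls(X, y, 5), "exceeds")
})

test_that("fitPls agrees with the independent Krylov-space solution", {
  set.seed(8)
  X <- matrix(rnorm(40), 8, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 1)) + rnorm(8, 0, 0.1)
  for (k in 1:3)
    expect_equal(coef(fitPls(X, y, k)), krylovPls(X, y, k), tolerance = 1e-8)
  # at full rank PLS predictions equal ordinary least squares
  bols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(coef(fitPls(X, y, 5)), bols, tolerance = 1e-8)
})

test_that("predict validates feature width and centres correctly", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3)
  y <- X[, 2] - X[, 3]
  f <- fitPls(X, y, 2)
  expect_equal(predict(f, X), f@fitted)
  expect_error(predict(f, matrix(0, 2, 5)), "features")
})

test_that("pressLoo matches an explicit leave-one-out refit loop", {
  set.seed(10)
  X <- matrix(rnorm(18), 6, 3)
  y <- drop(X %*% c(1, 0, -1)) + rnorm(6, 0, 0.2)
  pc <- pressLoo(X, y, 2)
  expect_s4_class(pc, "PressCurve")
  expect_equal(pressValues(pc), bruteLooPress(X, y, 2))
  expect_true(all(pressValues(pc) >= 0))
  # y perfectly linear in a single-column X: first-factor PRESS collapses
  expect_lt(pressValues(pressLoo(X[, 1, drop = FALSE], 3 * X[, 1], 1))[1],
            1e-18)
  expect_warning(pressLoo(X, y, 10), "clipped")
})

test_that("selectFactor reproduces hand-computed selections", {
  for (case in craftedPressCases())
    expect_identical(selectFactor(case$press), case$expect)
})

test_that("selectFactor is invariant to positive rescaling of the curve", {
  set.seed(11)
  for (rep in 1:5) {
    press <- cumprod(runif(12, 0.5, 1.05)) * 10
    k <- selectFactor(press)
    for (c0 in c(0.01, 3, 1e6))
      expect_identical(selectFactor(c0 * press), k)
  }
})

test_that("rmse and corrCoeff match hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), "mismatch")
  expect_equal(corrCoeff(1:5, 1:5), 1)
  expect_equal(corrCoeff(1:5, -(1:5)), -1)
  expect_equal(corrCoeff(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(84 / 9))
  expect_error(corrCoeff(c(1, 1, 1), 1:3), "constant")
})

test_that("kennardStone picks a deterministic coverage design", {
  X <- matrix(c(0, 1, 10, 4), ncol = 1)
  expect_identical(kennardStone(X, 2), c(1L, 3L))
  expect_identical(kennardStone(X, 3), c(1L, 3L, 4L))  # 4 is farthest from {0,10}
  set.seed(12)
  M <- matrix(rnorm(40), 10, 4)
  s1 <- kennardStone(M, 7); s2 <- kennardStone(M, 7)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1), 0L)
})

test_that("splitDataset labels calibration and prediction samples", {
  ds <- makeRegressionDataset(nSamples = 10, seed = 13)
  ds <- splitDataset(ds, calFraction = 0.8)
  expect_identical(sum(splitLabels(ds) == "calibration"), 8L)
  expect_identical(sum(splitLabels(ds) == "prediction"), 2L)
  all <- splitDataset(ds, "none")
  expect_true(all(splitLabels(all) == "calibration"))
})

test_that("selectScale returns the grid minimiser of RMSEC", {
  ds <- splitDataset(fineScaleWorld())
  sel <- selectScale(ds, "mexh")
  expect_identical(sel$scale, sel$report$SelectedA[which.min(sel$report$RMSEC)])
  # only fine-scale structure predicts y here: a small grid value wins and
  # large ranges destroy the calibration
  expect_lte(sel$scale, 20L)
  expect_lt(min(sel$report$RMSEC), 0.1 * max(sel$report$RMSEC))
  # single-value grid returns that value
  one <- selectScale(ds, "mexh", scaleGrid = 15L)
  expect_identical(one$scale, 15L)
  expect_identical(nrow(one$report), 1L)
  # RMSEC in the report equals rmse of the stored fit
  expect_equal(one$report$RMSEC,
               rmse(reference(ds)[splitLabels(ds) == "calibration"],
                    one$calibration@fitted))
})

test_that("noise-free latent structure is recovered exactly", {
  bands <- data.frame(center = c(80, 200, 320), width = c(15, 20, 12),
                      amplitude = c(1, 0.8, 1.1), shape = "gaussian")
  sp <- syntheticSpec(bands, baseline = 0, noiseSd = 0, channels = 400L)
  ds <- makeRegressionDataset(sp, nSamples = 20, coefficients = c(1, -0.5, 0.8),
                              amplitudeSd = 0.2, ySd = 0, seed = 9)
  ds <- splitDataset(ds)
  cal <- which(splitLabels(ds) == "calibration")
  k <- selectFactor(suppressWarnings(pressLoo(spectra(ds)[cal, ],
                                              reference(ds)[cal], 10)))
  expect_lte(k, 4L)                     # three latent components (+1 slack)
  fit <- suppressWarnings(fitPls(spectra(ds)[cal, ], reference(ds)[cal], k))
  pred <- predict(fit, spectra(ds)[-cal, ])
  expect_lt(rmse(reference(ds)[-cal], pred), 1e-6 * sd(reference(ds)))
})

test_that("table1Sweep reports one winning row per wavelet", {
  ds <- splitDataset(fineScaleWorld())
  tab <- table1Sweep(ds, wavelets = c("mexh", "db2"), scaleGrid = c(10L, 20L))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$Wavelet, c("mexh", "db2"))
  expect_true(all(is.finite(tab$RMSEC)))
  expect_true(all(abs(c(tab$Rc, tab$Rp)) <= 1))
})
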