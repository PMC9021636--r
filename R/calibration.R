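## Scale selection and reporting: the modelling loop reconstructs features
## over [aMin, aMax] for aMax on a grid (10..40 step 5 by default), selects
## the factor count by the PRESS ratio rule at each aMax, and keeps the aMax
## with minimum calibration RMSE. Kennard-Stone provides the deterministic
## calibration/prediction split.

#' Kennard-Stone sample selection
#'
#' Deterministic, seed-free coverage design: start from the two most distant
#' samples, then repeatedly add the sample whose minimum Euclidean distance
#' to the already-selected set is largest. Ties break to the smaller row
#' index.
#'
#' @param X Samples-by-features numeric matrix.
#' @param k Number of samples to select (2 <= k <= n).
#' @return Integer vector of `k` selected row indices, in selection order.
#' @export
kennardStone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("'k' must be between 2 and nrow(X)")
  D <- as.matrix(stats::dist(X))
  start <- which(D == max(D), arr.ind = TRUE)
  start <- sort(start[1, ])
  sel <- as.integer(start)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- as.integer(which.max(mind))  # first maximum: smallest index wins ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' Assign a calibration/prediction split
#'
#' @param dataset A [SpectralDataset-class].
#' @param policy `"kennard-stone"` (deterministic coverage split on the raw
#'   spectra, default), `"none"` (all samples become calibration), or
#'   `"first"` (first `calFraction` of rows calibrate; for pre-ordered data).
#' @param calFraction Fraction of samples assigned to calibration
#'   (default 0.8, i.e. 64/16 on the 80-sample corn set).
#' @return The dataset with its `split` labels set.
#' @export
splitDataset <- function(dataset, policy = c("kennard-stone", "none", "first"),
                         calFraction = 0.8) {
  policy <- match.arg(policy)
  n <- nrow(dataset@X)
  nCal <- max(2L, min(n - 1L, round(calFraction * n)))
  split <- rep("prediction", n)
  cal <- switch(policy,
                "kennard-stone" = kennardStone(dataset@X, nCal),
                "none" = seq_len(n),
                "first" = seq_len(nCal))
  split[cal] <- "calibration"
  if (policy == "none") split <- rep("calibration", n)
  dataset@split <- split
  dataset
}

.calRows <- function(dataset) {
  cal <- which(dataset@split == "calibration")
  if (length(cal) == 0L) cal <- seq_along(dataset@y)  # unsplit: all calibrate
  cal
}

#' Evaluate one scale range and factor choice
#'
#' Reconstruct-and-calibrate for a single `aMax`: used by [selectScale()] and
#' exposed for direct study of one scale.
#' @keywords internal
.evaluateScale <- function(feat, y, calRows, ratioThreshold, kMax, metadata) {
  Xc <- feat[calRows, , drop = FALSE]
  yc <- y[calRows]
  curve <- suppressWarnings(pressLoo(Xc, yc, kMax))
  k <- selectFactor(curve, ratioThreshold, kMax)
  fit <- suppressWarnings(fitPls(Xc, yc, k, metadata = metadata))
  predRows <- setdiff(seq_along(y), calRows)
  rmsec <- rmse(yc, fit@fitted)
  rc <- corrCoeff(yc, fit@fitted)
  if (length(predRows)) {
    yp <- predict(fit, feat[predRows, , drop = FALSE])
    rmsep <- rmse(y[predRows], yp)
    rp <- corrCoeff(y[predRows], yp)
  } else {
    rmsep <- NA_real_; rp <- NA_real_
  }
  list(fit = fit, curve = curve, nFactors = k, rmsec = rmsec, rc = rc,
       rmsep = rmsep, rp = rp)
}

#' Select the CWT scale range by minimum calibration RMSE
#'
#' For each upper scale endpoint `aMax` in `scaleGrid`, reconstructs the
#' spectra over `[aMin, aMax]`, picks the factor count by the PRESS ratio
#' rule on the calibration samples, fits, and records RMSEC; the `aMax`
#' with minimum RMSEC wins (ties to the smallest scale). If the dataset
#' carries a prediction split, RMSEP and the prediction correlation are
#' reported per scale as well.
#'
#' @param dataset A [SpectralDataset-class] of raw spectra (split labels used
#'   if present; otherwise every sample calibrates).
#' @param wavelet A [MotherWavelet-class] or name.
#' @param scaleGrid Candidate `aMax` values (default `seq(10, 40, 5)`).
#' @param layout Feature assembly, see [featureVector()].
#' @param aMin Fixed lower scale endpoint (default 1).
#' @param ratioThreshold,kMax PRESS ratio rule settings, see [selectFactor()].
#' @param mode Boundary extension mode.
#' @return A list: `scale` (winning `aMax`), `report` (one row per scale:
#'   Wavelet, Factor, RMSEC, SelectedA, Rc, RMSEP, Rp), `calibration` (the
#'   winning [PLSCalibration-class]), `curves` (PRESS curve per scale),
#'   `features` (winning feature matrix for all samples).
#' @export
selectScale <- function(dataset, wavelet, scaleGrid = seq(10L, 40L, 5L),
                        layout = c("concatenated", "max_only", "min_only"),
                        aMin = 1L, ratioThreshold = 0.9, kMax = 20L,
                        mode = "symmetric") {
  layout <- match.arg(layout)
  if (is.character(wavelet)) wavelet <- motherWavelet(wavelet)
  scaleGrid <- sort(unique(as.integer(scaleGrid)))
  if (length(scaleGrid) < 1L) stop("'scaleGrid' must be nonempty")
  calRows <- .calRows(dataset)
  feats <- reconstructMatrix(dataset@X, wavelet, aMin, scaleGrid, layout, mode)
  rows <- vector("list", length(scaleGrid))
  curves <- vector("list", length(scaleGrid))
  evals <- vector("list", length(scaleGrid))
  for (j in seq_along(scaleGrid)) {
    a <- scaleGrid[j]
    ev <- tryCatch(
      .evaluateScale(feats[[as.character(a)]], dataset@y, calRows,
                     ratioThreshold, kMax,
                     metadata = list(wavelet = wavelet@name, scale = a,
                                     layout = layout)),
      error = function(e) {
        warning("scale ", a, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    evals[[j]] <- ev
    if (!is.null(ev)) {
      rows[[j]] <- data.frame(Wavelet = wavelet@name, Factor = ev$nFactors,
                              RMSEC = ev$rmsec, SelectedA = a, Rc = ev$rc,
                              RMSEP = ev$rmsep, Rp = ev$rp)
      curves[[j]] <- ev$curve
    }
  }
  ok <- !vapply(evals, is.null, logical(1))
  if (!any(ok)) stop("all scales failed")
  report <- do.call(rbind, rows[ok])
  best <- which(ok)[which.min(report$RMSEC)]
  names(curves) <- as.character(scaleGrid)
  list(scale = scaleGrid[best], report = report,
       calibration = evals[[best]]$fit, curves = curves[ok],
       features = feats[[as.character(scaleGrid[best])]])
}

#' Sweep every supported wavelet
#'
#' Runs [selectScale()] for each wavelet and keeps the winning scale's row,
#' producing the summary table of the regression analysis (one row per
#' wavelet: Factor, RMSEC with the selected scale, Rc, RMSEP, Rp).
#'
#' @inheritParams selectScale
#' @param wavelets Character vector of wavelet names (default all fourteen).
#' @return A data frame, one row per wavelet.
#' @export
table1Sweep <- function(dataset, wavelets = supportedWavelets(), ...) {
  rows <- lapply(wavelets, function(wn) {
    res <- tryCatch(selectScale(dataset, wn, ...), error = function(e) {
      warning("wavelet ", wn, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) return(NULL)
    res$report[res$report$SelectedA == res$scale, , drop = FALSE]
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write a regression report table
#'
#' Delimited table mirroring the summary layout of the regression analysis:
#' Wavelet, Factor, RMSEC, SelectedA, Rc, RMSEP, Rp.
#'
#' @param report Data frame from [selectScale()] or [table1Sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeReportTable <- function(report, path) {
  write.csv(format(report, digits = 12, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
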