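## PLS1 regression (NIPALS, mean-centred) with leave-one-out PRESS and the
## 0.9 PRESS-ratio factor rule. Coefficients are accumulated per component
## so one fit yields the model for every factor count 1..K.

## core fit: returns coefficients for each number of components 1..Keff
.plsFit <- function(X, y, K, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  K <- min(K, n - 1L, p)
  W <- matrix(0, p, K); P <- matrix(0, p, K); q <- numeric(K)
  y0 <- sqrt(sum(yc^2))
  Keff <- 0L
  for (k in seq_len(K)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw <= tol * max(1, y0)) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt <= tol) break
    pk <- drop(crossprod(Xc, t)) / tt
    qk <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pk)
    yc <- yc - qk * t
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
    Keff <- k
  }
  coefAll <- matrix(0, p, max(Keff, 1L))
  if (Keff > 0L) {
    R <- crossprod(P[, seq_len(Keff), drop = FALSE],
                   W[, seq_len(Keff), drop = FALSE])  # unit upper triangular
    for (k in seq_len(Keff)) {
      bk <- backsolve(R[seq_len(k), seq_len(k), drop = FALSE], q[seq_len(k)])
      coefAll[, k] <- W[, seq_len(k), drop = FALSE] %*% bk
    }
  }
  list(coefAll = coefAll, xMeans = xm, yMean = ym, Keff = max(Keff, 1L),
       converged = Keff)
}

#' Fit a PLS1 calibration
#'
#' Mean-centred NIPALS partial least squares with a fixed number of latent
#' variables. With `nFactors` equal to the rank of the centred spectra the
#' fit reproduces ordinary least squares on the training data.
#'
#' @param X Samples-by-features numeric matrix (n >= 3).
#' @param y Reference values, length `nrow(X)`.
#' @param nFactors Number of latent variables, at most `min(n - 1, p)`.
#' @param metadata Optional provenance list stored on the model.
#' @return A [PLSCalibration-class].
#' @export
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' y <- X[, 1] - 0.5 * X[, 3]
#' fit <- fitPls(X, y, 2)
#' rmse(y, predict(fit, X))
fitPls <- function(X, y, nFactors, metadata = list()) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 samples")
  if (nrow(X) != length(y)) stop("row count of X must equal length of y")
  nFactors <- as.integer(nFactors)
  if (nFactors < 1L) stop("'nFactors' must be >= 1")
  if (nFactors > min(nrow(X) - 1L, ncol(X)))
    stop("'nFactors' exceeds min(n - 1, p)")
  f <- .plsFit(X, y, nFactors)
  if (f$converged < nFactors)
    warning("rank-deficient spectra: factor count reduced from ", nFactors,
            " to ", f$Keff, call. = FALSE)
  k <- min(nFactors, f$Keff)
  b <- f$coefAll[, k]
  fitted <- drop(sweep(X, 2L, f$xMeans) %*% b) + f$yMean
  new("PLSCalibration", nFactors = k, coefficients = b, xMeans = f$xMeans,
      yMean = f$yMean, fitted = fitted, metadata = metadata)
}

#' Predict from a PLS calibration
#'
#' @param object A [PLSCalibration-class].
#' @param newdata Matrix (or single spectrum) with the training feature width.
#' @param ... Ignored.
#' @return Numeric predictions.
#' @export
setMethod("predict", "PLSCalibration", function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
             else as.matrix(newdata)
  if (ncol(newdata) != length(object@coefficients))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object@coefficients))
  drop(sweep(newdata, 2L, object@xMeans) %*% object@coefficients) + object@yMean
})

#' Leave-one-out PRESS curve
#'
#' For every factor count `k` in `1..maxFactors`, the predicted residual
#' error sum of squares over leave-one-out models:
#' \eqn{PRESS(k) = \sum_i (y_i - \hat y_i^{(-i)})^2}.
#'
#' @inheritParams fitPls
#' @param maxFactors Largest factor count; clipped to `min(n - 2, p)` with a
#'   warning when infeasible.
#' @return A [PressCurve-class].
#' @export
pressLoo <- function(X, y, maxFactors = 20L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("leave-one-out PRESS needs at least 4 samples")
  if (n != length(y)) stop("row count of X must equal length of y")
  maxFactors <- as.integer(maxFactors)
  feasible <- min(n - 2L, ncol(X))
  if (maxFactors > feasible) {
    warning("maxFactors clipped from ", maxFactors, " to ", feasible,
            call. = FALSE)
    maxFactors <- feasible
  }
  if (maxFactors < 1L) stop("no feasible factor count")
  err <- matrix(0, n, maxFactors)
  for (i in seq_len(n)) {
    f <- .plsFit(X[-i, , drop = FALSE], y[-i], maxFactors)
    xc <- X[i, ] - f$xMeans
    pred <- drop(crossprod(f$coefAll, xc)) + f$yMean
    # a fold that ran out of rank keeps its last available model
    if (length(pred) < maxFactors)
      pred <- c(pred, rep(pred[length(pred)], maxFactors - length(pred)))
    err[i, ] <- y[i] - pred
  }
  pressCurve(colSums(err^2))
}

#' Select the PLS factor count from a PRESS curve
#'
#' Scans factor counts upward from 1: as soon as the ratio of the present to
#' the former PRESS value exceeds `ratioThreshold` (the additional factor no
#' longer buys a substantial drop), the former factor count is selected. If
#' every step keeps improving past the threshold the cap `kMax` is returned.
#' A PRESS of exactly zero means improvement is exhausted: its factor count
#' is returned.
#'
#' @param curve A [PressCurve-class] (or numeric PRESS vector for factors
#'   `1..K`).
#' @param ratioThreshold Ratio above which the previous factor is kept
#'   (default 0.9).
#' @param kMax Factor cap (default 20); clipped to the curve length.
#' @return Integer factor count.
#' @export
#' @examples
#' selectFactor(c(10, 5, 4.8, 4.7))  # 5/10 <= 0.9 but 4.8/5 > 0.9: select 2
selectFactor <- function(curve, ratioThreshold = 0.9, kMax = 20L) {
  press <- if (is(curve, "PressCurve")) curve@press else as.numeric(curve)
  if (any(press < 0)) stop("PRESS values must be >= 0")
  kMax <- as.integer(kMax)
  if (kMax > length(press)) kMax <- length(press)
  if (kMax < 1L) stop("empty PRESS curve")
  if (kMax == 1L) return(1L)
  for (k in 2:kMax) {
    if (press[k - 1L] == 0) return(k - 1L)
    if (press[k] / press[k - 1L] > ratioThreshold) return(k - 1L)
  }
  kMax
}

#' Root mean square error
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1L) stop("empty input")
  sqrt(mean((observed - predicted)^2))
}

#' Pearson correlation between observed and predicted values
#'
#' @inheritParams rmse
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
corrCoeff <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(observed, predicted)
}
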