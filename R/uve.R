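## Uninformative variable elimination (UVE) on the reconstructed features.
## The spectra matrix is augmented with an equal-width block of artificial
## uniform noise of very small amplitude; n leave-one-out PLS models give a
## collection of coefficient vectors, and each variable's "stability" is the
## mean of its coefficients divided by their standard deviation. Real
## variables whose |stability| does not beat the noise block's cutoff are
## eliminated. The pass is repeated (100 times by default) with fresh noise;
## the retained set with minimum leave-one-out PRESS wins, and variables
## retained in every repetition are flagged as always selected.

#' UVE stability profile
#'
#' @param X Samples-by-features numeric matrix (n >= 4).
#' @param y Reference values.
#' @param nFactors PLS factor count for the leave-one-out submodels.
#' @param noiseAmplitude Amplitude of the appended uniform noise block;
#'   default `1e-10 * max(abs(X))` (small enough not to perturb the real
#'   coefficients, see the package vignette).
#' @return A [StabilityProfile-class]. Drawing of the noise block uses the
#'   current RNG state; seed it for reproducibility.
#' @export
uveStability <- function(X, y, nFactors,
                         noiseAmplitude = 1e-10 * max(abs(X))) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 4L) stop("UVE needs at least 4 samples")
  if (n != length(y)) stop("row count of X must equal length of y")
  nFactors <- min(as.integer(nFactors), n - 2L, 2L * p)
  if (nFactors < 1L) stop("no feasible factor count")
  noise <- matrix(runif(n * p), n, p) * noiseAmplitude
  A <- cbind(X, noise)
  B <- matrix(0, n, 2L * p)
  for (i in seq_len(n)) {
    f <- .plsFit(A[-i, , drop = FALSE], y[-i], nFactors)
    B[i, ] <- f$coefAll[, min(nFactors, f$Keff)]
  }
  m <- colMeans(B)
  s <- sqrt(pmax(colSums(sweep(B, 2L, m)^2) / (n - 1L), 0))
  stab <- numeric(2L * p)
  zero <- s == 0
  stab[!zero] <- m[!zero] / s[!zero]
  stab[zero] <- sign(m[zero]) * Inf   # mean 0 & sd 0 (dead variable) stays 0
  stab[zero & m == 0] <- 0
  new("StabilityProfile", stability = stab[seq_len(p)],
      noiseStability = stab[p + seq_len(p)],
      flagged = zero[seq_len(p)], nFactors = nFactors,
      noiseAmplitude = noiseAmplitude)
}

#' Stability cutoff from the noise block
#'
#' @param profile A [StabilityProfile-class].
#' @param method `"max"` (strictest classical convention: largest absolute
#'   noise stability, default) or `"percentile"`.
#' @param percentile Quantile used by the `"percentile"` method (default 0.99).
#' @return Nonnegative cutoff; real variables must exceed it in absolute
#'   stability to be retained.
#' @export
uveCutoff <- function(profile, method = c("max", "percentile"),
                      percentile = 0.99) {
  method <- match.arg(method)
  ns <- abs(profile@noiseStability)
  if (length(ns) == 0L) stop("empty noise block")
  ns <- ns[is.finite(ns)]
  if (length(ns) == 0L) stop("no finite noise stabilities")
  if (method == "max") max(ns)
  else as.numeric(stats::quantile(ns, percentile, type = 7))
}

#' Variables retained at a cutoff
#'
#' @param profile A [StabilityProfile-class].
#' @param cutoff Nonnegative stability cutoff.
#' @return Integer indices of variables with `|stability| > cutoff`.
#' @export
uveRetain <- function(profile, cutoff) {
  which(abs(profile@stability) > cutoff)
}

#' Repeated UVE selection
#'
#' Runs the stability/cutoff/retain pass `repetitions` times with fresh
#' noise, scores every retained set by leave-one-out PRESS of a PLS model
#' restricted to it, and returns the minimum-PRESS set. Repetitions that
#' retain nothing are skipped with a warning.
#'
#' @inheritParams uveStability
#' @param repetitions Number of UVE passes (default 100).
#' @param seed Master seed; per-repetition noise streams are spawned from it,
#'   so results are reproducible.
#' @param method,percentile Cutoff rule, see [uveCutoff()].
#' @return A [UveSelection-class].
#' @export
uveRepeat <- function(X, y, nFactors, repetitions = 100L, seed = 1L,
                      noiseAmplitude = 1e-10 * max(abs(X)),
                      method = "max", percentile = 0.99) {
  X <- as.matrix(X)
  repetitions <- as.integer(repetitions)
  if (repetitions < 1L) stop("'repetitions' must be >= 1")
  set.seed(as.integer(seed))
  repSeeds <- sample.int(2147483646L, repetitions)
  n <- nrow(X)
  reps <- data.frame(seed = repSeeds, cutoff = NA_real_,
                     nRetained = NA_integer_, press = NA_real_,
                     cvRmsep = NA_real_)
  sets <- vector("list", repetitions)
  profiles <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(repSeeds[r])
    prof <- uveStability(X, y, nFactors, noiseAmplitude)
    cut <- uveCutoff(prof, method, percentile)
    keep <- uveRetain(prof, cut)
    reps$cutoff[r] <- cut
    reps$nRetained[r] <- length(keep)
    if (length(keep) == 0L) {
      warning("repetition ", r, " retained no variables; skipped",
              call. = FALSE)
      next
    }
    kf <- min(as.integer(nFactors), n - 2L, length(keep))
    press <- min(pressValues(suppressWarnings(
      pressLoo(X[, keep, drop = FALSE], y, kf))))
    reps$press[r] <- press
    reps$cvRmsep[r] <- sqrt(press / n)
    sets[[r]] <- keep
    profiles[[r]] <- prof
  }
  ok <- which(!is.na(reps$press))
  if (length(ok) == 0L) stop("every repetition retained no variables")
  best <- ok[which.min(reps$press[ok])]
  always <- Reduce(intersect, sets[ok])
  new("UveSelection", cutoff = reps$cutoff[best],
      retained = as.integer(sets[[best]]),
      alwaysSelected = as.integer(always), repetitions = reps,
      profile = profiles[[best]])
}

#' Per-variable UVE report
#'
#' @param selection A [UveSelection-class].
#' @param axis Optional channel positions, parallel to the variables.
#' @return Data frame: index, channel, stability, retained, alwaysSelected.
#' @export
uveReportTable <- function(selection, axis = NULL) {
  stab <- selection@profile@stability
  p <- length(stab)
  data.frame(index = seq_len(p),
             channel = if (is.null(axis)) seq_len(p) - 1L else axis,
             stability = stab,
             retained = seq_len(p) %in% selection@retained,
             alwaysSelected = seq_len(p) %in% selection@alwaysSelected)
}
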