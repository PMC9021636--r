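# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (direct double loops,
# Krylov-space closed form, explicit refit loops).

# direct O(n^2) evaluation of the discretised CWT integral on the
# boundary-extended signal (no convolution shortcuts)
oracleCwtRow <- function(x, wavelet, a, mode = "symmetric") {
  w <- if (is.character(wavelet)) motherWavelet(wavelet) else wavelet
  n <- length(x)
  kmin <- ceiling(a * w@support[1])
  kmax <- floor(a * w@support[2])
  if (kmax < kmin) kmin <- kmax <- 0
  hw <- max(abs(c(kmin, kmax)), 1)
  ext <- intensities(boundaryExtend(x, hw, mode))
  xi <- seq_along(ext) - hw              # channel index of each ext sample
  vapply(seq_len(n), function(b) {
    sum(ext * w@psi((xi - b) / a)) / sqrt(a)
  }, numeric(1))
}

# PLS1 coefficients through the Krylov-space characterisation:
# B_k = K_k (K_k' G K_k)^{-1} K_k' s with s = X_c' y_c, G = X_c' X_c,
# K_k = [s, G s, ..., G^{k-1} s] (independent of the NIPALS recursion)
krylovPls <- function(X, y, k) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- y - mean(y)
  s <- drop(crossprod(Xc, yc))
  G <- crossprod(Xc)
  Kk <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) {
    Kk[, j] <- v
    v <- drop(G %*% v)
  }
  drop(Kk %*% solve(crossprod(Kk, G %*% Kk), crossprod(Kk, s)))
}

# explicit leave-one-out loop refitting n models per factor count
bruteLooPress <- function(X, y, maxFactors) {
  n <- nrow(X)
  vapply(seq_len(maxFactors), function(k) {
    sum(vapply(seq_len(n), function(i) {
      f <- fitPls(X[-i, , drop = FALSE], y[-i], k)
      (y[i] - predict(f, X[i, ]))^2
    }, numeric(1)))
  }, numeric(1))
}

# crafted PRESS curves with hand-computed factor selections
# (ratio threshold 0.9, cap 20)
craftedPressCases <- function() {
  halving <- 10 * 0.5^(0:19)            # always improving -> cap
  slow <- 10 * 0.95^(0:19)              # first ratio 0.95 > 0.9 -> 1
  list(
    list(press = c(10, 9.5, 9.4, 9.3), expect = 1L),
    list(press = c(10, 5, 4.8, 4.7), expect = 2L),
    list(press = c(10, 8, 6, 5.9, 5.8), expect = 3L),
    list(press = c(10, 4, 1, 0.98), expect = 3L),
    list(press = halving, expect = 20L),
    list(press = slow, expect = 1L),
    list(press = c(10, 0, 0, 0), expect = 2L),      # ratio 0 at k=2; PRESS(2)=0 stops at 2
    list(press = c(0, 5, 4), expect = 1L),          # PRESS(1)=0 -> improvement exhausted
    list(press = c(10, 1, 0.95, 0.2), expect = 2L),
    list(press = c(5, 4.6), expect = 1L),
    list(press = c(5, 4.4, 4.2), expect = 2L),
    list(press = c(8, 7.9), expect = 1L),
    list(press = c(8, 7, 6, 5, 4, 3.9), expect = 5L),
    list(press = c(100, 10, 9.5), expect = 2L),
    list(press = c(1, 0.89, 0.7, 0.69), expect = 3L),
    list(press = c(1, 0.91, 0.5), expect = 1L),
    list(press = c(3, 2.6, 2.35, 2.3), expect = 2L),  # 2.35/2.6 = 0.904 > 0.9
    list(press = c(3, 2.8), expect = 1L),
    list(press = c(2, 1, 0.5, 0.48, 0.1), expect = 3L),
    list(press = c(6, 5, 4, 3, 2, 1, 0.99), expect = 6L),
    list(press = c(10, 9, 8.3), expect = 2L),  # 9/10 = 0.9 is not "more than" 0.9
    list(press = c(10, 8.9, 8.3, 8.2), expect = 2L),
    list(press = c(7, 0.1, 0.099), expect = 2L),
    list(press = rep(4, 20), expect = 1L))
}

# small regression world where only fine-scale structure predicts y:
# a narrow informative band rides on a broad, strongly varying nuisance band
fineScaleWorld <- function(seed = 5) {
  bands <- data.frame(center = c(120, 235, 240, 360), width = c(25, 30, 3, 28),
                      amplitude = c(1.0, 1.2, 0.4, 0.9), shape = "gaussian")
  spec <- syntheticSpec(bands, baseline = 0, noiseSd = 0, channels = 480L)
  makeRegressionDataset(spec, nSamples = 24, coefficients = c(0, 0, 1, 0),
                        amplitudeSd = 0.15, ySd = 0.005, seed = seed)
}
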