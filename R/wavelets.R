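## Mother wavelet construction.
##
## Three routes:
##   * closed forms: haar, mexh, gaus2;
##   * Fourier-domain quadrature: meyr;
##   * cascade refinement from scaling filters: db2, sym2, coif1,
##     bior2.2/2.4/2.6/2.8 and rbio2.2/2.4/2.6/2.8 (decomposition wavelet of
##     each biorthogonal pair).
## Every wavelet is translated so its support straddles 0 and scaled to unit
## L2 norm; tabulated wavelets are evaluated by linear interpolation on a
## dyadic grid and re-centred to numerically zero mean (admissibility).

.WAVELET_NAMES <- c("haar", "mexh", "gaus2", "meyr", "db2", "sym2", "coif1",
                    "bior2.2", "bior2.4", "bior2.6", "bior2.8",
                    "rbio2.2", "rbio2.4", "rbio2.6", "rbio2.8")

#' Supported mother wavelets
#'
#' @return Character vector of the fourteen supported wavelet names (`db2`
#'   and `sym2` are the same order-2 wavelet under both naming schemes, so
#'   fifteen names map to fourteen distinct shapes).
#' @export
supportedWavelets <- function() .WAVELET_NAMES

.waveletCache <- new.env(parent = emptyenv())

## ---- small helpers -------------------------------------------------------

## full linear convolution via FFT (deterministic, no sign/index ambiguity)
.convFull <- function(x, y) {
  nf <- length(x) + length(y) - 1L
  N <- nextn(nf, 2)
  r <- fft(fft(c(x, numeric(N - length(x)))) *
           fft(c(y, numeric(N - length(y)))), inverse = TRUE)
  Re(r)[seq_len(nf)] / N
}

## centred symmetric Laurent polynomials (odd length, middle = z^0 term)
.polyMulC <- function(a, b) .convFull(a, b)
.polyAddC <- function(a, b) {
  n <- max(length(a), length(b))
  pad <- function(p) {
    k <- (n - length(p)) / 2
    c(numeric(k), p, numeric(k))
  }
  pad(a) + pad(b)
}

## ---- filter banks --------------------------------------------------------

## Analysis (decomposition) lowpass of the CDF spline family bior2.N:
## m0~(w) = cos^N(w/2) * P(sin^2(w/2)),  P(y) = sum_{n<K} C(K-1+n, n) y^n,
## K = (2 + N)/2; synthesis lowpass is the linear spline (1,2,1)/4.
.bior2DualLowpass <- function(N) {
  cos2 <- c(1, 2, 1) / 4      # cos^2(w/2)
  y <- c(-1, 2, -1) / 4       # sin^2(w/2)
  cosN <- Reduce(.polyMulC, rep(list(cos2), N / 2))
  K <- (2 + N) / 2
  P <- 1
  yn <- 1
  for (n in seq_len(K - 1)) {
    yn <- .polyMulC(yn, y)
    P <- .polyAddC(P, choose(K - 1 + n, n) * yn)
  }
  sqrt(2) * .polyMulC(cosN, P)
}

.filterBank <- function(name) {
  splineLo <- sqrt(2) * c(1, 2, 1) / 4
  if (name %in% c("db2", "sym2")) {
    s3 <- sqrt(3)
    h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
    return(list(decLo = h, recLo = h))
  }
  if (name == "coif1") {
    h <- c(-0.015655728135465278, -0.07273261951285112, 0.38486484686420286,
           0.85257202021225542, 0.33789766245780922, -0.07273261951285112)
    return(list(decLo = h, recLo = h))
  }
  if (grepl("^bior2\\.", name)) {
    N <- as.integer(sub("bior2\\.", "", name)) * 2L
    return(list(decLo = .bior2DualLowpass(N), recLo = splineLo))
  }
  if (grepl("^rbio2\\.", name)) {
    N <- as.integer(sub("rbio2\\.", "", name)) * 2L
    return(list(decLo = splineLo, recLo = .bior2DualLowpass(N)))
  }
  stop("no filter bank for wavelet '", name, "'")
}

## ---- cascade construction ------------------------------------------------

## Approximate the scaling function of lowpass h on the dyadic grid 2^-J:
## phi ~ (sqrt(2))^J * h * (up2 h) * (up4 h) * ... (J factors).
.cascadePhi <- function(h, J) {
  up <- function(p, f) {
    u <- numeric((length(p) - 1L) * f + 1L)
    u[seq(1L, length(u), by = f)] <- p
    u
  }
  d <- h
  for (j in seq_len(J - 1L)) d <- .convFull(d, up(h, 2L^j))
  sqrt(2)^J * d
}

## Decomposition wavelet of the pair (decLo, recLo):
## psi~(x) = sqrt(2) * sum_n g~[n] phi~(2x - n), phi~ from cascade(decLo),
## g~[n] = (-1)^n recLo[L-1-n] (quadrature-mirror of the synthesis lowpass;
## the convention differs from the canonical g~[n] = (-1)^n h[1-n] by an even
## translation and possibly a global sign, both immaterial here).
.cascadePsi <- function(decLo, recLo, J = 10L) {
  phi <- .cascadePhi(decLo, J)
  Lg <- length(recLo)
  g <- (-1)^(seq_len(Lg) - 1L) * rev(recLo)
  nPsi <- ((Lg - 1L) * 2L^J + length(phi) - 1L) %/% 2L + 1L
  psi <- numeric(nPsi)
  half <- 2L^(J - 1L)
  for (n in seq_len(Lg)) {
    # contributions phi[m] at x-index k = (n-1)*2^(J-1) + (m-1)/2, m odd grid
    m <- seq(1L, length(phi), by = 2L)
    k <- (n - 1L) * half + (m - 1L) %/% 2L + 1L
    psi[k] <- psi[k] + sqrt(2) * g[n] * phi[m]
  }
  list(values = psi, dx = 2^-J)
}

## ---- Meyer wavelet -------------------------------------------------------

## Real, even Meyer wavelet from its Fourier modulus
## A(w) = sin(pi/2 nu(3w/2pi - 1)) on [2pi/3, 4pi/3],
##        cos(pi/2 nu(3w/4pi - 1)) on [4pi/3, 8pi/3],
## nu(t) = t^4 (35 - 84 t + 70 t^2 - 20 t^3); psi(x) = (1/pi) int A cos(wx) dw.
.meyerTable <- function(xmax = 12, dx = 1 / 64) {
  nu <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
  }
  A <- function(w) {
    out <- numeric(length(w))
    lo <- w >= 2 * pi / 3 & w <= 4 * pi / 3
    hi <- w > 4 * pi / 3 & w <= 8 * pi / 3
    out[lo] <- sin(pi / 2 * nu(3 * w[lo] / (2 * pi) - 1))
    out[hi] <- cos(pi / 2 * nu(3 * w[hi] / (4 * pi) - 1))
    out
  }
  w <- seq(2 * pi / 3, 8 * pi / 3, length.out = 4001L)
  Aw <- A(w)
  dw <- w[2] - w[1]
  x <- seq(-xmax, xmax, by = dx)
  # trapezoid quadrature of (1/pi) int A(w) cos(w x) dw
  tw <- c(0.5, rep(1, length(w) - 2L), 0.5) * Aw
  vals <- vapply(x, function(xx) sum(tw * cos(w * xx)) * dw / pi, numeric(1))
  list(x = x, values = vals)
}

## ---- assembly ------------------------------------------------------------

## turn a tabulated wavelet into a centred, unit-norm interpolating closure
.tabulatedWavelet <- function(x, values, trim = 1e-8) {
  dx <- x[2] - x[1]
  # centre the support interval on zero
  x <- x - (x[1] + x[length(x)]) / 2
  # restore numerically exact admissibility lost to truncation
  values <- values - sum(values) / length(values)
  values <- values / sqrt(sum(values^2) * dx)
  keep <- which(abs(values) >= trim * max(abs(values)))
  lo <- x[min(keep)]
  hi <- x[max(keep)]
  psi <- function(p) {
    out <- numeric(length(p))
    inside <- p >= lo & p <= hi
    if (any(inside))
      out[inside] <- approx(x, values, xout = p[inside], rule = 2)$y
    out
  }
  list(support = c(lo, hi), psi = psi)
}

.buildWavelet <- function(name) {
  if (name == "haar") {
    # centred Haar with the midpoint convention at the jumps (psi(0) = 0,
    # psi(+-0.5) averaged with the outside), so integer sampling stays
    # antisymmetric and extrema of a symmetric peak transform to exact zeros
    psi <- function(p) {
      as.numeric(p > -0.5 & p < 0) - as.numeric(p > 0 & p < 0.5) +
        0.5 * as.numeric(p == -0.5) - 0.5 * as.numeric(p == 0.5)
    }
    return(new("MotherWavelet", name = name, support = c(-0.5, 0.5), psi = psi))
  }
  if (name == "mexh") {
    C <- 2 / (sqrt(3) * pi^0.25)
    lim <- 6.87  # |psi| drops below 1e-8 of its maximum
    psi <- function(p) {
      out <- numeric(length(p))
      inside <- abs(p) <= lim
      out[inside] <- C * (1 - p[inside]^2) * exp(-p[inside]^2 / 2)
      out
    }
    return(new("MotherWavelet", name = name, support = c(-lim, lim), psi = psi))
  }
  if (name == "gaus2") {
    # second derivative of exp(-x^2), sign flipped so a peak in f transforms
    # to a positive maximum (same convention as mexh), unit L2 norm
    C <- 1 / sqrt(3 * sqrt(pi / 2))
    lim <- 4.9
    psi <- function(p) {
      out <- numeric(length(p))
      inside <- abs(p) <= lim
      out[inside] <- C * (2 - 4 * p[inside]^2) * exp(-p[inside]^2)
      out
    }
    return(new("MotherWavelet", name = name, support = c(-lim, lim), psi = psi))
  }
  if (name == "meyr") {
    tab <- .meyerTable()
    tw <- .tabulatedWavelet(tab$x + (tab$x[length(tab$x)] + tab$x[1]) / 2,
                            tab$values)
    # table is already centred; .tabulatedWavelet recentres harmlessly
    return(new("MotherWavelet", name = name, support = tw$support, psi = tw$psi))
  }
  fb <- .filterBank(name)
  cw <- .cascadePsi(fb$decLo, fb$recLo)
  x <- (seq_along(cw$values) - 1) * cw$dx
  tw <- .tabulatedWavelet(x, cw$values)
  new("MotherWavelet", name = name, support = tw$support, psi = tw$psi)
}

#' Construct a mother wavelet
#'
#' Builds (and caches) one of the fourteen supported mother wavelets. For the
#' biorthogonal families `bior2.x`/`rbio2.x` the decomposition (analysis)
#' wavelet of the pair is used. All wavelets are centred on zero and carry
#' unit L2 norm; the effective support is trimmed where \eqn{|\psi|} falls
#' below 1e-8 of its maximum.
#'
#' @param name Wavelet name, one of [supportedWavelets()], case-insensitive.
#' @return A [MotherWavelet-class] object.
#' @export
#' @examples
#' w <- motherWavelet("mexh")
#' evaluateWavelet(w, scale = 1, grid = 0)  # closed-form maximum 2/(sqrt(3) pi^(1/4))
motherWavelet <- function(name) {
  name <- tolower(as.character(name)[1])
  if (!name %in% .WAVELET_NAMES)
    stop("unsupported wavelet '", name, "'; see supportedWavelets()")
  if (is.null(.waveletCache[[name]]))
    .waveletCache[[name]] <- .buildWavelet(name)
  .waveletCache[[name]]
}

#' Evaluate a dilated mother wavelet
#'
#' Samples \eqn{\psi(x / a)} on a grid of positions (translation is applied
#' by the transform, not here). Values are ~0 outside `scale` times the
#' wavelet's base support.
#'
#' @param wavelet A [MotherWavelet-class] or a wavelet name.
#' @param scale Positive dilation factor \eqn{a}.
#' @param grid Numeric positions at which to sample.
#' @return Numeric vector of wavelet values.
#' @export
evaluateWavelet <- function(wavelet, scale, grid) {
  if (is.character(wavelet)) wavelet <- motherWavelet(wavelet)
  stopifnot(is(wavelet, "MotherWavelet"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a single positive number")
  if (any(!is.finite(grid))) stop("'grid' must be finite")
  wavelet@psi(grid / scale)
}
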