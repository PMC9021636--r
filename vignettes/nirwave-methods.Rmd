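---
title: "Resolving overlapped NIR bands by scalogram extremes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving overlapped NIR bands by scalogram extremes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirwave)
```

## The problem and the model

NIR absorbance bands are broad and collinear: a spectrum is closely modelled
as a sum of Gaussian-like sub-bands on a smooth baseline, with sub-bands
frequently hidden as shoulders of stronger neighbours. The package resolves
such spectra in three steps.

**Continuous wavelet transform.** For intensities $f(x)$ on an equally
spaced channel axis, the CWT at integer scale $a$ and channel $b$ is the
discretisation of

$$W(a,b) = \frac{1}{\sqrt{a}} \int f(x)\, \psi\!\left(\frac{x-b}{a}\right) dx$$

with $\Delta x = 1$ channel. The $1/\sqrt{a}$ prefactor is used as written
above; note that some packages normalise by $1/a$ instead, which rescales
rows but changes nothing qualitative. Mother wavelets are centred on zero
and normalised to unit $L^2$ norm. A small scale matches narrow structure
(and noise); a large scale responds to broad structure and background. The
response of a Gaussian band of width $\sigma$ and amplitude $A$ under the
Mexican hat peaks at $a = \sigma\sqrt{2}$ with height proportional to
$A\,\sigma^{-1/2}$ and decays for $a \gg \sigma$ — capping the scale range
therefore suppresses very broad background while keeping band-scale
structure.

**Max/min reconstruction.** No single scale matches every band, so over a
scale range $[a_{\min}, a_{\max}]$ each channel keeps its maximum and its
minimum coefficient across scales. Both channels enter the model: peaks
appear in the max channel and troughs (which also carry composition
information) in the min channel. The default feature layout concatenates
the two channels into a $2p$-vector; `max_only`/`min_only` are selectable
because nothing in the method fixes the combination.

**Calibration and variable selection.** PLS1 (mean-centred NIPALS; no
autoscaling, which is standard for absorbance-type features) regresses the
reference property on the reconstructed features. The factor count scans
$k = 1, 2, \ldots$ and stops at the first $k$ where
$\mathrm{PRESS}(k{+}1)/\mathrm{PRESS}(k) > 0.9$, with leave-one-out PRESS; a
PRESS of exactly zero terminates the scan (improvement exhausted), and the
cap (default 20) is returned if every step keeps improving. The upper scale
endpoint is selected from $\{10, 15, \ldots, 40\}$ by minimum calibration
RMSE with $a_{\min} = 1$ fixed; both endpoints are configurable. UVE then
augments the features with an equal-width uniform noise block of amplitude
$10^{-10} \max |X|$ — small enough that real coefficients are unperturbed
(checked to $10^{-6}$ in the tests), but nonzero so the noise block
calibrates the stability a meaningless variable can reach. Stability is
mean/sd of the coefficient over the $n$ leave-one-out submodels; variables
whose $|$stability$|$ does not exceed the maximum absolute noise-block
stability (strictest classical cutoff; a percentile variant is provided)
are eliminated. The pass repeats 100 times with fresh noise; the retained
set with minimum PRESS wins, and the intersection over repetitions flags
the variables selected always.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| extension mode | symmetric (half-point) | least-artifact standard for spectra; whole-point and zero selectable |
| scales | consecutive integers $1..a_{\max}$ | integer-scale scan as the method prescribes |
| scale grid | 10..40 step 5 | band-scale window; beyond it broad background dominates |
| PRESS ratio | 0.9 | an extra factor must buy a >10% PRESS drop |
| factor cap | 20 | safety stop for monotone PRESS curves |
| UVE noise amplitude | $10^{-10}\max|X|$ | "small amplitude" artificial block |
| UVE repetitions | 100 | enough for a stable always-selected intersection |
| split | Kennard–Stone, 80% calibration | deterministic, seed-free coverage design |

## Numerical choices

* **Wavelet evaluation.** haar, mexh and gaus2 are closed forms; meyr is
  tabulated once by quadrature of its Fourier modulus; db2/sym2, coif1 and
  the biorthogonal families are tabulated by cascade refinement (10 levels,
  grid $2^{-10}$) from their scaling filters, with the `bior2.x` dual
  lowpass generated algebraically from the spline construction
  ($\cos^{N}(\omega/2)$ times the minimal interpolating polynomial in
  $\sin^2(\omega/2)$) rather than from copied coefficient tables. For each
  biorthogonal pair the decomposition (analysis) wavelet is used. Tabulated
  wavelets are linearly interpolated, re-centred to numerically zero mean
  (admissibility lost to truncation), and trimmed where $|\psi|$ falls
  below $10^{-8}$ of its maximum, bounding convolution cost with negligible
  truncation error.
* **Haar at jumps.** The Haar wavelet is centred on its sign change and
  evaluates to the jump midpoint at discontinuities ($\psi(0)=0$,
  $\psi(\pm\tfrac12)=\pm\tfrac12$). Integer sampling then stays
  antisymmetric, so extrema of a symmetric band transform to exact zeros —
  the first-derivative behaviour the method relies on. The textbook
  uncentred form would shift the zero crossing by $a/2$ channels. At scale
  1 the centred Haar samples only its midpoint and the row is identically
  zero; scales $\ge 2$ are meaningful.
* **Sign conventions.** mexh and gaus2 are positive at the origin, so a
  band maximum produces a positive coefficient maximum at the band centre
  (negated-second-derivative reading).
* **Boundaries.** Extension tiles reflections, so scale ranges whose
  dilated support exceeds the signal remain defined (with a warning); a
  scale dilating the wavelet beyond 10 signal lengths is refused.
* **Degenerate fits.** Rank-deficient spectra reduce the factor count with
  a warning; a constant reference yields zero coefficients and
  mean-prediction; zero-variance coefficients in UVE are flagged (dead
  variables get stability 0, deterministic ones a signed-infinity
  sentinel).

## The synthetic world

`sevenBandSpec()` fixes a 500-channel composite of seven Gaussian sub-bands
on a gentle quadratic baseline. Five bands are isolated; bands 3 and 6 are
weak narrow bands (width 4 and 3.5 channels, amplitude 0.03) placed on the
flanks of broad hosts at ~2.5 host widths — inside the host's footprint, so
the raw composite shows five maxima, not seven. This realises the shoulder
structure of real NIR signals and is the regime in which the max-channel
genuinely resolves hidden bands: the hidden band's scale-matched response
(height $\propto A\sigma^{-1/2}$) locally exceeds the host's envelope. Two
regimes were deliberately *not* chosen, because the pointwise max over
scales cannot resolve them: equal twin bands closer than twice their width
(the merged large-scale response dominates both centres), and shoulders
strong enough to show in the raw derivative but wide enough to be buried in
the envelope. The constants were fixed while designing the fixture, before
any test thresholds were frozen.

`makeRegressionDataset()` draws per-sample band amplitudes
($\mathcal{N}(A_j, 0.2)$), composes each spectrum, and sets
$y = a_1 - 0.8\,a_4 + 1.2\,a_7 + \varepsilon$, $\varepsilon \sim
\mathcal{N}(0, 0.02)$ by default — the three isolated bands are informative
and everything else is a decoy. What a green test on this world establishes
is recovery of *known linear* structure under *Gaussian* band shapes and
noise; it does not establish robustness to instrument drift, scatter
effects, non-Gaussian lineshapes or wavelength miscalibration, none of
which the generator emulates.

## Design decisions taken where the method is open

* Whether the max, min or both channels feed the model is not fixed by the
  method; concatenation is the default (both peak and trough information),
  the alternatives are selectable, and the per-wavelet sweep can be run
  under any layout.
* PRESS uses leave-one-out rather than a Monte-Carlo split: deterministic,
  standard in NIR work, and it reproduces smooth PRESS-vs-factor curves.
* $R_c$/$R_p$ are Pearson correlations between reference and predicted
  values.
* UVE scores each repetition by PRESS and reports the cross-validated RMSE
  alongside; PRESS decides.
* UVE can be run on the reconstructed features (pipeline default) or on a
  single-scale CWT signal, since the method leaves the entry point open.
* The calibration/prediction split is Kennard–Stone on the raw spectra
  (deterministic and seed-free), so external comparisons are
  tolerance-based rather than split-exact.

## Known limitations

* The scalogram max/min is a pointwise envelope: it resolves hidden *narrow*
  structure but cannot split equal-width twins that merge in the raw signal;
  at a fixed suitable scale the rows themselves resolve more than the
  envelope does.
* With ~25 calibration samples the PRESS ratio rule tends to select 5–9
  factors, and prediction error then carries the usual
  $\sqrt{1 + k/n}$ inflation over the noise floor (measured ≈1.2× on the
  synthetic world); on small sets a stricter ratio threshold trades bias
  for variance.
* MAT input relies on an external Python/scipy for parsing; CSV is the
  first-class format.
* Scales are integers by construction; sub-integer scale grids are out of
  scope.
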