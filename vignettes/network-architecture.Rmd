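---
title: "Quantifying cross-linked actin network architecture and cross-linker kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-linked actin network architecture and cross-linker kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netarch)
```

## The measurement problem

Cross-linking proteins such as CaMKII holoenzymes organize F-actin into
networks whose architecture — how junctions are arranged, how strongly
filaments bundle, how stiff the cables are — carries the biological signal.
In diffraction-limited fluorescence images the network is reduced by
filament-tracing software (SOAX-style stretching open active contours) to
*snakes* (ordered, intensity-bearing point sequences along each cable) and
*junctions* (filament crossover coordinates). This package quantifies that
representation, and the single-molecule kinetics of the cross-linkers, with
a small set of descriptors:

* **Junction spatial statistics.** Each junction's nearest-neighbor
  distance $r_{NN}$ is the minimum of its interpoint distances; their mean
  is $R_{NN} = \sum r_{NN} / N$. For a homogeneous Poisson pattern of
  density $\sigma$ the expectation is $r_{rand} = 1/(2\sqrt{\sigma})$, so
  the **randomness index** $R = R_{NN}/r_{rand}$ calibrates architecture on
  an absolute scale: $R \to 0$ as points coalesce (aggregation), $R = 1$
  for a non-interacting (Poisson) arrangement, and
  $R = 2\sqrt{2/\sqrt{3}} \approx 2.149$ for the optimally spaced
  triangular ("hexagonal-packing") lattice, whose nearest-neighbor constant
  is $R_{NN}\sqrt{\sigma} = \sqrt{2/\sqrt{3}} \approx 1.0746$.
* **Bundling.** The cable intensity $Q$ (mean counts/pixel along a snake)
  grows additively with the number of unresolved filaments in a bundle; the
  adjusted Fisher–Pearson skewness $S$ of the $Q$ distribution (the
  spreadsheet SKEW formula) reports a bundled tail.
* **Stiffness.** Mean curvature $K = \frac{1}{n}\sum \Delta T/\Delta s$
  from unsigned tangent differences at sampling distance $\Delta s$; under
  a worm-like chain the per-segment curvature magnitudes follow the
  half-normal density
  $P(K) = \sqrt{2 l_p c/\pi}\, e^{-l_p c K^2/2}$, whose maximum-likelihood
  estimate is $\hat l_p = 1/(c\,\overline{K^2})$.
* **Compaction.** Myosin-driven collapse is read out from segmented
  fluorescent foci: the integrated intensity
  $\sum Q_{foci} = \sum_i A_i Q_i$ (area in pixel², mean intensity in
  counts/pixel) and the spacing index $R$ of the focus centroids; their
  time courses are fitted by a line ($R$) and a zero-intercept saturating
  exponential ($Q(t) = Q_\infty(1 - e^{-t/\tau})$).
* **Cross-linker kinetics.** Dwell times from single-particle tracks give
  the bound fraction (dwells $> 6$ frames, 0.3 s at 20 frames/s) and
  mono/bi-exponential off-rates $k_{off}$; lateral mobility comes from the
  mean-square displacement, $D_{lat} = \text{slope}/4$ in 2-D.

## Conventions and parameters that matter

| parameter | default | meaning |
|---|---|---|
| pixel size | 0.078 µm | camera sampling (0.119 µm for the lower magnification) |
| sampling distance $c$ | 0.625 µm (8 px) | snake point spacing; junction-fusion and curvature unit |
| junction fusion threshold | $1.2c$ | neighboring junctions closer than this are merged |
| curvature $\Delta s$ | $c$ | tangent-difference spacing (the analysis value is user-defined) |
| frame interval | 0.05 s | 20 frames/s video |
| bound threshold | 6 frames | detection limit for a "bound" dwell (0.3 s) |
| foci area filter | $> 50$ µm² (strict) | particle-analysis area rule |
| MSD fit range | first 4 lags, with offset | bias/variance compromise for short tracks |

Coordinates are micrometers with origin at the top-left pixel center, x
rightward, y downward; pixel files are converted on load. All statistics
treat the field of view as the sampling window; junction density can
alternatively use the convex hull of the points (cropped fields).

**Edge handling.** By default no boundary correction is applied to
$R_{NN}$ — border points lack neighbors beyond the field and their
$r_{NN}$ is biased slightly upward (about +0.4% on $R$ at $10^4$ points in
a 100 × 100 µm field; a test documents this). A guard-zone option
(`edge_margin`) excludes border points as nearest-neighbor *sources* while
keeping them as *targets*; the calibration suites use it so the analytic
constants are reproduced without boundary bias.

**Junction fusion.** "Neighboring junctions closer than $1.2c$" is read as
single-link clustering: the distance relation is closed transitively,
every group is replaced by the unweighted centroid of its members, and the
pass is repeated until no two centroids fall below the threshold. One pass
of connected components is almost always a fixed point already; iterating
guarantees idempotence even for pathological configurations (e.g. a ring
of junctions whose centroid lands near an isolated junction). Output is
coordinate-sorted, so the result is independent of input order.

**Survival fits.** Camera-frame dwells are ceiling-quantized (a molecule
visible during any part of a frame counts the frame), which makes an
exponential dwell exactly geometric in frames. The likelihood is therefore
discrete — an uncensored $m$-frame dwell contributes
$S((m{-}1)\Delta t) - S(m\Delta t)$, a right-censored one $S(m\Delta t)$ —
with left truncation at the detection threshold (the fit conditions on
$m > 6$). Fitting the continuous-time density to quantized data instead
would inflate $\hat k_{off}$ by roughly $k\Delta t/2$ (6% at
$k = 2.55\ \mathrm{s^{-1}}$), and ignoring censoring biases slow rates
upward, which is why both are in the likelihood. The mono MLE has a closed
form (censored-geometric, or 1/mean excess time in the continuous case);
the bi-exponential mixture is optimized from a deterministic grid of 10
starts in logit-amplitude/log-rate coordinates, rates reported descending.
Model comparison uses BIC: with hundreds of dwells the AIC penalty is too
weak to keep the three-parameter mixture from shadowing a one-component
truth.

**Persistence length.** $\hat l_p = 1/(c\,\overline{K^2})$ is reported as
the raw MLE; no bias correction is applied, and the fit records that
choice in its provenance (tracing pipelines are known to underestimate
$l_p$ systematically, so it is best used as a qualitative check). The
estimate is stable against the choice of $\Delta s$ only when the snake is
sampled much more finely than $\Delta s$; resampling chords at a spacing
comparable to the original point spacing redistributes tangent variance
(the effect is visible in the tests, where it is controlled by generating
chains at $\Delta s/8$).

**Foci segmentation.** Binarize at a manual threshold or an in-package
Otsu choice (logged in provenance), label 8-connected components
(configurable to 4), keep components with area strictly greater than
50 µm², then measure area, intensity-weighted centroid and mean intensity
on the *original* image under the binary mask.

## What the synthetic data emulate — and what they do not

Every pipeline input can be generated with known ground truth: Poisson,
Thomas-clustered and jittered-hexagonal junction patterns; worm-like-chain
snakes (tangent increments i.i.d. Gaussian with variance
$\text{step}/l_p$) rendered with a Gaussian PSF, additive bundle
intensity and optional Poisson shot noise; exponential-mixture dwell times
quantized at 20 frames/s and right-censored at a 60 s observation window
(long enough to resolve the slow 0.06 s⁻¹ cable component, mean dwell
16.7 s); Brownian tracks with per-axis increment variance $2D\Delta t$
plus Gaussian localization error; and Gaussian foci with analytic
half-max areas. The Thomas process stands in for "aggregated" because its
intensity (parents × mean offspring) is closed-form, which the tests
assert; parents live on a 4-SD buffer so the in-field intensity is
stationary.

Generators are pure functions of (parameters, seed) — the same seed gives
bit-identical output and the caller's RNG stream is untouched. Ground
truth travels with the object (and as a JSON sidecar on disk), so recovery
tests need no bookkeeping.

Deliberately **not** modeled: photobleaching, blinking and EMCCD
excess noise (shot noise only); 3-D geometry (the analysis is 2-D
projection); spot detection and track linking (tracks are an input); the
snake-evolution algorithm itself (its output format is parsed, and
ground-truth networks are generated directly). Passing recovery tests
therefore show estimator correctness under the stated noise model, not
robustness to every failure mode of real video microscopy.

## Numerical choices

* Nearest-neighbor search is exact; the default grid-binned search accepts
  a candidate only when it is provably global (ring bound) and falls back
  to brute force otherwise, so it equals exhaustive search to floating
  point. Problem sizes: the calibration suites use $10^4$-point patterns
  (20 seeds) and a 3,700-point lattice with ≥ 2,500 interior points.
* Unsigned tangent differences are wrapped to $[0, \pi]$; sign is
  discarded because the worm-like-chain curvature density is a density on
  magnitude.
* The bi-exponential optimizer uses Nelder–Mead with relative
  log-likelihood tolerance $10^{-10}$; a mixture collapsing to a boundary
  (amplitude $< 10^{-4}$ or equal rates) raises an error recommending the
  mono model rather than returning a degenerate fit.
* The time-course exponential is fixed at $Q(0) = 0$ (compaction starts at
  perfusion); a fitted $\tau$ above 10× the observation span or below the
  sampling interval is flagged as unresolvable.
* Degenerate inputs error early with named messages: empty patterns
  (density undefined), fewer than 2 points ($R_{NN}$), constant samples
  (skewness, auto-threshold), all-zero curvatures (infinite $l_p$), equal
  dwells (degenerate likelihood).

## A worked calibration

```{r calibration, eval = FALSE}
f <- field_spec(60, 60, seed = 1)
hex <- gen_hexagonal_pattern(1.0, jitter_sd = 0, f)
a <- hex$ground_truth$spacing
R <- randomness_index(hex, sigma = hex$ground_truth$density_lattice,
                      edge_margin = 2 * a)
as.numeric(R)                                  # 2.14914
attr(R, "provenance")$R_NN * sqrt(hex$ground_truth$density_lattice)  # 1.07457

mean(sapply(1:20, function(s) {
  as.numeric(randomness_index(gen_poisson_pattern(1, field_spec(100, 100),
                                                  seed = s), edge_margin = 1))
}))                                            # 1.0003
```

The lattice values are the exact geometric constants
($2\sqrt{2/\sqrt{3}} = 2.1491$, $\sqrt{2/\sqrt{3}} = 1.0746$); rounded
literature statements of the hexagonal maximum ("2.16") and
nearest-neighbor constant are reproduced to within half a percent.

## Limitations

* $R$ summarizes first-order nearest-neighbor structure only; patterns
  with identical $R$ can differ at larger scales (no pair-correlation or
  Ripley-K analysis is provided).
* $Q$ as a bundling proxy assumes additive fluorescence in a
  diffraction-limited cable — no self-quenching, and no absolute filament
  count without a single-filament calibration.
* The persistence-length MLE inherits the tracing pipeline's smoothing
  bias and is reported uncorrected.
* Kymographs are provided for visualization; dwell statistics are always
  measured from track tables, not from streak lengths.
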