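# netarch

Quantification of cross-linked actin filament networks and of the
single-molecule kinetics of their cross-linkers, for in vitro
reconstitution experiments imaged by fluorescence microscopy (TIRF or
epifluorescence) and traced with SOAX-style active-contour software.

Cross-linkers such as CaMKII holoenzymes bind actin filaments at crossover
**junctions** and along **cables** (single filaments or unresolvable
bundles). The package answers the questions such experiments pose:

* *How are the junctions arranged?* Each junction's nearest-neighbor
  distance `r_NN` is averaged into `R_NN = sum(r_NN)/N` and compared with
  the Poisson expectation `r_rand = 1/(2*sqrt(sigma))` at the observed
  junction density `sigma`. The **randomness index** `R = R_NN / r_rand`
  is ~0 for aggregated points, 1 for a random (non-interacting) network,
  and rises to the triangular-lattice maximum `2*sqrt(2/sqrt(3)) = 2.149`
  for optimal spacing.
* *How bundled are the cables?* Mean snake intensity `Q` (counts/pixel,
  additive in bundle size) and the adjusted Fisher–Pearson skewness `S`
  of its distribution.
* *How stiff are they?* Mean curvature `K = (1/n) * sum(dT/ds)` from
  unsigned tangent differences, and the worm-like-chain persistence
  length from the half-normal curvature density
  `P(K) = sqrt(2*l_p*c/pi) * exp(-l_p*c*K^2/2)`, MLE
  `l_p = 1/(c*mean(K^2))`.
* *How does myosin compact the network?* Segmented fluorescent foci
  (strict `>50 um^2` area filter), integrated intensity
  `sum(A_foci * Q_foci)`, foci spacing index, and linear/saturating-
  exponential time-course fits.
* *How do cross-linkers bind and move?* Dwell times from particle tracks
  (bound = longer than 6 frames, 0.3 s at 20 frames/s), censoring-aware
  mono/bi-exponential `k_off` fits, and `D_lat` from the MSD slope/4.

Synthetic-data generators (`gen_*`) produce every input — point patterns,
worm-like-chain filaments rendered with a Gaussian PSF, dwell times,
Brownian tracks, foci images — with known ground truth, so the whole
pipeline is testable without experimental data. `run_pipeline()` drives
simulate/import/analyze stages from a YAML or JSON config;
`inst/cli/netarch.R` is a thin Rscript wrapper.

## Worked example

```r
library(netarch)

## calibration: a jitter-free hexagonal-packing lattice, interior points
f   <- field_spec(60, 60, seed = 1)           # 60 x 60 um field
hex <- gen_hexagonal_pattern(1.0, jitter_sd = 0, f)
a   <- hex$ground_truth$spacing
R   <- randomness_index(hex, sigma = hex$ground_truth$density_lattice,
                        edge_margin = 2 * a)
as.numeric(R)
#> [1] 2.14914

## bi-exponential dwell-time recovery at the cable-fit mixture
d <- gen_dwell_times(rbind(c(0.43, 1.2), c(0.56, 0.06)), n = 5000,
                     frame_interval = 0.05, window = 60, seed = 13)
fit_survival(d, model = "bi", threshold_frames = 6)
#> bi-exponential dwell-time fit (n = 4257, 76 censored)
#>   component 1: amplitude 0.437, k_off = 1.142 1/s
#>   component 2: amplitude 0.563, k_off = 0.05865 1/s
#>   logLik -25747.97, AIC 51501.94

## lateral diffusion from MSD
tr <- gen_tracks(D = 0.37, n_tracks = 200, n_frames = 100,
                 field = field_spec(50, 50), seed = 14)
fit_dlat(msd_curve(tr, max_lag = 10))
#> MSD line fit (first 4 lags): D_lat = 0.362 um^2/s, offset = 0.002506 um^2

## persistence length from a traced worm-like chain
sn <- gen_wlc_snake(l_p = 4.5, step = 0.625, n_steps = 10000,
                    field = field_spec(1e4, 1e4), seed = 11)
fit_persistence_length(snake_curvature(sn, 0.625)$dT / 0.625, 0.625)
#> Worm-like-chain persistence length (half-normal curvature MLE)
#>   l_p = 4.436 um  (n = 9999, c = 0.625 um, KS D = 0.00746)
```

The lattice index lands on the exact geometric constant 2.1491; the
mixture fit recovers both generator rates (1.2 and 0.06 s⁻¹) and
amplitudes within sampling error despite frame quantization, truncation at
the 6-frame detection threshold and window censoring; the diffusion and
stiffness estimators recover their generator settings within a few
percent.

Typical analysis of traced experimental data:

```r
net <- parse_soax("network.txt", pixel_size = 0.078)
net <- fuse_junctions(net)                    # merge junctions < 1.2c apart
net <- prune_snakes(net, min_length = 1, min_mean_intensity = 100)
summarize_architecture(net)                   # sigma, R_NN, r_rand, R, Q, S, K, l_p
```

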