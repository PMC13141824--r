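# magnetokinetics

Image-based physical characterization of magnetotactic bacteria (MTB):
from time-lapse microscopy to per-cell swimming velocity, effective radius
and magnetic moment, and onward to population decomposition of
heterogeneous environmental samples.

MTB biomineralize chains of magnetic nanocrystals that give each cell a
permanent magnetic moment *m*. In the Bean model the cell is a
self-propelled dipole: it swims at constant speed *v* while magnetic
torque against rotational drag α relaxes its orientation towards the
field **B**. Reversing the field drives a U-turn of canonical shape

    y(x) = -(L/π) · ln sec(πx/L)

whose asymptotic width `L = π v α / (m B)` encodes the moment:

    m = π α v / (B L),    α = 8π²ηR³  (Stokes-sphere 8πηR³ optional)

with η the medium viscosity and `R = sqrt(area/π)` the effective radius
from the detected cell footprint.

The package implements the full chain:

* **Synthetic data** — Bean-model trajectory simulator (RK4, closed-form
  oracle), population samplers in (log10 v, R) space, rendered TIFF stacks
  with ground truth (`simulateTrajectory`, `samplePopulation`,
  `genUturnDataset`, `renderStack`).
* **Detection** — illumination flattening, denoising, contrast boost +
  Otsu segmentation, temporal-median suppression of stuck cells
  (`detectStack`, EBImage underneath).
* **Tracking** — gated global-nearest-neighbour linker with
  constant-velocity prediction and Hungarian assignment (`buildTracks`),
  contract-compatible with external multiple-hypothesis tracker exports.
* **U-turn magnetometry** — segmentation per field reversal, canonical
  alignment, shape fitting, per-track moment estimates with eligibility
  flags (`estimateMoments`).
* **Velocimetry** — central-difference speeds, Freedman-Diaconis binning,
  joint (R, log10 v) relative-frequency histograms, optional
  field-compliance filter, passive-motion labels.
* **Populations** — Sheather-Jones/Epanechnikov KDE surfaces,
  AIC-constrained multi-Gaussian decomposition by differential evolution,
  PDF-volume significance, error-weighted critical-radius fit,
  directional quantile envelopes, variational Gaussian mixture clustering
  in (R, v, m) (`kde2d`, `fitMixtureSweep`, `criticalRadius`,
  `quantileEnvelope`, `clusterRVM`).

## Worked example

Simulate a cell with a known moment under a square-wave field, then
recover the moment from its track alone:

```r
library(magnetokinetics)

fp <- fieldProtocol(magnitude = 2.55e-4, mode = "square_wave",
                    reversalTimes = c(2, 4))
cell <- cellState(speed = 25, moment = 1.5e-15, radius = 0.7)
tr <- simulateTrajectory(cell, fp, dt = 0.01, duration = 6)

estimateMoments(tr, fp)
#> MomentEstimates: 1 tracks with moments, 0 excluded
#>   m: median 1.5e-15 A m^2, range [1.5e-15, 1.5e-15]

momentTable(estimateMoments(tr, fp))[, c("R_um", "v_um_s", "m_Am2", "L_um", "n_uturns")]
#>   R_um v_um_s        m_Am2     L_um n_uturns
#> 1  0.7     25 1.497399e-15 5.013472        2
```

The two U-turns fit to width ≈ 5.01 µm; inverting the width relation
returns 1.497e-15 A·m² against the true 1.5e-15 (0.17 % error). Population
decomposition works the same way from any (x, y) sample matrix:

```r
comp <- data.frame(mu1 = c(0, 3), mu2 = c(0, 2),
                   sigma1 = 0.5, sigma2 = 0.4, rho = 0)
pts <- sampleMixture(comp, 15000, seed = 17)
m <- fitMixtureSweep(pts, nRange = 1:3, seed = 18, gridSize = 48,
                     popFactor = 8, maxIter = 100)
sum(isSignificant(m))
#> [1] 2
```

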