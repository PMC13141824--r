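---
title: "Methods: Bean-model magnetometry and population decomposition"
author: "magnetokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bean-model magnetometry and population decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetokinetics)
```

## The physical model

A magnetotactic bacterium is treated as a self-propelled magnetic dipole
(the Bean model): it swims at constant speed $v$ along its body axis while
the magnetic torque, opposed by rotational viscous drag, relaxes the angle
$\varphi$ between body axis and field,

$$\alpha \frac{d\varphi}{dt} = -mB\sin\varphi,
\qquad \tau = \frac{\alpha}{mB},$$

with $m$ the cell magnetic moment (A·m²), $B$ the flux density (T) and
$\alpha$ the rotational drag coefficient. When the field reverses, the cell
traces a U-turn; in the canonical frame the ideal path is

$$y(x) = -\frac{L}{\pi}\ln\sec\frac{\pi x}{L},$$

an even curve with apex at the origin whose legs approach $x = \pm L/2$.
The asymptotic width is $L = \pi v \tau = \pi v \alpha/(mB)$, so a fitted
width inverts to

$$m = \frac{\pi \alpha v}{B L}.$$

Two conventions for the sphere-equivalent drag circulate:
$\alpha = 8\pi^2\eta R^3$ and the classic Stokes value $8\pi\eta R^3$,
differing by a factor $\pi$. The package defaults to the former and exposes
`convention = c("pisq", "sphere")` on every function that touches
$\alpha$; both are exact cubic laws in the effective radius $R$, obtained
from the detected cell area as the equal-area circle radius
$R = \sqrt{A/\pi}$. Defaults $\eta = 0.90\times10^{-3}$ Pa·s and
$B = 2.55\times10^{-4}$ T correspond to aqueous medium at room temperature
and the square-wave amplitude used in the hanging-drop U-turn assays.

Units: user-facing lengths are micrometres and speeds µm/s; conversion to
SI happens in a single internal helper. Moments are always A·m².

### Numerical integration

`simulateTrajectory()` integrates the heading equation with fixed-step RK4
and advances the position along the mid-step heading, which preserves
$\lVert dx/dt\rVert = v$ exactly at every step. A field reversal leaves the
laboratory heading continuous; since exact anti-alignment is an unstable
equilibrium, a post-reversal misalignment of at least
$\varepsilon = 10^{-3}$ rad is enforced so the torque is nonzero. The
closed-form relaxation $\tan(\varphi/2) = \tan(\varphi_0/2)e^{-t/\tau}$ is
exported (`headingClosedForm`) and is used in the tests as an independent
oracle; RK4 at $dt = \tau/100$ agrees with it to $10^{-9}$ rad and
reproduces the asymptotic width to well under 1 %. Optional white
rotational noise (diffusivity in rad²/s) is added per step.

## U-turn analysis

Tracks recorded under a square-wave protocol are cut at each reversal time;
a candidate segment runs to the earlier of the next reversal or the first
step at which the smoothed heading settles within 5° of the new field
direction. Segments whose heading never swings past 90° are discarded (the
cell ignored the reversal, e.g. non-magnetic cells), as are segments with
fewer than `minPoints = 10` points. When no protocol is available,
reversals are detected as sign changes of the smoothed velocity component
along the track's principal axis, backtracked to the last step at which
the heading still matched the old settled direction. Such a detected
boundary necessarily lags the true field flip by the heading response
time (of order $\tau\ln(2/\varepsilon)$ — an anti-aligned cell responds
exponentially slowly), but the segment retains its entry leg and the
fitted widths agree with protocol-based segmentation.

Canonical alignment rotates the pre-reversal mean heading onto $+y$ and
puts the apex (maximal $y$) at the origin, so ideal points obey the shape
function directly. (The construction is stated elsewhere with the
pre-reversal heading on $-y$; the two frames differ by a flip of an even
curve and yield identical widths.) Fitting minimises the squared misfit
over $(L, x_0, y_0)$ by Nelder-Mead with a domain penalty keeping
$|x - x_0| < L/2$, started from the observed $x$-extent at several
inflation factors. Vertical residuals are weighted by $\cos^2$ of the
local slope angle — the first-order perpendicular distance — because on
the near-vertical legs an unweighted vertical gap amplifies centroid
noise without bound. A fit is *eligible* when (i) the weighted RMS
residual normalised by $L$ is at most 0.05, (ii) the observed leg-to-leg
span agrees with $L$ within 20 % (a developed U-turn's span approaches
$L$; shapes like circular arcs fit only with widths inconsistent with
their span), and (iii) $L$ does not exceed a configurable field-of-view
bound; ineligible fits are flagged, not raised as errors. Per eligible
U-turn, $v$ is the mean speed over that segment (each turn carries its own
speed); $R$ is the trajectory average; the track moment is the mean
(median available) over its eligible turns. Tracks with no eligible turn
are excluded with reason `"non-magnetic or unfit"` — this exclusion stream
is what downstream population analysis sees as the non-magnetic
population. The eligibility constants are heuristic choices; the original
assay reports only the number of eligible tracks, not its criteria, so
that count is not reproducible and is not a target here.

## Detection and tracking

Detection is a deliberately simple, swappable chain: illumination
flattening (default: robust degree-2 polynomial background, exact for
linear gradients; heavy Gaussian blur as alternative), edge-preserving
denoising (3×3 median by default), contrast boosting (gamma 0.7 by
default, CLAHE available), global Otsu threshold, connected components,
area filter, intensity-weighted centroids. Stuck and motionless cells and
static debris are suppressed by subtracting a per-pixel temporal median
(window 51 frames, subsampled). The published pipeline's exact non-linear
contrast operators are not public; accuracy is therefore judged against
synthetic ground truth (precision and recall at least 0.95 at SNR 5), not
against a reference filter chain.

Tracking is a gated global-nearest-neighbour linker: constant-velocity
prediction from the last three steps, gate $v_{\max}\Delta t +$ slack,
globally optimal per-frame assignment via a Hungarian solver written for
this package (the pre-installed stack has no linear-assignment solver),
new tracks from unmatched detections, closure after `maxGap = 2` missed
frames, and a `minTrackLength = 10` filter. This is a contract-compatible
stand-in for offline multiple-hypothesis tracking: at the densities used
here (tens of cells per frame) it reaches association accuracy 1.0 on
synthetic stacks, and externally produced track CSVs with the same header
can be imported unchanged. Full hypothesis-tree search, track
splitting/merging and 3D tracking are out of scope.

## Velocimetry

Per-step speeds are central differences at interior points (more
noise-robust than forward differences); each speed is paired with the
track-average radius. Histograms use Freedman-Diaconis widths
$2\,\mathrm{IQR}\,n^{-1/3}$ (Sturges fallback on zero IQR, with a warning)
and velocities are displayed in $\log_{10}$; joint (R, log10 v) grids are
normalised to relative frequencies summing to 1. Per-step instances, not
per-track means, populate the joint histogram — sample sizes of order
$10^4$–$10^5$ instances arise from a few hundred tracks. The ~7 µm/s
passive-motion threshold is attached as a label only and never filters
anything automatically. Compliance filtering against the guiding-field
direction exists but is off by default, matching the reported practice of
keeping all detected motion.

## Population identification

The density surface is a binned product-Epanechnikov KDE with per-axis
Sheather-Jones bandwidths (kernels scaled so their standard deviation
equals the bandwidth, the `stats::density` convention). Populations are
scaled bivariate Gaussians $G(\mu_1, \mu_2, \sigma_1, \sigma_2, \rho, a)$
— "symmetric" is read as a general symmetric covariance matrix, since the
reported per-component $\rho$ values exclude axis-aligned ellipses, and
negative correlations are deliberately not forbidden.

Whether the mixture is fitted to the KDE surface or to raw points by
likelihood is not documented for the original pipeline; the amplitude
parameter $a$ implies a surface objective, so the default minimises the
squared residual between $\sum_k a_k e^{-q_k/2}$ and the KDE grid, with an
`objective = "mle"` alternative fitting raw points with volume-derived
weights. For the surface objective the amplitudes enter linearly and are
solved exactly by non-negative least squares at every evaluation (variable
projection), so differential evolution searches only the $5n$ shape
parameters. DE uses best/1/bin mutation with dithered $F$, bounce-back
bounds (means: data range ±20 %; sigmas: 1/100 to 1× the range;
$|\rho| \le 0.95$), a mandatory seed, and a warm start: each $n$'s
population is seeded with the polished $(n-1)$-component solution plus a
random extra component, which keeps RSS monotone in $n$. An L-BFGS-B
polish follows.

Model selection minimises $\mathrm{AIC} = N\ln(\mathrm{RSS}/N) + 2k$ over
the sweep ($N$ grid cells, $k = 6n$), preferring the smallest $n$ within
$\Delta\mathrm{AIC} < 2$. Because grid residuals are smooth, the
minimum-AIC model often carries near-zero extra components; the
scientifically reported quantity is therefore the number of *significant*
components: each component's PDF volume is
$a\,2\pi\sigma_1\sigma_2\sqrt{1-\rho^2}$ and components below a 5 % volume
share (the threshold is not stated in the original analysis; 0.05 is this
package's default) are flagged non-significant. This mirrors the observed
phenomenology — e.g. a two-population day-2 sample yields a min-AIC model
with two significant components plus a negligible extra.

The critical radius below which cells carry no measurable moment comes
from weighted least squares of $m$ on $R$ with weights $1/\sigma_m^2$;
$r_c = -b_0/b_1$ with a delta-method standard error, undefined (flagged)
when the slope is not positive. Uncertainty regions use directional
quantile envelopes: the q-quantile of projections onto 250 evenly spaced
directions defines half-planes whose intersection (computed by polygon
clipping) is the envelope; Douglas-Peucker simplification stands in for
curve-evolution polyline simplification — vertex counts are not part of
the contract. For an isotropic Gaussian the q = 0.95 envelope is a circle
of radius 1.645, used as the analytic oracle.

Strict clustering in $(R, v, m)$, for data too sparse for a 3D mixture
fit, is a variational Bayesian Gaussian mixture (full covariance,
Gaussian-Wishart conjugate updates, Dirichlet concentration $1/K$)
written for this package — the pre-installed stack has no variational GMM,
and the EM/BIC-based `mclust` is kept as an independent cross-check in the
tests rather than as the implementation. Coordinates are standardized
internally (the three axes differ by ~15 orders of magnitude); k-means
under the run seed initialises responsibilities; components keeping more
than 1 % posterior weight count as effective clusters.

## The synthetic-data generator

Tests and the acceptance analysis run entirely on synthetic data with
known ground truth, emulating the study conditions:

* populations are bivariate Gaussians in $(\log_{10} v, R)$ with the
  published table parameters; weights are not published, so equal weights
  are the default; samples of $n = 75{,}000$ match the reported
  per-dataset instance counts;
* moments follow either per-component Gaussians around the reported
  most-probable value $1.5\times10^{-15}$ A·m², or the linear size law
  $m = b_1(R - r_c)$ clipped at zero with $r_c = 0.57$ µm;
* stacks render each cell as an isotropic Gaussian spot
  ($\sigma = 0.8R/\text{pixel scale}$, an arbitrary appearance stand-in —
  cell optics are not modelled) with total flux proportional to area, over
  a background with optional linear illumination gradient, Poisson and/or
  Gaussian read noise, and a configurable fraction of stuck cells.

What passing on these fixtures does **not** show: robustness to refocusing
and field-of-view drift, non-Gaussian cell appearance (rods, chains,
diplococci), flagellar wobble and helical swimming, 3D motion out of the
focal plane, and density regimes beyond ~50 cells per frame. Those remain
the domain of the full offline tracking stack.

## Problem sizes and seeds

Everything is seeded explicitly and reproducible bit-for-bit. The mixture
sweeps used in the tests and the acceptance script run on 56–64 grid cells
per axis, DE population 8 per parameter and 150 generations with the warm
start — sizes at which the recovered component means sit within ~0.01 of
the generating values for the table-based samples. `scripts/acceptance.R`
repeats each recovery over 5 replicate seeds and reports medians.

## Known limitations

* The detection chain is intentionally simpler than the published one;
  its acceptance is statistical, not operator-by-operator.
* Eligibility constants for U-turn fits are this package's own defaults;
  published per-track eligibility counts cannot be reproduced.
* AIC on KDE-surface residuals is a pragmatic, not a likelihood-principled,
  criterion; it is used because it reproduces the reported significant
  population counts, and the MLE objective is available for comparison.
* 2D only; the Bean model here has no thermal orientation noise by
  default (rotational diffusion is opt-in).
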