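---
title: "Gradient-based inverse planning for HDR brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-based inverse planning for HDR brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrplan)
```

## The planning problem

High-dose-rate brachytherapy delivers radiation from a single stepping
source that dwells at discrete positions inside implanted applicator
channels. With the implant geometry and the dwell positions fixed, the only
free variables are the dwell times $t_{m,n}$ (channel $m$, position $n$).
Inverse planning turns the clinical prescription — cover the high-risk
clinical target volume (HR-CTV), spare bladder, rectum and sigmoid — into
an objective function over the dwell times and minimizes it.

`hdrplan` implements this pipeline end to end: TG-43 dose kernel,
objective and analytic gradient, bounded quasi-Newton minimization, DVH
evaluation, and a synthetic phantom generator so everything runs without
patient data.

## Dose model

Dose is linear in the dwell times,
$$D_i = \sum_{m=1}^{N_M} \sum_{n=1}^{N_N} d_{m,n,i}\, t_{m,n},$$
with the kernel entry $d_{m,n,i}$ the TG-43 point-source dose rate per unit
dwell time,
$$d = S_K\,\Lambda\,\left(\frac{r_0}{r}\right)^2 g(r)\,\phi_{an}(r) ,$$
where $S_K$ is the air-kerma strength (U), $\Lambda$ the dose-rate constant
(Gy h$^{-1}$ U$^{-1}$), $r_0 = 1$ cm, $g(r)$ the radial dose function and
$\phi_{an}(r)$ the 1D anisotropy factor, both linearly interpolated from
tables. Three numerical choices matter:

* **Point-source (1D) formalism.** The 2D line-source formalism with
  $F(r,\theta)$ would change near-source dose shapes but none of the
  optimizer behavior studied here; the 1D form keeps the kernel a pure
  function of distance and is the natural extension point if orientation
  data are ever added.
* **Near-source clamp** `r_min = 0.1` cm (one voxel of the 0.1 cm planning
  grid). Distances below one voxel are unresolvable on the dose grid, and
  the clamp guarantees finite kernel entries even when a calculation point
  coincides with a dwell position.
* **Out-of-table radii** are clamped to the nearest table end rather than
  extrapolated — safe, monotone behavior far from the implant.

The packaged source characterization
(`inst/extdata/source_ir192_synthetic.csv`) is *synthetic*: smooth analytic
$g(r)$ and $\phi_{an}(r)$ curves on the Ir-192 scale with
$\Lambda = 0.01109$ Gy/h/U and $S_K = 40800$ U (a typical 10 Ci HDR
source). No result in this package depends on the exact table values — all
checks are analytic, relative or trend-based — but the scale makes dwell
times come out in clinically familiar seconds.

## Objective and gradient

The objective is
$$F(t) = \sum_{i \in \mathrm{TAR}} p_{\mathrm{TAR}}\, H(D_i - D_0)\,(D_i - D_0)^2
 + \sum_{i \in \mathrm{OARs}} p_{\mathrm{OAR}}\, H(D_i - D_0)\,(D_i - D_0)^2
 + p_{\mathrm{SOU}} \sum_m \frac{1}{N_m} \sum_n (t_{m,n} - t_{m,\min})^2 ,$$
with one-sided Heaviside switches: a target voxel is penalized when
$D_i \le D_0$ (underdose), an OAR voxel when $D_i \ge D_0$ (overdose). At
exact equality the switch is on but the squared factor vanishes, so the
convention is value- and gradient-neutral. Each ROI may carry both a
minimum and a maximum objective; a voxel belonging to several ROIs is
penalized once per ROI.

The last term is the dwell-time modulation term, weighted by the
dwell time modulation factor (DTMF, $p_{\mathrm{SOU}}$). Two design points
distinguish it from the dwell-time restrictions used by simulated-annealing
planners:

* it is anchored at each channel's **minimum** dwell time, not the mean —
  positions unsuited to dwelling (e.g. adjacent to an OAR) keep their short
  times while long dwells are pulled down; and
* the factor is **not normalized** to $[0, 1]$: any nonnegative value is
  accepted (default 10), leaving the modulation range open for sites with
  different trade-offs.

The gradient is analytic. The dose penalties contribute
$2 p (D_i - D_0)\, d_{m,n,i}$ over violating voxels. The modulation term is
piecewise smooth in $t$ because of the channel minimum; it is
differentiated with the argmin frozen at the evaluation point (first index
wins ties), which includes the coupling through $t_{m,\min}$ on the
minimizing coordinate:
$-\frac{2 p_{\mathrm{SOU}}}{N_m} \sum_n (t_{m,n} - t_{m,\min})$ there and
$+\frac{2 p_{\mathrm{SOU}}}{N_m} (t_{m,n} - t_{m,\min})$ elsewhere. This is
exact almost everywhere; switching surfaces and min-ties form a
measure-zero set on which the vanishing squared terms keep $F$ continuous.
The test suite verifies the gradient against central finite differences on
randomized instances away from those surfaces (relative tolerance $10^{-4}$).

## Optimization

Minimization uses L-BFGS-B (via `stats::optim`) with box constraint
$t \ge 10^{-6}$ s on every dwell time — strict positivity without an
explicit reparameterization — starting from a uniform 1 s plan, for at most
100 outer iterations (earlier stop when the projected gradient norm falls
below $10^{-8}$). Any limited-memory quasi-Newton method with a monotone
line search would do; what the package guarantees, and the tests assert, is:

* all returned times $\ge$ the lower bound, exactly;
* determinism — identical inputs give bit-identical dwell times;
* a non-increasing objective trace. `optim` does not expose per-iteration
  callbacks, so the trace records the objective at each evaluation that
  improved on all previous ones; under a monotone line search this
  coincides with the accepted-iterate values, and its length is capped at
  `max_iterations + 1`.

One consequence of the one-sided objective is that the optimum is generally
a *set*: once every voxel satisfies its objectives, $F = 0$ on a whole
region. On a single-dwell problem the optimizer recovers the boundary root
$t = D_0/d$ when approaching from below; starting inside the flat region it
(correctly) stays put.

## Plan evaluation

DVH metrics follow the empirical, non-interpolated convention: doses sorted
descending, thresholds compared with $\ge$. $D_{x\%}$ is the dose of the
point at the smallest cumulative volume $\ge x\%$; $V_{y\%}$ is the
fractional volume at or above $y\%$ of the **prescription** (not of any
plan statistic); $D_{z\mathrm{cc}}$ is the same construction at absolute
volume. Interpolated DVHs would differ by sub-voxel amounts that are
irrelevant at a 0.1 cm grid, and the empirical form is exactly checkable
against a brute-force threshold-scan oracle, which the tests do.

Plans are normalized by uniformly rescaling all dwell times so the target
$D_{90\%}$ equals the prescription (6 Gy by default). Because dose is
linear in the times, the rescaled $D_{90\%}$ matches the prescription to
round-off and the operation is idempotent.

The dwell time standard deviation (DTSD) is the population standard
deviation pooled over all dwell positions of all channels. For the
DTMF–DTSD trade-off curve (`dtmf_sweep()`) it is computed on the
**un-normalized** optimized plan: normalization multiplies all times by a
common factor, which rescales the curve but not its shape, and keeping the
raw optimizer output makes runs with different normalization factors
comparable. The plan quality report, by contrast, quotes the DTSD of the
plan as delivered (after normalization), so that a report recomputed from a
stored plan CSV reproduces the original exactly.

## Synthetic phantoms

`make_phantom()` builds the five stylized applicator geometries (Fletcher
tandem-and-ovoids with its 3 channels, double ovoid, tandem-ring,
multi-channel cylinder, tandem-with-needles), with dwell positions at the
0.25 cm source step. The HR-CTV is an ellipsoid centred on the applicator
with seeded jitter of its centre and semi-axis ratios, iteratively rescaled
until the voxelized volume is within 5% of the setpoint (exact volumes are
unattainable on a discrete grid). The default setpoint of 52.65 cm³ and the
supported 36–80 cm³ range reflect typical cervix HR-CTV volumes. Bladder,
rectum and sigmoid are ellipsoids placed anterior, posterior and superior
at a 0.3 cm surface margin — close enough that their 4.5 Gy maximum-dose
objectives engage during optimization (an optimization test is only
informative if the constraints bind) — and are clipped against the target
so the masks never overlap. Generation is a pure function of the
`phantom_spec`, so every downstream artifact is reproducible.

What the phantoms deliberately do **not** emulate: vendor-accurate
applicator curvature, real patient anatomy (only volume scale), contour
(mesh) geometry, inter-fraction motion. Passing tests on these phantoms
demonstrate correctness of the dose model, objective, optimizer and
metrics — not clinical plan quality on real anatomies, which depends on
per-patient geometry this generator cannot reconstruct.

## Problem sizes and sampling

The canonical regression case (`make_regression_case()`) uses the clinical
0.1 cm grid (~53 000 target voxels plus three OARs, 27 dwell positions) and
a seeded uniform 10% subsample of calculation points per ROI, giving about
10 000 points. Percent-based DVH metrics are invariant under uniform
subsampling; for absolute-volume metrics each sampled point carries the
volume it represents (`voxel_volume / fraction`, up to rounding), so
$D_{z\mathrm{cc}}$ still refers to the full ROI volume. With `fraction = 1`
sampling is exhaustive and seed-independent. The unit-test suite runs most
cases on a coarser 0.2–0.25 cm grid; the acceptance checks use the
regression case as stated.

## Degenerate inputs and edge behavior

* Empty ROI masks, mixed grids, mismatched time-vector lengths and
  non-finite coordinates raise categorized input/config errors (mapped to
  distinct exit codes by the CLI wrapper).
* A plan whose target $D_{90\%}$ is zero cannot be normalized and raises a
  degenerate-plan error.
* Calculation points coincident with a dwell position are finite by the
  near-source clamp.
* $D_{z\mathrm{cc}}$ demands $0 < z \le$ ROI volume; the quality report
  silently omits volumes exceeding a small OAR rather than failing.

## Known limitations

* 1D TG-43 only: no $F(r, \theta)$, line-source geometry factor, scatter or
  heterogeneity corrections, or source decay.
* Dwell positions are inputs; the package does not activate/deactivate
  positions from a reference target the way simulated-annealing planners do.
* The DTMF scale is tied to the dwell-time unit (seconds) and objective
  weights; its absolute values are not transferable across planners or
  disease sites, only the shape of the DTMF–DTSD trade-off is.
* Single-CPU dense kernel; fine for desk-scale phantoms (seconds per
  optimization), not tuned for full clinical grids without subsampling.
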