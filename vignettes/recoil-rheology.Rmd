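---
title: "Kelvin-Voigt rheology of laser-ablation recoil: models, estimators and synthetic benchmarks"
author: "kvrecoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kelvin-Voigt rheology of laser-ablation recoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvrecoil)
```

## The physical model

When a pulsed laser cuts a few cells in a stressed epithelium, the
surrounding tissue recoils. `kvrecoil` describes that recoil with a
zero-dimensional viscoelastic circuit: the ablated cell patch is a spring of
stiffness $k$ in series with two Kelvin-Voigt elements (spring $k_f$ with
dashpot $\eta_f$; spring $k_s$ with dashpot $\eta_s$), all under a constant
tissue stress $\sigma$. Cutting removes the spring $k$; force balance on each
element then gives the bond displacement

$$\Delta x(t) = X_f\left(1 - e^{-t/\tau_f}\right) +
               X_s\left(1 - e^{-t/\tau_s}\right),$$

with $X_{f,s} = \sigma\kappa/k_{f,s}$, $\tau_{f,s} = \eta_{f,s}/k_{f,s}$,
$\kappa = k/(k+\bar k)$ and $\bar k = k_f k_s/(k_f + k_s)$. Only the four
observables $(X_f, X_s, \tau_f, \tau_s)$ are identifiable from a trace; the
five mechanical constants are constrained but not unique, which is why the
package never inverts for them (`relaxation_from_mechanics()` maps forward
only). The interpretation of the two modes: the fast, sub-second mode is
dominated by the ablated cell's own cortex and adhesion machinery, the slow
mode (tens of seconds) by the collective response of the surrounding cell
network.

Because no imaging is possible while the cutting laser fires, the first
$\delta t = 0.65$ s after ablation are unobserved. Three consequences run
through the whole package:

* the **initial recoil velocity** $v = \Delta x(\delta t)/\delta t$ is
  measured from the membrane displacement across the dark gap;
* with $\tau_f \approx \delta t$, about $1 - e^{-1} \approx 63\%$ of $X_f$
  but only $\sim 3\%$ of $X_s$ has relaxed at first observation, so $v$ is a
  proxy for the fast mode (with mid-range displacements, the fast mode
  carries $\gtrsim 80\%$ of $v$, `fast_fraction()`);
* every trace keeps `delta_t` as metadata, and all model evaluations use
  $t + \delta t$, so the fast timescale remains estimable even though its
  relaxation is mostly hidden in the gap.

## Fitting: `fit_relaxation()`

The estimator is bounded nonlinear least squares (Levenberg-Marquardt, all
parameters positive). Initialization is deterministic and data-driven: the
long-time displacement is estimated from the mean of the last 10% of samples
(traces should span a few $\tau_s$; the generators default to 60 s);
$\tau_s$ starts at the time to 80% of it, $\tau_f$ at the time of the first
sample at or above 30% of it, and $X_f{:}X_s$ at 20:80. A second
deterministic start places the fast mode inside the gap
($X_f^{(0)} = 0.8\,y_1$, $\tau_f^{(0)} = \delta t$); the lower-RSS solution
wins. The second start exists because the first one, alone, can slide into a
$\tau_f \to 0$ local minimum on image-derived traces whose first few points
carry a small tracking bias — with both starts, recovery is accurate across
all benchmarked conditions. No random restarts are used, so a fit is a pure
function of its trace.

Numerical conventions: the model is exchange-symmetric in its two modes, so
fitted parameters are canonically ordered $\tau_f \le \tau_s$; fits whose
timescales agree within 5% are flagged `effectively_single`; traces that
trend downward are flagged `degenerate`; non-convergence returns the best
iterate with `converged = FALSE` rather than an error.

`compare_exponential_orders()` selects between one and two modes with AICc
on Gaussian residuals — the small-sample correction matters because a second
mode adds two parameters that a short trace cannot always support. On
well-separated truths (paper-range parameters) order 2 wins; on
single-exponential or coincident-timescale truths order 1 wins.

## Kymograph analysis

`generate_kymograph()` renders the standard experimental readout: intensity
along a line perpendicular to the cut, one column per frame (0.09 s), with
two Gaussian membrane ridges whose separation follows $\Delta x(t)$ (split
symmetrically), a dark gap of 0.65 s, background noise and per-frame
amplitude jitter. Table-level acquisition parameters (0.2 um/px by default,
0.09 s frames, 0.65 s gap) are the generator defaults.

`preprocess_kymograph()` applies the conventional sigma = 1 px Gaussian blur.
Note that the blur is two-dimensional: it also mixes adjacent *frames*, so
tracked positions next to the gap inherit a small (sub-half-pixel) temporal
smoothing bias. This is a property of the standard preprocessing, not of the
tracker; on raw noiseless images the tracker is exact to machine precision.

`track_membranes()` replaces classifier-based segmentation with
deterministic ridge detection: per-frame local maxima above an Otsu
threshold, sub-pixel refinement by a parabola through the *log* intensity
(exact for Gaussian ridges, which stay Gaussian under Gaussian blur), and
nearest-neighbour continuity linking. Frames with fewer than two ridges are
interpolated and flagged; more than 30% flagged frames, or membranes closer
than 2 px, abort. `extract_displacement_trace()` subtracts the pre-gap
baseline separation, and `recoil_velocity_from_kymograph()` measures the
across-gap displacement. One convention needs care: each membrane moves
$\Delta x/2$, so the mean per-membrane displacement is half the bond
displacement. The default (`bond_displacement = TRUE`) rescales by 2 so that
image-based and closed-form velocities agree; the raw per-membrane
convention is available.

Benchmarks (regenerated in the test suite and acceptance script): at noise
sd 0.05 the tracked separation has RMS error < 0.1 px, and the full
generate → blur → track → trace → fit pipeline recovers $X_s$ within 5%,
$\tau_s$ within 15% and $X_f + X_s$ within 5% on 50/50 seeded replicates.

## Cell elongation and coarse shear decomposition

The cell elongation nematic is
$\epsilon_{xx} = \frac{1}{A_c}\int\cos 2\phi\, dA$,
$\epsilon_{xy} = \frac{1}{A_c}\int\sin 2\phi\, dA$, with $\phi$ measured
about the cell centroid (the centroid is not stated everywhere the
definition is used, but it is the convention that makes the tensor
translation-invariant, and it is what `elongation_tensor()` uses). On the
centroid triangle fan the area integral of any function of $\phi$ alone
reduces per edge to $\tfrac{1}{2}(A \times B)\int_0^1 f(\phi(t))\,dt$ — a
smooth one-dimensional integral handled by adaptive quadrature — so convex
and star-shaped cells are integrated essentially exactly, with no
rasterization. $Q \equiv \epsilon_{xx}$ is the proximal-distal (PD)
component, with $x$ = proximal→distal and $y$ = anterior→posterior.
`mean_Q()` averages per cell (unweighted by default; area weighting is an
option because tissue-scale averaging conventions differ).

`align_to_peak()` defines the relative clock used for comparing specimens:
time zero is the vertex of a quadratic fitted over ±40 samples around the
absolute maximum of blade-mean elongation ("hours relative to peak cell
elongation", hRPCE). On an exact parabola the vertex is exact; with noise
sd 0.005 the median error is ~0.12 h. On a *skewed* bump the vertex carries
a deterministic bias toward the flatter side (~0.4 h for the generator's
5 h rise / 7 h decay) — the bias is identical for same-shaped series, so
relative alignment is unaffected, but the estimate should not be read as
the curve's true mode. Boundary maxima are fitted one-sided and flagged;
an upward-opening fit is an error.

`coarse_shear_decomposition()` is deliberately a two-way split: per
interval, total PD shear is the change of the region ellipse's log aspect,
$\Delta\,\tfrac{1}{2}\ln(L_{PD}/L_{AP})$ with $L$ the semi-axis lengths of
the area-normalized second-moment tensor (equivalently
$\tfrac14\Delta\ln(m_{xx}/m_{yy})$, using the signed axis components to stay
consistent with $Q = \epsilon_{xx}$); the cell-shape term is
$\Delta \bar Q$; and rearrangements are *defined* as the residual, so
closure is exact by construction. Semi-axis lengths (not raw eigenvalues)
are used because their log-aspect change equals $\Delta\bar Q$ under small
affine strain — with raw second-moment eigenvalues the "total" would be
twice the shape term and a pure affine deformation would spuriously appear
half rearrangement-driven. Neighbour exchanges, divisions, extrusions and
correlation terms are all absorbed into the residual; this is not the
triangle-method decomposition and is not meant to be.

## Group statistics and the subsampling power analysis

`dispatch_test()` reproduces the conventional gatekeeping: Shapiro-Wilk in
every group at $\alpha = 0.05$ (level unstated in common practice; 0.05 is
the default here), then Student's t / one-way ANOVA if all groups pass,
Mann-Whitney / Kruskal-Wallis if any fails (any single non-normal group is
enough — the conservative rule). All base tests come from `stats`; the
package's own content is the dispatch and the resampling.

`subsample_power()` repeats, `n_iter` times: draw $m$ values with
replacement from each genotype pool, run a tie-corrected Kruskal-Wallis
test, count $p \le \alpha$. `power_curve()` sweeps
$m \in \{3,\dots,10,20,40\}$ with 10,000 iterations by default. Two
honest caveats, both visible in the package's own numbers:

* for $m = 3$ per group the $\chi^2$ reference is discrete and
  conservative (fresh-draw null rejection ~2%); an exact-style permutation
  option (`method = "permutation"`) is provided for small $m$;
* the procedure resamples from *realized* pools, so its level under the
  null is only approximately $\alpha$: conditional on a pool whose group
  means differ by sampling luck the rate shifts by several points, and
  because power is convex in that imbalance the marginal rate sits slightly
  above $\alpha$ (~7% at $m = 10$ for these pool sizes). The acceptance
  script therefore reports the marginal rate over independent null pools.

`aspect_ratio()` is the major-to-minor axis ratio of the area-normalized
second-moment ellipse, computed exactly for polygon outlines and from pixel
moments for binary masks.

## The synthetic scenario

`genotype_scenario()` fixes the study conditions all generators draw from:

* wild-type recoil parameters as truncated normals centred in the measured
  bands — $X_f$: mean 2.2 um on [1.8, 2.6]; $X_s$: mean 7 um on [6, 8];
  $\tau_f$: mean 0.65 s; $\tau_s$: mean 20 s. Ranges are all the data
  constrain, so the truncated-normal shape is a stand-in.
* the *pk* genotype differs **only** in the fast mode: $k_f$ (and $\eta_f$
  with it, conserving $\tau_f$) scaled by 1.5, so $X_f$ shrinks by 1/1.5
  while everything else is distributionally identical.
* adult-wing aspect-ratio pools at the measured sizes (wt 53, pk 47,
  stbm 74, fmi 56), Gaussian with sd 0.05; pk and stbm shifted down by
  0.065 (a calibrated, arbitrary constant: it makes the full-pool
  Kruskal-Wallis significant in every tested seed while three wings per
  genotype detect the effect only ~15-20% of the time, the regime the
  power analysis is about). fmi matches wt.
* a blade-elongation time course sampled every 5 min: an asymmetric
  Gaussian bump peaking at 0.2 at 23 hAPF (5 h rise, 7 h decay), noise
  sd 0.005.

Gaussian noise everywhere is a modelling choice, not a measurement;
magnitudes were picked once to give parameter scatter of the same order as
published box plots. What passing tests on these synthetics demonstrate is
that the *estimators* are correct and well-calibrated under the stated
conditions; they say nothing about un-modelled features of real data —
drift, uneven illumination, segmentation errors, non-Gaussian outliers, or
biological correlation between specimens.

## Problem sizes and numerical tolerances

Defaults were chosen so the whole suite exercises realistic sizes quickly:
traces of ~660 samples (60 s at 0.09 s), kymographs of ~80 x 680 px,
100-cell meshes, 2,000-iteration power estimates in tests (10,000 is the
analysis default). Quadrature tolerance for the elongation tensor is 1e-7
per edge (tensor accurate to ~1e-5); the ODE cross-check of the closed form
uses a stiff solver at rtol 1e-10 and agrees to better than 1e-6 relative;
fit convergence tolerances are 1e-12 on both gradient and step.

## Known limitations

* The circuit is zero-dimensional: no spatial stress field, no inference of
  absolute moduli, and $\sigma$, $k$, $k_{f,s}$, $\eta_{f,s}$ are never
  reported individually from a fit.
* The membrane tracker assumes two dominant ridges; crossing membranes,
  strong photobleaching or drifting baselines are out of scope.
* The scripted neighbour-exchange program rearranges square cells
  geometrically rather than performing topological T1s on a shared vertex
  mesh — sufficient for exercising the decomposition's accounting, not a
  tissue simulation.
* Normalized stress inputs to `active_stress()` come from external
  measurements (e.g. circular-ablation ellipse fitting); that method's
  internals are outside this package.
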