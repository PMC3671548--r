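---
title: "Measuring the curvature of strongly bent bilayers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the curvature of strongly bent bilayers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcurv)
```

## The problem

Coarse-grained simulations of laterally asymmetric bilayers — for example a
DOPC/DOPS patch built from two inverted blocks — can relax into strongly
bent, meander-like shapes. Standard membrane-analysis tools assume a planar
bilayer with a global normal along Z, so none of their observables (leaflet
assignment, thickness, curvature) are defined once the membrane folds over.
`memcurv` analyses such membranes under one geometric assumption: the
membrane is significantly curved in the XZ plane and stays nearly planar
along Y (the simulation box is thin in Y). The bilayer shape is then a
closed plane curve — the *midline* — and every observable is built from it.

The pipeline has four stages, each exposed as ordinary functions:

1. **Leaflet assignment** (`assign_leaflets`). One headgroup marker bead per
   lipid (the coarse-grained phosphate bead, `PO4`, by default) is
   connected to every other marker closer than `r_p` (default 2.0 nm,
   minimum-image distance, strict `<`). A well-formed bilayer gives exactly
   two connected components — the monolayers. Any other count aborts with
   the component count in the error: a merged graph means `r_p` exceeds the
   inter-leaflet gap, a fragmented one means the membrane is torn or `r_p`
   is too small. This stage runs once per trajectory; labels propagate by
   molecule identity because lipids do not flip between leaflets on
   simulation timescales.
2. **Midline tracing** (`local_frame`, `trace_midline`). A local
   centre/normal probe is stepped tangentially around the membrane in
   increments of `s` (default 1 nm) until the trace closes on itself.
3. **Spectral curvature** (`midline_spectra`, `curvature_profile`). The
   midline coordinates `X(l)`, `Z(l)` are Fourier-transformed, low-pass
   filtered at `lambda_c` (default 15 nm), differentiated in the wavenumber
   domain, and combined into the signed parametric curvature
   \[ \kappa(l) = \frac{\dot X \ddot Z - \dot Z \ddot X}{(\dot X^2 + \dot Z^2)^{3/2}}. \]
4. **Statistics** (`curvature_distribution`, `free_energy_profile`,
   `partition_ratio`, `detect_flipflops`, `fit_double_exponential`).
   Curvature distributions conditioned on cholesterol location and domain
   residence, Boltzmann-inversion free energies at `T` = 320 K, the
   DOPC/DOPS partition ratio, and cholesterol flip-flop kinetics.

## The local centre/normal probe

`local_frame(p)` must return a bilayer centre and an upper-pointing normal
for any point near the membrane. Our construction:

* Select, per leaflet, the markers inside a cylinder of radius `r_loc`
  (default 3.0 nm) whose axis passes through `p` along the current normal
  estimate. During tracing the previous step's normal orients the
  cylinder; for a cold start the direction is bootstrapped from marker
  patches anchored at each leaflet's nearest marker to `p`.
* Weight the markers by a Hann taper in lateral distance,
  `cos^2(pi d/(2 r_loc))`. With hard-edged selection the centroid jumps
  whenever a marker crosses the boundary; on a discrete marker lattice
  those jumps put spurious jitter into the midline parameterization. The
  taper makes the centroid a smooth function of `p`.
* The **centre** is the midpoint of the two per-leaflet weighted
  centroids. Because the leaflet shells sit at ±h/2 along the normal, any
  tilt of the selection axis shifts the two centroids by equal and
  opposite tangential amounts, which cancel in the midpoint — the centre
  is robust to an imperfect axis.
* The **normal** is *not* the inter-centroid direction: that direction
  inherits an axis tilt one-for-one (the two shifted windows reproduce the
  tilt), so a trace using it accumulates orientation error with no
  restoring force. Instead the tangent is taken as the principal XZ
  direction (weighted PCA) of the leaflet-centred marker displacements —
  a direction estimate independent of the window orientation — and the
  normal is its perpendicular, signed to point from the lower to the upper
  centroid.

With at least 3 markers per leaflet required in the window, the probe
errors out (carrying the counts) rather than extrapolating.

On the synthetic sinusoid benchmark (amplitude 5 nm, wavelength 50 nm,
bead noise 0.1 nm) this probe keeps the traced arc length within 0.3% of
the analytic value and the filtered curvature within ~4% RMS of the closed
form; the literal "hard cylinder + inter-centroid normal" construction
gives ~12% RMS and a 3% length bias, which is why we deviated from it.

## Tracing and termination

The trace starts at the marker of the lipid with the lowest molecule id
(deterministic), computes the first centre/normal, and repeatedly steps
\( t_k = (n_k \times \hat j)/\lVert n_k \times \hat j\rVert \cdot s \)
— the tangent is the cross product of the local normal with the Y unit
vector — then refines the predicted point with one `local_frame` call. The
tangent sign is chosen so the first step advances in +X and is kept by
continuity (`t_{k+1} · t_k > 0`), which protects vertical membrane
segments from direction flips. Tracing stops when the refined point lands
within `s` of the first point after at least two steps.

One subtlety: appending that final near-coincident point would give the
stored midline a duplicated seam point, and the downstream FFT assumes
uniformly spaced arc samples `l_i = i s` — a duplicated seam produces a
sawtooth parameterization error that rings through the spectra. We
therefore stop *without* storing the closing point: the stored points are
uniformly spaced everywhere including across the seam (gap between s/2 and
3s/2), and the termination distance is reported as `closure_distance`
(always < `s` for a closed trace).

## Spectral differentiation choices

* `X(l)` winds once around the periodic box per loop. The series is
  unwrapped (minimum-image increments), the integer winding is separated
  as a linear trend, and only the periodic residual is transformed. The
  trend re-enters the first derivative as a constant slope.
* Wavelengths are `lambda_k = N s / k` (folded index); filtering zeroes
  all components with `lambda <= lambda_c`, keeping the DC term and trend.
  The hard cutoff (no taper) is a projection — applying it twice equals
  applying it once — and its derivative operator is `i 2\pi/\lambda` per
  component (the Nyquist component's first derivative is set to zero, the
  standard convention for even N). The 2π factor is validated by a circle
  oracle: a circle of radius R fed through the pipeline must return
  |kappa| = 1/R, which fails by (2π)² under the alternative reading.
* `mean_curvature` averages |κ|: the signed mean over a closed meander is
  near zero by periodicity and carries no shape information, whereas the
  magnitude mean reproduces the circle relation mean|κ| = 1/R (16.7 nm ↔
  0.06 nm⁻¹) that anchors the equilibrium mean-curvature scale.

The cutoff `lambda_c` trades noise suppression against shape fidelity, and
the default 15 nm is tuned for membranes whose curvature lives at
wavelengths ≥ 30 nm. The bias is *method-inherent*: for a sinusoid of
amplitude 2 nm and wavelength 30 nm the third arc-length harmonic of
`Z(l)` (wavelength ≈ 10.4 nm) is genuine signal carrying ~8% of the
curvature RMS, and the 15 nm cutoff removes it no matter how accurately
the midline is traced. Users analysing sharply kinked membranes should
lower `lambda_c` and accept more noise.

## Cholesterol statistics

Cholesterol residence (leaflet, lipid domain) is the leaflet and lipid
type of the nearest lipid marker to the cholesterol head bead (`ROH`),
with exact ties broken toward the lowest molecule id. A distance-to-midline
sign test would give the leaflet but not the domain; the nearest-marker
rule yields both in one deterministic step.

Curvature distributions are histograms of |κ| (bin width 0.0085 nm⁻¹ by
default), density-normalized. Free-energy profiles are computed by
Boltzmann inversion, `E(κ) = -k_B T ln(P_a/P_b)` at `T` = 320 K, reported
in units of k_BT (and Joules). Bins where either distribution holds fewer
than `n_min` = 10 samples are masked rather than extrapolated — empty-bin
ratios are unbounded and any smooth continuation there would be invention,
not measurement. The partition ratio `r_DOPC/DOPS` uses pooled counts over
frames (sum counts, then one ratio), which stays defined when individual
frames have empty domains; the mean-of-ratios alternative differs on
unbalanced frames and is not used.

## Flip-flop kinetics

A flip-flop event requires **both** the leaflet and the lipid-domain type
of a cholesterol to change between consecutive frames. Requiring the
domain change discards regions where the same lipid type faces itself
across the bilayer (there a leaflet change is geometrically ambiguous).
Frames must be uniformly spaced.

Inter-event intervals are pooled over molecules into a histogram and
fitted with a double exponential `A1 exp(-t/t1) + A2 exp(-t/t2)` by
weighted nonlinear least squares (Poisson weights `1/max(count, 1)`;
Levenberg–Marquardt refinement of a log-spaced grid search with linearly
solved amplitudes; `t1 <= t2` by convention). Because binning an
exponential preserves its exponential form exactly (the integral over a
bin is proportional to the value at the bin centre), the histogram fit is
unbiased for the time constants regardless of bin width.

Two diagnostics accompany every fit. A single-exponential model is fitted
alongside and compared by AIC, flagging data that do not support two
timescales (`t2/t1 < 2` is additionally flagged as degenerate). And when
the fitted `t1` falls within 25% of the frame spacing the result is
flagged as the frame-rate oscillation artifact: a cholesterol lingering at
the bilayer centre can appear to hop leaflets on consecutive frames
without a genuine translocation, contributing a spurious fast component
whose time constant equals the sampling interval; only `t2` should then be
read as the physical flip-flop time. Debouncing (discarding event pairs
that revert within a window) is available but **off** by default, so the
raw frame-to-frame detection rule is reported unless the caller opts in.
An interval-level maximum-likelihood fit (`fit_interval_mle`) serves as an
independent cross-check of the histogram fit.

## The synthetic generator

`generate_membrane` builds frames whose ground truth is analytic: a
prescribed midline curve (flat, sinusoid, Fourier series, or circle),
leaflet marker shells offset ±h/2 (default 2.0 nm) along the *local
analytic normal* — a vertical offset would thin the bilayer on curved
segments and break the probe's geometry — block lipid domains with the
two-block inverted layout between leaflets, cholesterol head beads planted
at known (leaflet, domain, curve parameter) positions just inside their
leaflet shell, and isotropic Gaussian bead noise (default σ = 0.1 nm,
small against both `r_p` and the bilayer half-thickness). Markers are
placed at equal arc-length spacing so the surface density is uniform along
curved and flat segments alike, with spacing ≈ 0.8 nm chosen to match the
headgroup spacing implied by coarse-grained areas per lipid (~0.64 nm²).

The `"paper"` preset reproduces the reference system scale: 4032 lipids
(2016 DOPC + 2016 DOPS), 784 cholesterol (cholesterol/lipid ≈ 0.2), on a
111 × 12.4 nm patch, bent into a two-period sinusoid of 6 nm amplitude as
a stand-in for the equilibrium meander. Its cholesterol placement odds
between DOPC and DOPS domains default to 0.65:1 — the equilibrium
preference reported for this lipid pair — so the residence pipeline can be
validated against a known planted ratio. `generate_trajectory` keeps
molecule identity across frames, morphs the curve per frame (e.g. an
amplitude ramp emulating progressive bending), and applies a planted
flip-flop schedule whose countable events are exported as ground truth.
`generate_intervals` draws seeded exponential-mixture interval samples for
the kinetics fit.

What the generator does **not** emulate: thermal undulations with a
physical spectrum (noise is white), lipid tilt and per-leaflet thickness
fluctuations, lateral diffusion, genuinely meandering (non-graph) shapes,
and any force-field physics. Passing the synthetic tests therefore
validates the *geometry and statistics* of the pipeline — leaflet
partitioning, trace accuracy, spectral differentiation, estimator
correctness — not the biological conclusions one would draw from real
trajectories.

## Numerical choices and degenerate inputs

* Distances use the minimum-image convention per periodic axis throughout;
  the graph cutoff comparison is strict (`< r_p`) so results are
  reproducible at the boundary.
* "Upper" vs "lower" labels: the component whose markers sit on average at
  +Z of their nearest counterpart in the other component is upper; for
  closed membranes (a vesicle cross-section) where that signal cancels,
  the radially outer component is upper. Labels are assigned once and
  propagated by molecule identity.
* Exact nearest-neighbour ties (constructed inputs) resolve to the lowest
  molecule id or lowest index — documented, deterministic.
* `curvature_profile` refuses midlines whose parameterization speed
  vanishes (`\dot X^2 + \dot Z^2 < 10^{-12}`); `midline_spectra` requires
  N ≥ 8; `unwrap_periodic` rejects jumps of half a box length as
  ambiguous.
* Problem sizes in the test-suite and acceptance script: full-scale
  composition checks run on the 4032-lipid preset; trace and curvature
  benchmarks on ~1700-marker membranes; free-energy recovery on 10⁶
  draws; kinetics recovery on 2×10⁵ intervals. These sizes give
  statistical errors comfortably below the assertion tolerances while
  keeping a complete run in tens of seconds.

## Known limitations

* The XZ-curve assumption is not checked: a membrane with structure along
  Y violates the model silently. Callers must ensure the thin-Y geometry.
* The trace cannot follow membranes whose local radius of curvature
  approaches the bilayer half-thickness, nor pass through self-contacts.
* The hard spectral cutoff biases curvature of shapes with genuine
  sub-`lambda_c` structure (quantified above).
* The Eq-for-energy comparisons between a no-cholesterol and a cholesterol
  system use two different sampling rules (midline points vs cholesterol
  locations), matching the sampling rules the statistics are defined with; the asymmetry means the
  two distributions weight arc length differently wherever cholesterol
  density correlates with curvature.
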