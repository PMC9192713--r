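---
title: "Models and methods behind cortmag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortmag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices, and what the synthetic data do and do not emulate.

## Conventions

Polar angle is measured in degrees, counter-clockwise, with 0° at the right
horizontal meridian and 90° at the upper vertical meridian; x is positive
rightward and y positive upward, both in degrees of visual angle. The left
hemisphere represents the right visual hemifield (angles in (−90°, 90°])
and the right hemisphere the left hemifield. The four measurement locations
are the left and right horizontal meridian and the upper and lower vertical
meridian (`cortmagLocations()`), all at 4.5° eccentricity in the
psychophysics and spanned by 1–8° wedges in the cortical analysis.

## The magnification model and the synthetic cortex

Areal cortical magnification (mm² of cortex per deg² of visual field) is
modelled as

$$M(ecc, \theta) = M_0 \left(\frac{A}{ecc + e_2}\right)^2
  \big(1 + \alpha\cos 2\theta - \gamma\sin\theta\big).$$

The eccentricity term is the square of the classical inverse-linear
magnification; the defaults A = 17.3 mm and e₂ = 0.75° are the standard
human V1 estimates, which put the total simulated hemisphere area and V1
(0–8°) area in the physiological range (roughly 1.4 × 10³ mm² per
hemisphere for 0–8°). The angular term is the minimal two-harmonic
modulation with independent horizontal–vertical (α) and upper–lower (γ)
asymmetries. `solveAsymmetryAmplitudes()` inverts the closed-form wedge
integrals — the wedge mean of cos 2θ over ±15° is sin 30°/(π/6) ≈ 0.9549 —
so that a requested HVA/VMA of the ±15° wedge areas maps exactly onto
(α, γ).

`makeSyntheticHemisphere()` lays a log-spaced-eccentricity × uniform-angle
grid over the hemifield and maps it to flat cortical coordinates whose
radial component integrates the linear magnification and whose tangential
component is scaled by the local linear magnification times the integrated
angular modulation. The mapping's Jacobian is exactly M(ecc, θ)·ecc, so
triangle areas converge to the analytic sector integrals
(`analyticSectorArea()`) as the grid refines. Per-vertex areas are one
third of the incident triangle areas and therefore sum exactly to the mesh
area. Cortical depth (pial, white) is emulated by scaling coordinates by
√depthScale — the analysis only ever consumes vertex-area maps, and this
keeps the vertex-area/triangle-area invariant intact — not by remeshing or
folding.

The default resolution is 121 eccentricity rings × 91 angular spokes per
hemisphere (2° angular spacing). Two considerations fix it: spoke counts
are odd so that the cardinal meridians fall exactly on spoke lines (the
meridian line-ROIs are then well defined), and at 2° spacing the wedge-ROI
areas sit within about 1% of the analytic integrals, comfortably inside
the 3% oracle band used in the tests. Discretization error is not monotone
across arbitrary grid sizes (boundary vertices alias in and out of the
wedge), so convergence is checked on a spacing-halving ladder
(31×21 → 61×45 → 121×91).

## The pRF stimulus and model

`makeBarAperture()` reproduces the standard sweeping-bar mapping stimulus:
a circular aperture of radius 12.4°, a bar 1/8 of the stimulus extent wide
(3.1°), 24 one-second steps per sweep, eight sweeps alternating cardinal
and diagonal, with the second half of each diagonal sweep blank — 192
frames in all. The exact sweep order is not constrained by the analysis
(the fit sees the whole design matrix), so a fixed default order is used
and generation is fully deterministic. Only the binary contrast aperture
enters the model; carrier textures and the fixation task are irrelevant to
the forward model and are not rendered. Pixels are rasterized by the
pixel-centre rule at a default 64×64 grid (0.39°/pixel; the bar is 8
pixels wide), which keeps the fit fast while resolving the bar.

The forward model multiplies a circular 2D Gaussian (centre x, y; SD σ)
pointwise with each aperture frame, sums over pixels, and convolves with a
five-parameter double-gamma HRF (delays 6 and 16 s, unit dispersions,
peak:undershoot ratio 6, unit-peak normalized; its positive lobe peaks
near 5 s). The HRF is held fixed during fitting and exposed as a
parameter; per-vertex HRF estimation is out of scope.

`fitPRF()` is coarse-to-fine: an exhaustive first stage over log-spaced
eccentricities × 16 angles × log-spaced σ (0.25–6°) with the gain fitted
by non-negative least squares on mean-removed series, then a continuous
second stage (Nelder–Mead on (x, y, log σ), relative tolerance 1e-10, with
a BFGS polish) started from the two best grid candidates; the better final
residual wins. Two starts guard against the occasional local minimum that
a single simplex run falls into. Negative gains are rejected (clamped to
zero) because the model assumes aperture-driven positive responses. R² is
1 − RSS/TSS on the mean-removed series, making it invariant to affine
rescaling, and vertices enter downstream analyses only when R² > 0.10.
Flat series are excluded with R² = 0.

## Wedge-ROIs

The wedge construction mirrors the distance-map procedure used on real
cortical surfaces. Meridian line-ROIs — drawn by hand on real data — are
replaced by an automated surrogate: inclusion-gated vertices within a small
angular tolerance of the meridian, thinned to one vertex per
log-eccentricity bin. Geodesic distance from the line is multi-source
shortest path along mesh edges (igraph), which is deterministic and
accurate to one edge length — below the pooling variability; an exact
polyhedral geodesic could be substituted behind the same interface. Within
each of 10 log-spaced eccentricity bands between 1° and 8° (log spacing is
approximately equispaced on the cortex), the 15° boundary distance is the
mean distance of included vertices whose pRF angle offset lies in
15° ± 8°; the pooling band is symmetric in angle about the boundary. If a
pool is empty it is widened once by +4°; a band still empty is excluded
from the union rather than silently interpolated, which would bias areas.
Band membership uses each vertex's pRF eccentricity (ground truth in
synthetic tests, fitted values otherwise). The V1-size measurement spans
0–8° while wedges span 1–8° (the central degree is excluded from wedges
because polar-angle estimates are noisy near the fovea); both limits are
parameters.

Vertical-meridian wedges take 15° from each hemisphere; the upper and
lower wedge areas are each the sum of their two hemifield halves, the
horizontal meridian sums the left- and right-hemisphere wedges, and the
full vertical meridian is UVM + LVM.

## Psychophysics

Observers are Weibull 2AFC observers,
p(c) = guess + (1 − guess − lapse)·(1 − exp(−(c/λ)^slope)), with guess
0.5, lapse 0.01 and slope 3.5 — a typical contrast psychometric slope —
and λ solved per location so that p(threshold) equals the 3-down-1-up
convergence accuracy. That accuracy is
the balance point of the up/down rule, p³ = 0.5, i.e. 0.5^(1/3) ≈ 79.4%
correct, which ties the generator's thresholds to what the staircase
estimates.

Each 200-trial block interleaves four 3-down-1-up staircases (one per
location, 50 trials each) in a seeded random order. Step-size adaptation
follows classical PEST on log10 contrast: initial level 0.5, initial step
0.3, step halves at each reversal, doubles on the third consecutive
same-direction step (delayed one step when the run follows a reversal that
was preceded by a doubling), bounded to [0.01, 0.6] log units; contrast is
clamped to [0.001, 1]. The published protocol names PEST without printing
constants, so these classical defaults are parameters. The threshold
read-out is the mean log contrast at the last six reversals (final level
if fewer occurred) — the standard reversal-averaging convention — and
per-location thresholds are averaged over five independent blocks before
taking reciprocals to get sensitivity. Fixation breaks and aborted trials
are not simulated; trial counts are exact by construction.

A known consequence of this protocol, quantified in the test suite: a
50-trial staircase yields a log-threshold SD of roughly 0.29, because
about a third of blocks end with seven or fewer reversals so the last-six
window reaches into the large-step transient; five-block averaging brings
the per-location error to about 0.12 log units while remaining essentially
unbiased (within ±5% of the true threshold). This measurement noise
attenuates near-ceiling pooled rank correlations between measured
sensitivity and surface area by roughly 0.07–0.08 relative to the planted
values — visible in the end-to-end recovery checks, where the measured
pooled ρ sits slightly more than 0.1 below a planted ρ of ≈0.99.

## The cohort generator

`makeCohort()` plants, per observer: a log-normal V1 size whose ±2 SD
range spans the requested fold-change (default twofold, around a 2500 mm²
both-hemisphere 0–8° mean); wedge areas equal to the observer's V1 share
times meridian modulations realizing the requested surface-area HVA/VMA
(defaults 60/25 index points); and contrast sensitivities (default mean
50, i.e. 2% thresholds) linked to the corresponding wedge area. The link
blends, in log space, a power law of wedge area with an independent
component (its own location effects realizing the requested CS HVA/VMA of
50/20, and an independent observer factor), weighted by `coupling`. At
coupling = 1 and zero noise, sensitivity is an exact monotone function of
wedge area, so the pooled Spearman correlation is exactly 1; at
coupling = 0 sensitivity carries no observer-level association with the
areas. The power-law exponent is solved from the SA and CS HVA targets,
which makes the CS VMA at full coupling a derived quantity (≈20.7 rather
than 20 with the default targets) — one of the two CS asymmetries cannot
be planted independently once sensitivity is forced to be a function of
area. Multiplicative log-normal noise (default SD 0.05, a realistic
repeatability level for such measurements) doubles as true individual
variation in the asymmetries: without it all observers share identical
asymmetry indices and split-half reliability is undefined.

What the generator does **not** emulate: anatomically realistic folding,
physiological BOLD noise structure (noise is i.i.d. Gaussian), eye
movements, lapses of attention beyond a constant lapse rate, or any
retinal/geniculate contribution to the asymmetries. Passing tests
therefore show that the analysis code recovers what it assumes — planted
monotone structure under these idealized conditions — not that the
biological claims hold in real data.

## Statistics

The asymmetry indices are difference-over-mean percentages: HVA =
100·(H − V)/mean(H, V) with sensitivities averaged (and areas summed) over
the left/right horizontal and upper/lower vertical locations; VMA is the
same form on (lower, upper). Both are antisymmetric and scale-invariant.

Brain–behaviour associations use Spearman's ρ, one-tailed for a positive
monotonic association (average ranks for ties; exact p below n = 10
without ties). The pooled correlation treats all observer × location pairs
as points. Two permutation nulls decompose it: shuffling which observer's
sensitivity quadruple is paired with which observer's area quadruple
(location ties preserved) removes between-observer structure, and
shuffling location labels within each observer removes the shared location
structure; each null is summarized by the 95th percentile (x₀.₉₅, linear
interpolation between order statistics) of 10,000 (default; tests use
1,000) re-computed correlations, with a fresh random permutation drawn
every iteration. Observer/location centring (`centerData`) provides the
complementary decomposition view. Group-level comparisons use paired t
tests with Cohen's d = mean(diff)/sd(diff).

## Reproducibility and problem sizes

All randomness flows from one root seed through named child streams
(mesh jitter, cohort, BOLD noise, blocks, nulls), so every stage is
independently reproducible and whole-pipeline reports are byte-identical
under a fixed seed. The test suite runs at deliberately modest sizes — the
default 121×91 meshes, 64×64 stimulus grids, 500-vertex recovery sets,
29-observer cohorts, 1,000-iteration nulls, and 50-replicate recovery
loops — chosen so the full suite exercises every stage at sizes where the
oracles (closed-form integrals, quadrature, brute-force rank computation,
hand-traced staircases) are exact or near-exact.

## Known limitations

- The flat synthetic cortex has no folding, so geodesic and Euclidean
  distances nearly coincide; the distance-map code is exercised, but not
  stressed, by this geometry.
- The pRF fit assumes the generating model (no compressive spatial
  summation, fixed HRF); model mismatch is not simulated.
- The staircase threshold estimator's variance at 50 trials per staircase
  is substantial (see above); analyses that need tighter individual
  estimates should raise the trial or block count in the configuration.
- `combineMeridianAreas()` assumes both hemispheres are present; partial
  acquisitions are rejected rather than imputed.
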