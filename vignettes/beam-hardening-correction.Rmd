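---
title: "Segmentation-based beam-hardening correction for dark-field chest radiography: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-hardening correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfbhc)
```

## The signal model

A Talbot–Lau interferometer delivers two perfectly registered images per
scan: the attenuation radiograph and the dark-field radiograph. For a
polychromatic effective source spectrum $S_0(E)$ (tube spectrum times
detector response) and transmitted spectrum
$S(E) = S_0(E)\,e^{-\mu_w(E)t_w - \mu_{Al}(E)t_{Al}}$, the measured signals
are

$$A_p = -\ln\frac{\int S\,dE}{\int S_0\,dE},\qquad
  V_p = \frac{\int V_0(E)\,S\,dE}{\int S\,dE},\qquad
  D_p = -\ln\frac{V_p}{V_{0,p}}.$$

For a *purely absorbing* object, $D_p$ should be zero — but it is not,
because absorption hardens the spectrum and $V_0(E)$ is energy dependent.
This **beam-hardening-induced dark-field signal** $D_p^{BH}$ is an artifact:
it is strongest under ribs and clavicles and contaminates the lung signal.
True microstructural scatter composes multiplicatively with the hardened
visibility ($V_{\text{sample}} = V_p^{BH} e^{-D_{\text{true}}}$), hence
additively in the log domain: $D_p = D_p^{BH} + D_{\text{true}}$.

The correction estimates $D_p^{BH}$ from the attenuation image alone. Two
calibration curves, simulated by sweeping pure water (0–40 cm, step 0.5 cm)
and pure aluminum (0–8 cm, step 0.1 cm) through the forward model, give
monotone maps $A_p \mapsto D_p^{BH}$ per material. At each pixel the two
table values are blended with an anatomically resolved aluminum contribution
weight $\omega_{Al}(x,y)$ and its water complement
$\omega_{H_2O} = 1 - \omega_{Al}$, and the blend is subtracted from the
measured dark-field image.

Assumptions worth keeping in mind:

* a two-material world: everything in the beam is a water/aluminum mixture;
  metal implants and contrast agents are outside the model;
* per-pixel line integrals (parallel projection); no scatter, divergence or
  focal-spot blur;
* $\omega_{Al}$ is a *population-level prior* painted onto segmentation
  masks, not a per-patient measurement.

## Spectral components and their parameters

| parameter | default | units | role |
|---|---|---|---|
| `kvp` | 70 | kV | tube voltage; spectrum endpoint |
| `prefiltration_mm_al` | 2.5 | mm | aluminum-equivalent beam filtration |
| `energy_min/max/step` | 10 / 70 / 0.5 | keV | trapezoid integration grid |
| `v0_model$v_max` | 0.35 | — | peak reference visibility |
| `v0_model$design_energy_kev` | 27 | keV | interferometer design energy |
| `v0_model$slope_per_kev` | 0.02 | 1/keV | visibility decay above design energy |
| `c_d` | 1 | — | setup constant scaling the scatter line integral |

The tube spectrum is a Kramers-form bremsstrahlung continuum,
$(\mathrm{kvp}-E)/E$, shaped by Beer–Lambert transmission through the
prefiltration; characteristic lines are omitted. This is a deliberate
minimal model: it is smooth, parameter-free beyond the two quantities above,
and produces realistic hardening. Any tabulated spectrum can be substituted
through the `spectrum()` constructor, and a tabulated detector response can
be folded in via `detector = list(type = "table", ...)`. The default
response is flat; we chose not to embed a scintillator absorption model
because no tabulation we would be willing to stand behind ships with the
package, and the correction itself is agnostic to where the effective
spectrum comes from.

The reference visibility $V_0(E)$ of a clinical interferometer is device
specific and not publicly available, so the package uses a parametric
stand-in: constant $v_{max}$ below the design energy, exponential decay
above it, clipped to $[0,1]$. Any monotone non-increasing $V_0(E)$ makes
$D_p^{BH}$ non-negative and monotone in material thickness — the behaviour
seen clinically (positive rib artifacts). Quantitative results on real
devices require the device's measured $V_0(E)$; with the stand-in, artifact
*magnitudes* (here ~0.2–0.3 at 20 cm water equivalent) are plausible but not
device-calibrated.

Attenuation coefficients for water and aluminum over 10–200 keV are embedded
as standard reference tabulations and interpolated log–log (both materials
are edge-free in this range). The table extends to 200 keV so that
mono-energetic image pairs at the conventional 50/200 keV choice can be
decomposed.

## Look-up tables: numerical choices

Calibration knots are interpolated with the monotone shape-preserving
Fritsch–Carlson cubic (`splinefun(method = "monoH.FC")`). A plain cubic
spline overshoots near the steep low-$A_p$ region; the monotone cubic
reproduces knots exactly and stays within bracketing knot values, which the
test suite asserts. With the default 0.5 cm water grid the interpolation
error against the exact forward model stays below $3\times10^{-5}$ in
$D_p^{BH}$, comfortably inside the $10^{-3}$ correction-residual budget.

Out-of-range attenuations (metal, collimator edges) are **clamped** to the
end knots by default, with a classed warning; linear extrapolation is
available but never silent. Clamping keeps pathological pixels from
producing runaway corrections.

## From masks to contribution maps

The splitting of each rib into posterior and anterior components follows the
projection anatomy: in a posterior–anterior radiograph a rib crosses the
lateral lung outline near the point where its posterior (superior) and
anterior (inferior) segments meet. Per image column, the boundary row is the
median row of the rib's overlap with the inner lung-boundary band; columns
without overlap inherit the nearest computed boundary; ribs that never touch
the lung outline fall back to a centroid rule (whole rib posterior if its
centroid lies above the lung centroid). The median-row rule is a choice —
nothing in the projection geometry dictates an exact interpolation scheme —
and it is robust to ragged mask borders.

Weights are painted by region (Table: posterior 0.15, anterior 0.10,
clavicle 0.20, edge 0.05, background 0.05 for male anatomy; 0.10/0.05
posterior/anterior for female), overlaps resolved by **maximum**. Maximum
rather than addition keeps interior weights exact where regions abut (a
clavicle bordering a rib stays at the clavicle level). Bone edges are
extracted with a Sobel filter on the binary masks, dilated by 2 px
(configurable) and composed with the same maximum. Edges are incorporated
*before* Gaussian smoothing; the reverse order would smear the regional
plateaus before the edge band is known. Smoothing (σ = 2.2 px, truncated at
3σ, replicate borders) produces the gradual transitions the subtraction
needs to avoid ringing at mask borders; the water complement is taken *after*
smoothing, so $\omega_{Al} + \omega_{H_2O} = 1$ holds exactly on the output
by construction.

The background weight of 0.05 is applied to the whole image rather than only
between ribs: at extra-thoracic attenuations the LUT values are near zero,
so the simplification is numerically irrelevant and removes a mask
dependency.

## The synthetic thorax phantom

The generator builds, per seed: an elliptical water torso (peak 22 cm water
equivalent), two lung ellipses (water path reduced up to 65%, constant true
dark-field 0.6 inside the lung), 8–10 rib pairs per side — each a "V" of a
near-horizontal posterior band and an oblique anterior band meeting at the
lateral lung boundary, 9 px wide — and clavicles above the apices. The seed
drives rib count, slopes and row jitter; everything else is deterministic.

Aluminum thicknesses are assigned so that the *true* aluminum
attenuation-contribution fraction of each region equals its configured
weight at the reference energy (the mean energy of the default spectrum,
37.5 keV). Soft tissue carries a true 0.05 background fraction — mirroring
the fact that a ~5% aluminum contribution is *measured* between ribs in
decomposed spectral CT of real patients (residual bone overlap, spine,
scapulae). Two consequences:

* profiling the phantom's decomposed maps re-derives the configured weight
  table from ground truth (tested to ±0.02);
* the default weights are exactly *matched* to the phantom, so correction
  residuals reflect the method (weighted-LUT linearization, smoothing
  transitions), not a deliberate weight mismatch. At the matched 5%
  background the weighted-sum linearization leaves residuals of at most
  ~$1.3\times10^{-3}$ at thoracic attenuations; a *truly pure* water pixel
  corrected with a 0.05 background weight would instead keep a ~$5\times
  10^{-3}$ residual, because the water and aluminum LUTs separate by ~0.1
  in $D_p^{BH}$ at $A_p \in [2,5]$.

What the phantom does **not** emulate: 3D anatomy and realistic projection
overlap (the mediastinum, scapulae and soft-tissue folds of real chests),
counting statistics and stepping-curve noise propagation (noise is additive
Gaussian on the two signal images), scatter, and anatomical variability of
bone density. Passing tests therefore demonstrate correctness of the
*pipeline* under its own assumptions, not clinical performance.

The phantom's rib cage is also intentionally crowded: posterior and anterior
bands of neighbouring ribs interleave with gaps smaller than the band
height, as they do in real radiographs. That is exactly the regime in which
classical single-element morphology cannot segment ribs — the package's
`tophat_segmenter()` (vertical-line grayscale opening plus a relative
contrast threshold) is demonstrated at Dice 1.0 on a flat-field slab phantom
whose assumptions it meets, and is documented as unsuitable for dense
anatomy, which is the reason the clinical pipeline uses a learned segmenter.
The segmenter *interface* (`segment_bones()`) is the extension point for
plugging one in; training parameters for such networks are documented
constants, not shipped models.

## Evaluation statistics

* **Coefficient of variation** uses the population convention (divide by
  $n$); a `variance = "sample"` switch exists. CV is scale invariant, so it
  measures lung-signal *homogeneity* independent of signal level.
* **Quartiles** use linear interpolation of the empirical CDF
  (`stats::quantile` type 7). The IQR-overlap statistic
  $\delta = \max(0, \min(Q_3^A, Q_3^B) - \max(Q_1^A, Q_1^B))$ inherits the
  convention; it is symmetric and zero for separated cohorts.
* The **Wilcoxon signed-rank test** drops zero differences (Pratt handling
  optional), uses midranks for ties, and computes the exact null
  distribution for up to 25 informative pairs by convolving the rank
  generating function (ties included exactly); beyond that, a normal
  approximation with tie and continuity correction. The two-sided exact p
  is twice the smaller tail, capped at 1. Under a symmetric null at
  $n = 20$ the exact rejection rate at $\alpha = 0.05$ is 0.0484 — the
  usual discreteness-induced conservatism.
* **Relative changes** are reported to one decimal with
  round-half-away-from-zero, the printed-table convention. Cohort summaries
  report both medians and means of pre/post metrics, because the two are
  easy to conflate when tables label one and prose the other.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data:
256×256 phantoms for end-to-end checks (20 seeds), 128×128 for unit
fixtures, 121-bin spectral grids, 10 000 replicates for the type-I-error
simulation. These sizes were chosen so the full pipeline on one phantom
(forward projection, calibration, correction, evaluation) completes in a few
seconds on a single core while leaving interpolation and discretization
errors far below the tolerances being asserted. Every stochastic stage
(phantom geometry, noise) is seeded; one seed governs a pipeline run and
derived per-stage seeds are deterministic, so re-running a configuration
reproduces outputs byte for byte.

## Known limitations

* The parametric $V_0(E)$ and the flat detector response are stand-ins; the
  package cannot validate against a specific clinical device without its
  measured visibility spectrum and response.
* The correction inherits segmentation quality: mask errors propagate into
  $\omega_{Al}$ and become local over- or under-correction. With σ = 2.2 px
  smoothing, weight transitions extend ~7 px, so structures thinner than
  ~2σ are under-corrected at their centers.
* The two most caudal ribs are excluded by default (mirroring their absence
  from the clinical training annotations); residual artifacts in the lower
  lobes are expected where they overlap lung.
* Metallic implants violate the two-material model and are clamped, not
  corrected.
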