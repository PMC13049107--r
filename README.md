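# dfbhc — beam-hardening correction for x-ray dark-field chest radiography

Grating-based (Talbot–Lau) dark-field radiography images ultra-small-angle
scattering from sub-resolution microstructure — in the chest, the millions of
air–tissue interfaces of the alveoli. The dark-field signal is encoded in the
loss of interferometer fringe visibility,

    Dp = -ln(Vp / V0,p),

and, like the attenuation signal `Ap = -ln(∫S dE / ∫S0 dE)`, is formed by a
*polychromatic* spectrum. Because the reference visibility `V0(E)` is energy
dependent, spectral beam hardening by strongly attenuating anatomy (ribs,
clavicles) shifts the transmitted spectrum and produces an **artificial
dark-field signal** `DpBH` that carries no microstructural information. It
appears as rib- and clavicle-shaped artifacts superimposed on the lung signal.

`dfbhc` implements a segmentation-based correction of this artifact:

1. **Per-material look-up tables.** Calibration sweeps of pure water and pure
   aluminum (surrogates for soft tissue and bone) through the spectral forward
   model give monotone tables `LUT_m : Ap → DpBH` for each material.
2. **Anatomically resolved weighting.** Rib and clavicle masks are split into
   posterior/anterior components at the lung boundary and painted with
   region-specific aluminum attenuation-contribution fractions (posterior rib
   0.15, anterior rib 0.10, clavicle 0.20, bone edges and background 0.05 for
   male anatomy; derived from two-material decomposition of spectral CT).
   Sobel-extracted bone edges are dilated and incorporated; the map is
   smoothed with a Gaussian kernel (σ = 2.2 px, truncated at 3σ) and
   complemented: `ω_H2O(x,y) = 1 − ω_Al(x,y)`.
3. **Pixel-wise weighted correction.**

       DpBH(x,y) = ω_Al(x,y)·LUT_Al(Ap(x,y)) + ω_H2O(x,y)·LUT_H2O(Ap(x,y))
       D̂p(x,y)  = Dp(x,y) − DpBH(x,y)

A spectral forward simulator (Kramers-form 70 kVp tube spectrum with 2.5 mm
aluminum-equivalent prefiltration, embedded reference attenuation tables, a
parametric reference-visibility model) and a synthetic thorax phantom with
ground-truth masks and lung dark-field make the whole pipeline testable
without clinical data. Evaluation statistics mirror the clinical analysis:
coefficient of variation of the lung signal, interquartile-range overlap
between cohorts, and an exact Wilcoxon signed-rank test.

The package is aimed at physicists and engineers working on dark-field
radiography systems and at methodologists who want a reproducible, fully
synthetic test bed for beam-hardening corrections.

## Worked example

```r
library(dfbhc)

ph   <- generate_phantom(seed = 7)          # synthetic thorax, ground truth attached
pair <- forward_project(ph)                 # registered Ap / Dp radiographs
luts <- calibrate_luts()                    # water + aluminum LUTs for the default setup
res  <- run_bhc(pair, ph$bone_masks, ph$weights, luts)

lung <- ph$lung_mask == 1
coefficient_of_variation(pair$darkfield[lung])   # before
coefficient_of_variation(res$corrected[lung])    # after
```

Output on this machine:

```
thorax phantom 256x256 (seed 7, male): 18 ribs, lung 18476 px, d_true max 0.6
lung CV before: 0.0404  after: 0.0056  (change -86.2%)
lung RMSE vs truth before: 0.1688  after: 0.0037
normalized lung signal before: 0.766  after: 0.602  (truth 0.600)
```

The uncorrected lung dark-field carries a large beam-hardening offset and
rib-structured variation (CV 0.040, RMSE 0.17 against the known true signal
of 0.6); after the weighted-LUT subtraction the lung signal returns to the
ground truth within ~0.004 and the residual variation drops by ~86%.

A full demo pipeline (simulate → calibrate → correct → evaluate, with TIFF,
CSV and provenance-JSON artifacts) runs from one configuration file:

```r
run_end_to_end(system.file("extdata", "demo-config.yaml", package = "dfbhc"),
               out_dir = "demo-out")
```

or from the shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","dfbhc.R",package="dfbhc"))')" \
    demo --out demo-out --seed 7
```

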