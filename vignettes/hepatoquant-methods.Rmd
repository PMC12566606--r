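---
title: "hepatoquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepatoquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the optical model, the segmentation and filtering rules, the statistics,
what the synthetic generator does and does not emulate, and the choices we
made where the methodology left the design open.

## 1. The optical model

Brightfield absorption stains obey the Beer–Lambert law: stain
contributions add in optical density (OD), not in intensity. We convert
8-bit intensities to OD per channel as

$$\mathrm{OD}_c = -\log_{10}\frac{I_c + 1}{I_{0,c} + 1},$$

clipped to $[0, \mathrm{od\_cap}]$. The $+1$ offset inside the logarithm
removes the $I = 0$ singularity without a special case; it shifts OD by at
most $\log_{10}(256/255) \approx 0.0017$ for bright pixels. The forward
renderer (`render_field()`) uses the exact inverse,
$I_c = (I_{0,c}+1)\,10^{-\mathrm{OD}_c} - 1$, so a noiseless rendered
field deconvolves back to its concentration maps at machine precision —
this identity is asserted in the test suite at $10^{-6}$. `od_cap`
defaults to 3 because below 0.1 % transmission an 8-bit sensor carries no
signal, only noise.

Deconvolution solves, per pixel, the linear system
$\mathrm{OD} = M^\top c$ where the rows of $M$ are unit-norm stain
vectors. We ship the standard published hematoxylin, eosin and DAB
vectors; since the slides of interest carry two stains, the third basis
vector is the orthogonal residual of the two named vectors (negatives
clamped to zero, renormalised), the usual convention for two-stain
deconvolution. Stain-vector estimation from real slides (Macenko-style) is
out of scope. Negative concentrations can arise from noise; they are kept
for diagnostics and clamped to zero only for area measurement, with the
clamping recorded in an attribute.

## 2. IHC percent positive area

The tissue region is delimited as pixels whose summed OD reaches
`od_min = 0.15` (about half the OD of the faintest plausible hematoxylin
counterstain), then regularised by morphological closing (disc radius
2 px) and removal of components under 100 px² — pinholes and dust, not
tissue. The DAB channel is thresholded and the readout is
$100\cdot|\mathrm{DAB}^+\cap \mathrm{tissue}|/|\mathrm{tissue}|$. Note the
denominator: tissue area for the IHC metric, but *total image area* for
the H&E fat metric below. The asymmetry is deliberate — it mirrors how
each measurement is conventionally reported — and both raw pixel counts
are always emitted so either normalisation can be recomputed.

**Thresholding.** Otsu's method maximises between-class variance on a
histogram (256 bins per field; 512 bins over $[0, \mathrm{od\_cap}]$ when
pooling). Two numerical choices matter:

* *Tie-break.* Between two well-separated populations the between-class
  variance is flat across the gap; we take the middle cut of the plateau
  (the convention of common implementations, and the test suite checks
  agreement with both EBImage's Otsu and a brute-force sweep oracle).
* *Unimodality guard.* Otsu always splits a histogram, even a unimodal
  one — a field with no positive staining would otherwise have its noise
  floor split and report a few percent positive, and a uniformly positive
  field would report roughly half. When the two classes found by Otsu
  differ by less than `min_contrast = 0.2` OD-equivalents (well below the
  ≈0.7 contrast of genuine DAB against counterstain, well above the ≈0.03
  OD noise scale), the histogram is declared unimodal and a fixed floor of
  0.15 decides whether the single mode is positive.

The default batch mode is `shared-otsu`: histograms restricted to tissue
are pooled across all fields and one threshold is applied uniformly to
every sample, matching the principle that thresholds should not be tuned
per image. Per-field Otsu and fixed thresholds are available; whether the
original measurements shared thresholds across the batch or set them per
image is not documented, so both are implemented and the shared variant is
the default.

**Artifact rejection.** Positive components under `min_area = 20 px²` are
always removed (chromogen specks). Large-component rejection is
*conjunctive*: a component is discarded only when it is both larger than
`max_area_frac = 5 %` of tissue *and* rounder than
`circularity_max = 0.95` — the signature of air bubbles and precipitate,
which are large near-perfect discs. A pure size cut would be wrong at
realistic positive fractions: above roughly 30 % positivity, genuine
stained regions percolate into connected clusters far larger than any
fixed size cap, but they are irregular, not round, and must be kept.
Rejected component counts are reported per field
(`n_rejected_artifacts`), never silently dropped.

**Aggregation.** Fields are nested within animals (typically 5 animals
per group), so the default summary averages fields to animal means and
takes the group mean and sample SD ($n-1$) across animals — animals are
the unit of replication, avoiding pseudo-replication. Field-level pooling
(`pool_fields = TRUE`) is available for comparison because the original
nesting of such datasets is often unstated.

## 3. H&E morphometry

**RBC segmentation.** Erythrocytes are intensely eosinophilic: a pixel is
RBC when its eosin concentration is ≥ 0.7 (parenchyma sits near 0.3) and
its red/green intensity ratio is ≥ 2.5 (parenchyma ≈ 1.9, RBC ≈ 10);
specks under 20 px are removed. Area is reported as percent of image area
and as raw px² and µm², because the axis units of such measurements vary
between studies.

**Droplet detection.** Lipid vacuoles are near-white (all channels
≥ 0.85·I₀), round, convex, sharply bordered. Candidates are 8-connected
components, hole-filled before measurement, and must pass four uniformly
applied filters: `min_area = 30 px²` (≈ 2 µm² at 0.25 µm/px — smaller
white spots are indistinguishable from processing tears),
`circularity_min = 0.6`, `solidity_min = 0.85`, and
`border_gradient_min = 8` intensity units/px. The filter *structure* is
fixed; the numeric defaults are package choices (the methodology they
implement names the filters but not their values) and every one is
overridable. Vessel lumina are white and round too; the shape filters
cannot fully distinguish a vacuole from a small round lumen, which is a
known limitation of this class of measurement. Merged vacuoles are
counted as one object (no watershed splitting).

**Shape numerics.** Perimeter uses chain-code length along the traced
boundary with the Proffitt–Rosen corrected weights (0.948 axial, 1.340
diagonal), which removes the systematic overestimation of naive chain
length; a rasterized disc then measures circularity ≈ 1.0–1.05 (small
discs legitimately exceed 1 from discretisation, capped at 1.2) while a
4×60 px rectangle measures ≈ 0.22 and is rejected at the 0.6 cut.
Solidity compares pixel count against the convex hull's lattice-point
count ($A + B/2 + 1$ by Pick's theorem), so convex shapes score 1 without
a half-pixel bias. Connected components are 8-connected; EBImage's
4-connected labelling is extended by merging diagonally adjacent labels
with a union-find pass. Border-touching components are kept.

## 4. Group statistics

Classic equal-variance one-way ANOVA from textbook sums of squares, and
Tukey HSD with
$q_{ij} = |\bar y_i - \bar y_j| / \sqrt{\mathrm{MS}_W(1/n_i + 1/n_j)/2}$
(Tukey–Kramer for unbalanced groups) and adjusted p from the
studentized-range distribution (`stats::ptukey`). No Welch correction —
the equal-variance model is the stated method of the analyses this
package reproduces. No cross-metric multiplicity adjustment is applied
over biomarker panels, matching common practice for exploratory panels;
each metric's Tukey family controls its own error rate. Degenerate data
(zero within-group variance with unequal means) yield `F = Inf`, `p = 0`
and an explicit flag; all-identical data are an error, never a silent
zero. The implementation is cross-checked in the tests against
`stats::aov`/`TukeyHSD`, against the algebraic $F = t^2$ and
$q = |t|\sqrt2$ identities at $k = 2$, against a $10^6$-draw Monte-Carlo
simulation of the studentized-range distribution, and against nominal
type-I error (5 % ± 0.6 pp over $10^4$ null replicates at $k=6$, $n=5$).

## 5. What the synthetic generator does and does not emulate

The generator exists to give every downstream stage an exact ground
truth. H&E fields emulate eosinophilic parenchyma (smooth-textured eosin
0.30 ± 0.05 and hematoxylin 0.22 ± 0.04 concentration fields), lipid
vacuoles as unstained discs with a 1 px anti-aliased rim just outside the
nominal radius (so the recorded disc is fully white and the sharp border
is measurable by gradient), and RBC blobs as discs of eosin concentration
1.10. Objects are placed by rejection sampling with mutual clearance
(1000 attempts per object before an explicit "too crowded" error), so all
ground-truth masks are pairwise disjoint. IHC fields draw tissue as a
union of random discs, a hematoxylin counterstain of 0.45 ± 0.05 on
tissue, and DAB (concentration 0.70) painted as clustered blobs until the
positive pixel count equals the rounded target fraction of tissue
*exactly* — the final blob is truncated to its pixels nearest its centre
and any remainder grows along the positive region's boundary, so no
isolated speck falls under the artifact filter. Additive Gaussian
intensity noise (sd 3 on the 8-bit scale) models sensor noise. The
default geometry is 512×512 px at 0.25 µm/px, consistent with a 40×
field.

These values were fixed once as the simulation's study conditions, before
any recovery measurement, and are not tuned.

What is *not* emulated: nuclei as instances, chromatic aberration and
uneven illumination, stain-vector drift between slides, out-of-focus
blur, tissue folds and edge artifacts, partial-volume mixtures at object
borders beyond the 1 px rim, and biological covariance between droplet
size and density. Passing recovery tests on synthetic fields therefore
demonstrates that the measurement chain is unbiased under the stated
optical model — not that segmentation parameters are optimal for any
particular real staining protocol, which always requires inspection of
the saved masks (`--save-masks`, mask attributes).

## 6. Problem sizes and runtime choices

The validation suite measures: DAB recovery with 25 fields of 512×512 px
per level at six levels (36.1, 43.5, 48.2, 46.2, 28.4, 27.2 % — the
TNF-α group means the pipeline is expected to recover within ±1
percentage point); droplet morphometry on 30 fields spanning 4–30
droplets per field; the $10^6$-draw studentized-range oracle; and
$10^4$ null ANOVA replicates. These sizes make each check statistically
meaningful while keeping the whole suite to a few minutes on one CPU.
Unit tests use 160–256 px fields, which are large enough for every
geometric property being tested.

## 7. Known limitations

* Two-stain slides only; no spectral unmixing beyond three basis vectors,
  no stain-vector estimation from data.
* No micro- vs macrovesicular classification, ballooning score, or
  intensity grading (weak/moderate/strong DAB) — area fractions only.
* The white-region shape filters cannot fully separate vessel lumina from
  lipid vacuoles; defaults are documented guesses, not fitted values.
* Whole-slide pyramids are out of scope; inputs are single fields
  (8-bit RGB TIFF/PNG).
* The determinism contract (identical seeds → byte-identical CSVs) holds
  within a given R/EBImage version; floating-point kernels may differ
  across library builds.
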