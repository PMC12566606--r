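# hepatoquant

Quantitative brightfield histology for rodent liver studies: RBC
(erythrocyte) area and lipid-droplet morphometry on H&E-stained fields,
DAB percent-positive-area measurement on immunohistochemistry (IHC) fields
for inflammatory and metabolic markers such as TNF-α and arginase, and
one-way ANOVA with Tukey HSD post hoc comparison of any per-group metric —
image-derived or blood chemistry. A synthetic histology generator with
exact pixel-level ground truth makes every stage of the pipeline
verifiable without slide material.

The package is aimed at groups running chronic-treatment studies (for
example, exogenous ketone supplementation safety studies) who need a
reproducible, scriptable alternative to interactive image-analysis tools
for per-group histomorphometry.

## The methods in brief

**Color deconvolution (Ruifrok–Johnston).** Brightfield stains mix
additively in optical density. Each pixel is converted to OD,

```
OD_c = -log10((I_c + 1) / (I0_c + 1)),          c ∈ {R, G, B}
```

and unmixed against a basis of unit-norm stain vectors `M` (hematoxylin,
eosin or DAB, plus an orthogonal residual) by solving the 3×3 system
`OD = Mᵀ·conc` per pixel. The standard published hematoxylin / eosin / DAB
vectors are the defaults (`he_basis()`, `hdab_basis()`).

**IHC percent positive area.** Tissue is delimited by total OD; the DAB
concentration channel is thresholded by Otsu's method — by default with a
single threshold from the histogram pooled across the whole batch, so one
threshold is uniformly applied to all samples — and artifacts are rejected
by size and shape filters. The readout per field is

```
dab_pos_pct = 100 · |DAB-positive ∩ tissue| / |tissue|
```

**H&E morphometry.** RBCs are segmented by their strong eosin signal and
red/green intensity ratio; lipid vacuoles are near-white, round, convex
components with sharp borders, filtered by area, circularity (4πA/P²),
solidity, and mean border gradient. Fat droplet area is the cumulative
droplet cross-section normalised to total image area.

**Group statistics.** Classic one-way ANOVA (`F = MS_between/MS_within`)
followed by Tukey HSD with the Tukey–Kramer standard error for unbalanced
groups; per-field measurements can be nested within animals
(fields → animal means → group mean ± SD) to avoid pseudo-replication.

**Synthetic ground truth.** `generate_he_field()` and
`generate_ihc_field()` render Beer–Lambert forward-model fields (the exact
inverse of the deconvolution) with known object masks, and the IHC
generator paints clustered DAB blobs until the positive fraction of tissue
hits the requested target to within one pixel — so recovery error of the
whole pipeline can be measured exactly.

## Worked example

Generate five synthetic TNF-α-like IHC fields at a true positive-area
level of 36.1 % of tissue and quantify them with a shared-Otsu threshold:

```r
library(hepatoquant)

p <- scene_params(width = 512, height = 512, target_dab_fraction = 0.361)
fields <- lapply(1:5, function(i)
  generate_ihc_field(p, seed = field_seed(101, 1, i))$image)
quantify_ihc_batch(fields, threshold_mode = "shared-otsu")
#>    field_id dab_pos_pct tissue_area_px dab_area_px n_rejected_artifacts
#> 1 field_001       36.09         170176       61425                    0
#> 2 field_002       36.10         148317       53537                    0
#> 3 field_003       36.09         143640       51846                    0
#> 4 field_004       36.09         166882       60230                    0
#> 5 field_005       36.10         152185       54935                    0
```

Every field's true fraction is 36.1 % by construction; the pipeline
recovers it to within a few hundredths of a percentage point. Group
comparison of per-group positive-area percentages:

```r
d <- data.frame(group = rep(c("Control", "KE", "KS"), each = 5),
                dab_pos_pct = c(36.2, 35.8, 36.4, 36.0, 36.1,
                                48.3, 47.9, 48.6, 48.0, 48.2,
                                28.6, 28.1, 28.5, 28.3, 28.4))
tukey_hsd(d, value = "dab_pos_pct")
#>   group_a group_b   diff      q     p_adj significant
#> 1 Control      KE  12.10 116.43 2.709e-14        TRUE
#> 2 Control      KS  -7.72  74.29 3.531e-14        TRUE
#> 3      KE      KS -19.82 190.72 2.709e-14        TRUE
```

The whole simulate → quantify → statistics pipeline runs from a single
YAML config via `run_full()` or the CLI:

```sh
Rscript inst/scripts/hepatoquant full --config run.yaml --seed 1 --out results/
```

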