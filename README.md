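# plaqglia

Quantification of amyloid plaques, plaque-associated glial cells and
neuroinflammation expression profiles — in R, with seeded synthetic
ground truth for every stage.

## The problem

Studies of amyloid pathology routinely report, per confocal field of
view: the number, area and integrated intensity of amyloid plaques;
the number of marker-positive glial cells (Iba1⁺ or CD68⁺ microglia,
GFAP⁺ astrocytes), where a cell counts as positive when its DAPI
nucleus overlaps the marker signal; and the number of those cells
lying within a physical distance of a plaque boundary (conventionally
20 µm for microglia, 50 µm for astrocytes). In parallel, multiplexed
expression panels (e.g. a 770-gene neuroinflammation panel) are
background-subtracted, normalized to the geometric mean of ten
housekeeping genes, screened for differentially expressed genes
(FC > 1.5 or FC < 0.66, p < 0.05, one-way ANOVA with Tukey's range
test), and summarized by how many disease-associated DEGs *reverse
direction* under treatment. These computations are usually spread
across commercial software with unpublished settings; `plaqglia`
implements them as open, tested, deterministic code.

The core quantitative pieces:

- **Calibration.** Areas are pixel counts × (µm/px)²; a 1024 × 1024
  field at 0.63 µm/px covers 416,179.81 µm².
- **Plaque association by exact EDT.** The dilated plaque zone at
  radius *r* is `{x : min_p ||x − p|| ≤ r}` over plaque pixels *p*,
  computed by thresholding the exact Euclidean distance transform
  (20 µm at 0.63 µm/px = 31.746 px — honoured exactly, unlike iterated
  3 × 3 dilation). Each associated cell is credited once, to its
  nearest plaque.
- **Housekeeping normalization.** Sample *s* is scaled by
  `f_s = G_ref / G_s`, with `G_s` the geometric mean of its
  housekeeping counts and `G_ref` the geometric mean of all `G_s`.
- **Reversal statistic.** Over disease-contrast DEGs, the fraction
  whose treatment-contrast fold change has the opposite sign of the
  disease fold change (direction only, no significance filter).

Synthetic generators (`render_scene()`, `simulate_expression()`)
produce image scenes and grouped negative-binomial count matrices with
known ground truth, so plaque counts, areas, positive-cell counts,
association counts, fold changes and reversal fractions can all be
checked exactly.

## Worked example

```r
library(plaqglia)

# a synthetic 512 x 512 field at 0.63 um/px: 4 plaques, 20 glial cells
sp <- random_scene_spec(seed = 7, field_shape = c(512L, 512L),
                        n_plaques = 4, n_cells = 20)
scene <- render_scene(sp)
q <- quantify_field(scene$field, radius_um = 20, marker = "Iba1")
q$plaque_table
#> plaque_table: 4 plaque(s), 2516.74 um^2 total (2.419% of field)
q$plaque_table$plaques
#>   id  area_um2 integrated_intensity centroid_row centroid_col
#> 1  1 1239.1218            442569.72     210.9901     88.17233
#> 2  2  457.2288            133975.18     472.5825    101.76910
#> 3  3  575.9019            125942.27     106.0000    133.16678
#> 4  4  244.4904             54017.53     135.0000    392.76948
q$association
#> association_result: 1 / 15 positive cells within 20 um of a plaque
```

Four plaques were segmented; each row gives one plaque's area in µm²,
its summed fluorescence and its centroid in 0-based pixel coordinates.
Of the 20 planted cells, 15 are marker-positive (nucleus overlapping
glial signal) and exactly one has its nucleus within 20 µm of a plaque
boundary — all matching the generator's ground truth in
`scene$ground_truth`.

```r
# expression: 770 genes, 3 groups of 10, 99 genes planted up in disease,
# 71 of them planted to reverse under treatment
sim <- simulate_expression(expr_sim_spec(seed = 7))
m <- normalize_housekeeping(background_subtract(sim$matrix))
de_dis <- differential_expression(m, c("disease", "control"))
de_trt <- differential_expression(m, c("treated", "disease"))
table(de_dis$class)
#>  ns  up
#> 671  99
reversal_analysis(de_dis, de_trt)
#> reversal_summary: 71 of 99 DEGs reversed (71.7%)
```

The caller recovers exactly the 99 planted up-regulated genes
(FC > 1.5, Tukey p < 0.05) and the 71 planted directional reversals.

```r
# figure-style group summary of a field-level measure
compare_groups(c(12, 15, 14, 9, 8, 10, 4, 5, 6),
               rep(c("disease", "treated", "control"), each = 3),
               measure = "plaque_count")
#> group_comparison of 'plaque_count' (anova test): statistic = 39.08, p = 0.0003624 ***
#>   control      n= 3  5 +/- 0.5774
#>   disease      n= 3  13.67 +/- 0.8819
#>   treated      n= 3  9 +/- 0.5774
#>   disease-control          p_adj = 0.0002877 ***
#>   treated-control          p_adj = 0.01538 *
#>   treated-disease          p_adj = 0.007499 **
```

`run_pipeline()` drives the whole chain (synthesis → image
quantification → expression → group statistics) from one YAML
configuration and writes CSV/JSON tables plus a JSON-lines run log,
byte-identically across reruns with the same seed.

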