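# ihcspat

Spatial point-pattern analysis of immunostained inflammatory cells in
brightfield immunohistochemistry (IHC) fields.

Pathology studies of the tumor microenvironment increasingly ask not just
*how many* marker-positive cells a tissue contains but *how they are
arranged*: evenly spread, random, or clustered. `ihcspat` implements that
workflow end to end for H-DAB stained brightfield fields:

1. **Colour deconvolution** — the RGB field is converted to optical density
   (`OD = log10(I0 / I)`, Beer–Lambert) and unmixed into hematoxylin and
   DAB concentration channels with a 3×3 stain matrix (published H-DAB
   vectors by default, configurable).
2. **Positive-cell extraction** — Otsu (or fixed) thresholding of both
   channels, morphological cleaning, selection of nuclei co-localized with
   immunoreactivity, giving per-field (x, y) cell coordinates and the
   immunoreactive **Area%**.
3. **Spatial statistics per field** —
   * a **uniformity index** in [0, 1] (normalized Clark–Evans
     nearest-neighbour ratio: 0 = all cells coincident, ≈ 0.465 = random,
     1 = regular array), and
   * **Ripley's K-function** `K(d)` compared against pointwise 95%
     Monte-Carlo envelopes from 100 simulated random (CSR) patterns with
     the *same* point count and window, with the deviation curve
     `L(d) = K(d) − K0(d)` and a verdict
     (`clustered` / `random` / `avoidance` / `mixed`) based on sustained
     excursions outside the envelope.
4. **Cohort comparison** — per-sample averaging of Area% and uniformity
   index over fields, then a two-sample Student's t-test between two
   patient groups (e.g. the ABC vs GCB subgroups of diffuse large B-cell
   lymphoma), significance at p < 0.05.

A first-class **synthetic-data module** generates point patterns across
the clustered → random → regular spectrum (Thomas process, CSR, jittered
hexagonal lattice, coincident), Beer–Lambert-rendered two-stain field
images with exact ground truth, and full two-arm cohorts (15 samples × 10
fields per arm by default), so the entire pipeline is testable without
patient material.

## Worked example

```r
library(ihcspat)

# a clustered synthetic field: Thomas process, 150 cells in a 1000x1000 px window
p <- generate_pattern(pattern_spec("thomas_cluster", 150, offspring_spread = 30),
                      ihc_window(1000, 1000), seed = 7)
s <- analyze_field(p, ihc_config(seed = 7))
s
#> field: n = 150 cells, Area% = -, uniformity = 0.208, verdict = clustered
uniformity_index(p)
#> uniformity index: 0.208 (Clark-Evans R = 0.447, n = 150)
plot(s$k)   # L(d) = K(d) - K0(d) with dashed 95% envelopes
```

The uniformity index 0.208 sits well below the ≈ 0.465 expected for a
random arrangement, and the K-function stays above the upper envelope over
a sustained range of distances, so the field is called `clustered`.

A whole two-arm cohort, one clustered arm versus one random arm, at the
emulated study design (15 samples × 10 fields per arm):

```r
rep <- simulate_cohort(
  pattern_spec("thomas_cluster", 100, offspring_spread = 30),
  pattern_spec("csr", 100),
  n_samples = 15, n_fields = 10, n_range = c(50, 200),
  config = ihc_config(seed = 1))
rep$comparisons$uniformity_index
#> uniformity_index: A 0.1753 +/- 0.0094 (n=15) vs B 0.4834 +/- 0.0102 (n=15)
#>   Student t = -86.0060, df = 28, p = 1.761e-35 (*)
```

The clustered arm's mean sample-level uniformity index (0.175) is far
below the random arm's (0.483); the pooled-variance t-test flags the
difference at p < 0.05.

Image-mode input works the same way: `analyze_field("field_01.tif",
ihc_config(mode = "images"))` runs deconvolution, thresholding, and cell
detection first; `read_patterns_csv()` ingests pre-extracted coordinate
tables (`sample_id, field_id, x, y`).

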