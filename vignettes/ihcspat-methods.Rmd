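---
title: "Methods: quantifying the spatial arrangement of immunostained cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the spatial arrangement of immunostained cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcspat)
```

## The problem

In brightfield immunohistochemistry, marker-positive cells (stained brown by
the DAB chromogen, on a blue hematoxylin nuclear counterstain) are not only
more or less abundant across patient groups — they are *arranged*
differently. Two tissues with the same positive-cell density can have those
cells spread evenly, thrown down at random, or packed into clusters, and
that architecture carries biological meaning for the tumor
microenvironment. `ihcspat` turns a field image (or a table of
positive-cell coordinates) into two complementary spatial descriptors, and
compares them between two patient cohorts.

The pipeline has four stages:

1. **Stain separation** — colour deconvolution of the RGB field into
   hematoxylin and DAB channels.
2. **Cell detection** — thresholding of the two channels, selection of
   nuclei co-localized with immunoreactivity, immunoreactive Area%.
3. **Spatial statistics** — a nearest-neighbour uniformity index and
   Ripley's K-function compared against Monte-Carlo envelopes.
4. **Cohort analysis** — per-sample averaging and a two-sample Student's
   t-test between groups.

A synthetic-data module generates every input with known ground truth, so
each stage and the pipeline as a whole are testable without patient
material.

## Stain separation

Stain amounts add linearly in optical-density (absorbance) space
(Beer–Lambert): a pixel's OD vector is

$$\mathrm{OD}_c = \log_{10}\!\frac{I_0}{\max(I_c, \varepsilon)},
\qquad \mathrm{OD} = c_H S_H + c_D S_D + c_R S_R,$$

with $I_0 = 255$ the incident intensity and $\varepsilon = 1$ a clamp that
keeps zero-intensity pixels finite. `unmix()` recovers the concentration
triple $(c_H, c_D, c_R)$ by a single 3×3 solve per pixel. The default
absorbance vectors are the published H-DAB pair used by the standard ImageJ
colour-deconvolution plugin — hematoxylin $(0.650, 0.704, 0.286)$ and DAB
$(0.269, 0.568, 0.778)$, re-normalized to unit length — with the residual
vector built as their normalized cross product (the usual orthogonal
completion). The vectors are configurable through `stain_system()` because
real scanners and stain batches deviate from the published values; no
automatic stain estimation (e.g. Macenko) is attempted. Negative
concentrations from noise are clipped to zero for masking; the raw solution
is kept for diagnostics. White-balancing to the 99th-percentile background
(`white_balance()`) is available as optional shading correction and is off
by default — synthetic renders need none, and for real slides it is a
cosmetic step whose exact original settings are unknowable.

## Cell detection

`threshold_channel()` defaults to Otsu's method (maximum between-class
variance over a 256-bin histogram), the conventional choice for bimodal
stain channels; a fixed threshold is available for reproducibility across
batches. `clean_mask()` applies a disc opening and removes components below
a minimum area. `detect_positive_cells()` labels the connected components
of the nuclei mask and emits the centroid of every component whose overlap
with the immunoreactive mask is at least `min_overlap_fraction` of its
area. The default of 0.5 operationalizes "co-localized" as *majority
overlap*; it is deliberately a tunable, since the boundary between a
touching and an overlapping nucleus is a judgement call. Coordinates are
pixel-center based with the origin at the image's top-left, x along
columns, y along rows — stated once here and used consistently everywhere.
Watershed splitting of touching nuclei (`split_nuclei()`) is provided but
off by default; the core procedure does not require it and it changes
counts in ways that should be opted into knowingly.

Area% is defined by this package's own masks:
$100 \times$ (immunoreactive pixels) / (total pixels). It is *not* the
proprietary scanner-software "positivity" metric, which is pixel-based with
unpublished internals.

## Uniformity index

The morphological descriptor is a scalar in $[0, 1]$: 0 at maximal
clustering (all points coincident), 1 for an ideal regular array. We
implement it as a normalized Clark–Evans nearest-neighbour ratio,

$$R = \frac{\overline{d}_{NN}}{0.5/\sqrt{\lambda}}, \qquad
\text{index} = \min\!\left(\frac{R}{2.1491},\, 1\right),$$

where $\lambda = n/|W|$ and $2.1491 = 2/\sqrt{\sqrt{3}/2}$ is the
theoretical maximum of $R$, attained by the hexagonal lattice. This
normalization provably satisfies both endpoints: coincident points give
$\overline{d}_{NN} = 0$ hence index 0 exactly, and a hexagonal lattice
tiling the window gives index 1 up to finite-size edge effects (within
0.03 for a 400-point lattice; the acceptance script reproduces this). Under
CSR the expected index is $1/2.1491 \approx 0.465$. This is a *declared
design choice*: uniformity indices of this kind appear in the morphometry
literature in several variants, and the Clark–Evans normalization was
chosen because it is the simplest statistic that provably has the required
endpoints. No edge correction is applied to the nearest-neighbour distances
by default (the comparison between groups uses the same estimator on both
sides); the Donnelly boundary correction is available behind
`edge_correction = "donnelly"`.

Patterns with fewer than two points have no defined index; they are
flagged (`defined = FALSE`) and excluded from the per-sample mean rather
than raising an error, so a sparse field cannot abort a cohort run.

## Ripley's K and Monte-Carlo envelopes

The spatial-statistics descriptor is Ripley's
$K(d)$ — the expected number of further points within distance $d$ of a
typical point, divided by intensity; $\pi d^2$ under complete spatial
randomness (CSR). The default estimator is the naive one,

$$\hat K(d) = \frac{|W|}{n(n-1)} \sum_{i \ne j}
\mathbf{1}(\lVert p_i - p_j \rVert \le d),$$

*without* edge correction. The rationale: all inference in the pipeline is
relative to a Monte-Carlo null with the *same* number of points in the
*same* window, evaluated with the *same* estimator — 100 simulated CSR
patterns per field — so the edge bias is common to both sides of the
comparison and cancels. For users who want the absolute $K$ (e.g. to
compare against $\pi d^2$ directly) the translation edge correction for a
rectangular window is available via `correction = "translation"`; it is
unbiased under CSR, and the package's own closed-form check uses it, since
the uncorrected estimator's expectation on a unit square,
$\pi d^2 - \tfrac{8}{3}d^3 + \tfrac{1}{2}d^4$, is already ~8% below
$\pi d^2$ at $d = 0.1$.

The distance grid is 50 equal steps from $d_{max}/50$ to $d_{max} =$ ¼ of
the shorter window side — standard practice keeping $K$ well inside the
regime where the window contains meaningful pairs. Envelopes are
*pointwise*: at each grid distance the bounds are the order statistics at
rank $\lceil (n_{sim}+1)\alpha/2 \rceil$ from each end of the simulated
values — for $n_{sim} = 100$ and $\alpha = 0.05$, the 3rd-smallest and
3rd-largest. A fresh CSR pattern therefore lands outside the envelope at
roughly 5% of grid distances on average (slightly less at small $d$, where
the discrete pair counts tie at zero), which the acceptance suite verifies
over 200 replicates. A global (rank/MAD) envelope would control the
family-wise excursion rate instead; pointwise envelopes are what the
standard envelope display shows, and the verdict rule below compensates
for their multiplicity.

**Verdict rule.** Because ~5% of grid points stray outside the envelope by
chance, an isolated excursion is not evidence. `classify_pattern()` calls a
pattern *clustered* only when $\hat K$ exceeds the upper envelope over a
contiguous run of at least `min_run_fraction` (default 0.2, i.e. 10 of 50
grid points) of the grid — a sustained excursion over "a large interval of
cell-to-cell distances" — and *avoidance* symmetrically below the lower
envelope; both gives *mixed*, neither *random*. The run rule's false-call
rate on CSR input is low but not zero (isolated seeds can produce a
10-point run); the cohort-level inference does not depend on per-field
verdicts, which are descriptive.

The deviation curve plotted by `plot()` on a `k_analysis()` result is
$L(d) = \hat K(d) - K_0(d)$ with $K_0$ the simulated mean, drawn with the
re-centred envelope bounds as dashed lines — the familiar envelope display.

## Synthetic data: what it emulates, and what it does not

`generate_pattern()` produces point patterns in four regimes spanning the
spectrum the pipeline must discriminate: `coincident` (maximal clustering),
`thomas_cluster` (Thomas process: Poisson parents, Gaussian offspring —
the canonical clustered model), `csr`, and `jittered_lattice` (hexagonal
lattice with uniform jitter — the regular extreme). All generators
*condition on the point count*: the Monte-Carlo null matches the observed
count exactly, so fixed-$n$ generation mirrors the analysis' own null.
Thomas offspring falling outside the window are resampled until inside,
keeping $n$ exact; the induced slight inward bias of offspring near the
boundary is irrelevant to the fixed-$n$ comparisons the patterns serve.
Per-field point counts in cohorts are drawn uniformly from 50–400 by
default — a fixture choice representing a plausible range for a 40×
high-power field, not an empirical fact about any tissue.

`render_field()` builds a two-stain field by Beer–Lambert composition:
every nucleus deposits hematoxylin absorbance over a hard disk (default
radius 4 px, amplitude 0.6), positives additionally deposit DAB (amplitude
0.8), intensities are $I_c = I_0 10^{-A_c}$. Renders carry their exact
ground truth (masks, concentration canvases, coordinates). Intensities are
kept as doubles; quantization to 8-bit happens on `write_field()`, so the
zero-noise round-trip contract (stain concentrations recovered to better
than 1% of the true amplitude) tests the optics model, not the file
format. The renderer makes no attempt at photorealism — no texture,
stroma, folds, chromatic aberration or uneven illumination. Consequently a
passing round trip demonstrates that the deconvolution-and-detection chain
is *self-consistent and exact on ideal input*; it does not demonstrate
robustness to the messiness of real slides, which is what the
configurable thresholds, morphology parameters and white balance exist
for.

Cohorts mirror the target study design: two arms (labelled ABC and GCB) of
15 samples × 10 equal-area fields. Each field draws from its own RNG
stream keyed by (master seed, group, sample, field) via `field_seed()`, so
any subset of a cohort can be regenerated bit-identically without
generating the rest.

## Cohort analysis

Per-field Area% and uniformity index are averaged over the usable fields of
each sample — the sample is the statistical unit, fields are repeated
measures — and the two groups are compared per parameter with the classical
pooled-variance two-sample Student's t-test (two-sided,
$n_A + n_B - 2$ df), significance at $p < 0.05$. Welch's variant is
available behind a flag. Both SD and SEM are reported per group. No
multiple-testing correction is applied across markers or parameters — a
deliberate mirror of common practice in this literature, and a documented
caveat: with five markers and two parameters, one nominally significant
result is expected by chance in every other null study. Samples with zero
usable fields are excluded listwise per parameter with a warning. Under
identical generating conditions for both arms the test's rejection rate is
calibrated at the nominal 5% (verified over 200 replicate cohorts against
the 99% binomial acceptance region, 1–9%).

## Numerical choices and degenerate inputs

* OD clamp $\varepsilon = 1$ intensity unit; keeps $\log_{10}$ finite at
  black pixels (OD $= \log_{10} 255 \approx 2.41$).
* Otsu on a constant image is a degenerate histogram and errors with a
  pointer to the fixed-threshold fallback, rather than guessing.
* `compare_groups()` with zero pooled variance and equal means returns
  $t = 0, p = 1$ instead of 0/0.
* K on $n < 2$ points errors at the operation level; the pipeline level
  converts this to a flagged, skipped field.
* Envelope rank $\lceil (n_{sim}+1)\alpha/2 \rceil$ is clamped to
  $[1, n_{sim}/2]$ so tiny $n_{sim}$ cannot produce crossed bounds.
* The hexagonal lattice generator chooses its row/column counts to match
  the requested $n$ at the hex aspect ratio $dy/dx = \sqrt{3}/2$ and keeps
  the first $n$ points in row-major order when the grid does not factor
  exactly; nearest-neighbour spacing, which is what the uniformity index
  sees, is unaffected.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at the design scale of the
emulated study where that scale matters (15 × 10 × 2 cohorts, 100
simulations per envelope, 200 replicates for coverage and type-I
calibration) and at reduced sizes for unit-level oracles (e.g. brute-force
K equivalence on patterns of up to 200 points), chosen so the whole suite
completes in a few minutes on one core.

## Known limitations

* The uniformity index is a *declared substitute* for the family of
  morphometric uniformity indices in the literature; other variants scale
  differently between the endpoints, so absolute values should not be
  compared across software.
* Pointwise envelopes plus the run rule give a descriptive per-field
  verdict, not a formal global test.
* No pair-correlation function, cross-type K between markers, or
  inhomogeneous K; the pipeline is univariate by design.
* Real-slide preprocessing (shading, contrast) is reduced to an optional
  white balance; strong vignetting or stain drift should be corrected
  upstream.
* Whole-slide formats and field selection are out of scope: inputs are
  already-selected equal-area fields.
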