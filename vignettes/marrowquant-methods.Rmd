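---
title: "Quantification methods in marrowquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in marrowquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowquant)
```

marrowquant implements the quantification procedures used to study
galectin-1 and extracellular-matrix (ECM) remodeling in the myelofibrotic
bone marrow niche: chromogenic-IHC positivity calling with spatial heatmaps,
fluorescence-assay quantifiers for the fibroblast-to-myofibroblast
transition (FMT) and organoid fibrosis assays, per-cell gene-set
expression-fraction scores on single-cell UMI counts, and the shared
nonparametric statistics. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the
underlying procedures leave room for interpretation. Every empirical claim
here is computed by the package's test suite or its acceptance script — the
synthetic generators below are first-class, tested code, not throwaway
fixtures.

## The Beer–Lambert color model for H-DAB IHC

Brightfield chromogenic stains absorb light: a pixel with per-stain
concentrations $c = (c_1, c_2, c_3)$ transmits intensity
$I_k = I_0 \cdot 10^{-(c^\top M)_k}$ in channel $k$, where $M$ is a $3
\times 3$ matrix whose rows are unit-length optical-density (OD) color
vectors and $I_0$ is the unstained background intensity. Stain
concentrations therefore combine *linearly in OD space*, and deconvolution
is a per-pixel solve $c = \mathrm{OD} \cdot M^{-1}$ after
$\mathrm{OD}_k = \log_{10}(I_0 / \max(I_k, 1))$.

Choices and parameters:

* **Stain vectors.** `hdab_stain_model()` bundles the standard published
  unit vectors for hematoxylin (0.650, 0.704, 0.286) and DAB
  (0.268, 0.570, 0.776); measured vectors can be supplied through
  `stain_model()` or a JSON config on the command line. Two stains are
  completed to an invertible basis by the normalized cross product
  (`complete_stain_matrix()`); the completed H-DAB matrix has condition
  number ≈ 3.6, so 8-bit quantization (±0.5 intensity counts) propagates to
  well under 0.01 OD in concentration space as long as intensities stay
  above ~20 counts.
* **Intensity floor** $i_{\min} = 1$ bounds the OD of saturated pixels
  without special cases.
* **$I_0 = 255$** by default; it is a `stain_model` field for cameras with a
  different white level.
* **Negative concentrations** (noise, off-model color) are clipped at zero
  by default because concentrations are physically non-negative;
  `clipping_policy = "raw"` keeps them for diagnostics, and the linearity
  property (scaling OD scales concentrations) is only exact pre-clipping.

**Stain normalization.** Staining batches differ in overall intensity. The
package aligns slides by rescaling each stain map so its robust maximum
(99th percentile over tissue pixels) matches a reference cohort
(`stain_reference_stats()` + `normalize_stains()`). Percentile matching is
the simplest transform consistent with correcting batch-to-batch gain: it
is linear, preserves within-slide rank order, and cancels a global
chromogen gain exactly (verified in the tests by construction of a
gain-perturbed slide pair). A stain whose source percentile is zero is left
unscaled with a warning rather than dividing by zero.

## Positivity calling and spatial summarization

A pixel is **tissue** when its total OD across channels exceeds `od_min`
(default 0.15 — unstained background sits near 0 OD and any stained tissue
well above it; configurable because the right floor depends on the faintest
counterstain of interest).

The **positivity cutoff** is computed once per cohort, not per slide: the
deconvolved chromogen concentrations of all tissue pixels from all slides
are pooled into a single distribution, and an Otsu threshold (the histogram
split maximizing between-class variance, 256 bins by the 8-bit convention)
is applied to it (`pooled_positive_cutoff()`). Pooling is what makes
positivity comparable across a cohort — a per-slide cutoff would erase
between-slide differences in expression. "Intensity distribution" is taken
to mean the deconvolved chromogen concentration (the quantity the
deconvolution step exists to produce), not a raw channel; the functions
accept any matrix, so a raw-channel analysis remains possible. The Otsu
implementation is exactly the exhaustive between-class-variance maximizer
(the test suite checks equality against a brute-force search on random
histograms), with ties broken at the lowest qualifying bin edge, and
histogram counts accumulated in doubles so megapixel cohorts cannot
overflow.

The **heatmap** partitions the slide into square tiles of 256 µm (the
default tile size; `tile_size_um` configurable) anchored at the top-left
pixel. Partial edge tiles are kept and flagged rather than discarded so
that per-tile counts sum exactly to slide-level counts and the
tissue-weighted mean of tile ratios equals the whole-slide positive ratio
to machine precision — a conservation identity the tests assert at 1e-12.
Tiles with no tissue carry a missing ratio. `per_field_positivity()` is the
same tiling at a "high-power field" size. No standard field area exists, so
the default is a 487 µm square (≈ 0.237 mm², a common 40× field), exposed
as `field_size_um`; both the positive-pixel ratio and the mean chromogen
concentration are emitted per field, with the ratio as the headline number.
`intensity_density_correlation()` correlates tile ratios with an externally
supplied per-tile fibrosis-density map (e.g. a machine-learned fibrosis
severity score on the same grid) by Spearman rank correlation, which is
invariant to the monotone-but-unknown relation between positivity and
density.

## Fluorescence quantifiers

**Nuclei counting (FMT assay).** The detector is an edge-detection
pipeline: Gaussian smoothing (`sigma` = 2 px) → Sobel gradient magnitude →
hysteresis thresholding → morphological closing (disc radius 2) → hole
filling → connected components → minimum-area filter (20 px²). The strong
hysteresis threshold defaults to the Otsu split of the gradient-magnitude
distribution with the weak threshold at half of it. A fixed-quantile rule
(the `"quantile"` mode) is retained as an option but is not the default: a
quantile assumes a fixed fraction of edge pixels, and on fields where
foreground covers a few percent of the image a 0.7-quantile threshold sits
at the noise floor and floods the background. The Otsu split instead adapts
to however much of the gradient mass is edge-like. A noise-floor guard
returns an empty segmentation when the strong threshold is within a few
multiples of the median gradient, i.e. when the gradient distribution is
unimodal noise rather than edges. Touching nuclei are *not* split (no
watershed): the counting rule is faithful to a plain
edge-detect-and-count design, and clumped fields are a documented
limitation — the simulator's `allow_touching` flag exists precisely to
exercise it.

**Per-cell collagen.** The default `"per_count"` mode divides the
integrated collagen intensity of the field by the nuclei count. This
matches a program that counts nuclei and reports a per-cell mean without
segmenting cytoplasm; since the field total divided by count and the mean
of per-cell integrals are identical on a field basis, no cell assignment is
needed. The `"per_mask"` alternative (mean within dilated nuclear masks) is
provided because "mean intensity per cell" is genuinely ambiguous; the mode
is recorded in every record. Fold changes (`normalize_to_control()`) divide
each condition's mean by the no-stimulus control mean, which cancels any
global camera gain.

**Organoid z-stacks.** `max_intensity_projection()` →  3×3 median denoising
→ rolling-ball background subtraction → mean intensity per ROI
(`organoid_roi_intensity()`). The rolling-ball background is the grayscale
opening with a *non-flat* ball (sphere-cap) structuring element — the
surface a ball of radius `radius_px` traces rolling under the intensity
landscape — implemented directly since flat-disc morphology would delete
any object narrower than the disc instead of preserving it. Properties
guaranteed by construction and asserted in tests: a flat image maps to all
zeros, the output is bounded by `0 ≤ out ≤ input`, and a bright disk
narrower than the ball keeps its peak (the ball cannot enter it). The ball
radius defaults to 50 px and should exceed the largest genuine foreground
object; the residual bias it leaves under a plateau of half-width $a$ is
the sagitta $R - \sqrt{R^2 - a^2} \approx a^2/2R$ in intensity units, which
is negligible when signals are large relative to their footprint and is
the reason the defaults keep ROIs much narrower than the ball.

## Gene-set expression-fraction scores

For a cell with UMI counts $x_g$ and a gene set $S$, the score is

$$\mathrm{score} = \frac{\sum_{g \in S^\ast} x_g}{\sum_{g} x_g},$$

where $S^\ast \subseteq S$ is the *expressed* subset: set genes with at
least `min_total_umis` (default 50) UMIs summed over all cells of the
compartment (hematopoietic and stromal compartments are filtered
independently). Two deliberate readings of the definition:

* the **denominator is all genes, unfiltered** — the score is the fraction
  of a cell's transcriptional output devoted to the (reliably detected)
  set;
* the **numerator filter is compartment-level**, so a gene expressed by a
  rare subpopulation still counts for every cell of the compartment once
  its total clears the threshold.

Scores are bounded in [0, 1], invariant to multiplying a cell's counts by a
constant, and a cell with zero total counts gets `NA` rather than 0 (0/0 is
undefined; such cells are upstream QC failures). With multinomial counts at
depth $d$ and designed set mass $p$, the per-cell score has expectation $p$
and variance $p(1-p)/d$, so 500 cells at depth 10⁴ pin the mean within
±0.01 — the recovery the acceptance checks assert for
$p \in \{0, 0.1, 0.3, 1\}$. Gene lists are user input (two-column CSV,
`gene_id, category`); category labels (collagens / glycoproteins /
proteoglycans) drive `count_expressed_set_genes()`, the per-compartment
expressed-gene census. Group contrasts on scores use the shared Wilcoxon
rank-sum with BH adjustment across group pairs.

## Nonparametric statistics

`wilcoxon_rank_sum()` is two-sided with midranks for ties: the exact
permutation distribution when the combined sample is ≤ 14 with no ties (at
most $\binom{14}{7} = 3432$ assignments, where the normal approximation is
weakest), the continuity- and tie-corrected normal approximation otherwise;
the path taken is recorded in a method tag. The exact path is verified
against full enumeration; the approximation sits within ~0.02 of the exact
p at the boundary size (its worst case ~0.012 mid-range, measured in the
tests). `bh_adjust()` is Benjamini–Hochberg step-up (Bonferroni available);
the proteomics pipeline (`compare_protein_groups()`) applies
$\log_2(x + 1)$ then per-feature min–max scaling to [0, 1] before testing —
both monotone within a feature, so the rank-based test is unaffected by
the log base; the dual normalization matters only for cross-feature
display. A constant feature min–max-scales to all zeros with a warning; a
feature with no observed values is an error naming the feature. The
proteomics comparison is unpaired (the group sizes in its intended use are
unequal and unpaired).

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of (spec, seed) via a named RNG stream,
restores the ambient RNG state, and emits its ground truth, so no pipeline
test needs manual annotation.

* `gen_ihc_slide()` runs the Beer–Lambert model *forward*: designed
  chromogen/counterstain concentrations (defaults 1.0 positive / 0.1
  negative / 0.4 counterstain, chosen so every quantized channel stays
  above ~30 counts and the round trip is limited only by 8-bit rounding),
  Gaussian noise added in OD space (hence multiplicative in intensity, as
  the physics implies), tissue as a top-anchored band covering
  `tissue_fraction`, and noise-free background so the tissue mask has an
  exact truth.
* `gen_fluor_pair()` places non-overlapping disks with a clear 12-px edge
  gap by default (`min_gap_px`): disks closer than the detector's smoothing
  support are *optically* touching even if geometrically separate, and
  touching fields are the `allow_touching` mode's job. The collagen channel
  is uniform, so the per-cell truth has the closed form $WHI/c$.
* `gen_zstack()` builds a 2-D truth image of disjoint ROI disks and
  distributes it so the per-pixel maximum over slices equals the truth
  exactly; per-slice noise (default fixtures ~1% of the dimmest signal, the
  same SNR regime as the FMT fixtures) is added afterwards.
* `gen_counts()` draws each cell's counts from one multinomial with mass
  `p_set` spread over the set genes — column sums equal the depth exactly.
  Fixed depth is the default (simplest variance accounting); log-normal
  depths are available behind `depth_lognormal_sd`.
* `gen_proteomics()` draws log-normal abundances and shifts a designated
  subset by `effect_log2fc` in one group.

None of this emulates real tissue morphology, cell-shape variation, count
overdispersion/dropout, or batch effects; passing the recovery tests shows
the *algorithms* are correct under their stated models, not that real
images or libraries meet those models. Two measured caveats worth knowing:
maximum projection takes the max of $k$ noise draws per pixel, which biases
background up by $\approx 1.16\sigma$ (for $k = 5$) relative to
single-slice-dominated signal pixels, so per-ROI means are depressed by
about that much after background subtraction when the per-slice noise
$\sigma$ is not small against the signal; and the rolling-ball sagitta bias
above. Both are properties of the standard pipeline itself, not of this
implementation.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic data
at desk scale: 512×512 px for the stain round trip and the 50 nuclei
fields, 128×128 px cohorts (6–20 slides) for positivity recovery and
conservation, 320×320 px FMT fields (16 per condition), a 192×192×5 stack
for the organoid pipeline, 500 cells/type at depth 10⁴ for score recovery,
and 500 simulated null datasets for type-I calibration. These sizes were
chosen so the whole battery completes in a few minutes while leaving the
statistical margins (binomial/permutation standard errors) an order of
magnitude below the asserted tolerances. Degenerate inputs fail loudly
rather than silently: constant input to Otsu, zero detected cells in a
per-cell mean, an empty control condition, an all-missing feature, a
singular stain matrix and an oversized rolling ball are all validation
errors with named causes.
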