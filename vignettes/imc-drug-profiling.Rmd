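---
title: "Methods: single-cell drug-response profiling for Imaging Mass Cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell drug-response profiling for Imaging Mass Cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Imaging Mass Cytometry (IMC) rasters a laser across an antibody-stained
sample in 1 um steps and reads each ablated spot with a time-of-flight
mass cytometer, so every pixel is a vector of ion counts across ~30
isotope channels. For in vitro drug profiling, a monolayer of cells
(here, an MCF-7 breast-cancer model) is exposed to compounds, stained
with a metal-tagged antibody panel, and ablated as rectangular ROIs.
`imcprofiler` turns those multichannel count images into per-cell
phenotype calls and treatment-similarity summaries:

1. simulate or load multichannel ROI stacks (`generate_experiment()`,
   `read_stack()`);
2. segment nuclei (primary objects) and whole cells (secondary objects)
   (`segment_nuclei()`, `segment_cells()`);
3. extract per-cell morphology and mean intensities
   (`extract_features()`);
4. normalize and compare conditions (`zscore_cells()`,
   `compare_conditions()`, `spatial_heatmap()`);
5. embed cells in 2-D (`tsne_embed()`);
6. classify nuclear phenotypes with Fast Gentle Boosting
   (`train_fast_gentle_boosting()`, `cross_validate()`,
   `mitotic_index()`);
7. quantify multiparametric similarity (`pearson_matrix()`,
   `hierarchical_order()`, `cross_condition_similarity()`,
   `edge_bundle_graph()`).

`run_pipeline()` chains all stages under one master seed and writes a
reproducible output bundle.

## The synthetic-data generator

No public IMC acquisition accompanies this analysis, so the package
ships a ground-truthed generator whose defaults define the study
conditions used by every end-to-end test. Each condition is a
`treatment_profile()`: cell density (600 cells/mm^2), a mixture over six
nuclear phenotype classes (`pHistone3+`, `pH2A.X+`, `p53+`, `cyclinD3+`,
`Ki-67+`, `negative`), a cell-area distribution (180 +/- 50 um^2,
nuclear fraction 0.45), and a per-class, per-channel mean ion count.
Cells are placed by dart throwing without overlap, class labels are
drawn from the mixture, and each pixel of each channel draws a Poisson
count whose rate is background (0.2 counts/px) plus the covering cell's
rate deposited into the channel's compartment: nuclear markers inside
the nucleus ellipse, membrane markers in a 2 px rim inside the cell
boundary, cytoplasmic markers in the cell minus the nucleus. There is no
channel spillover, consistent with the negligible contamination of
well-designed isotope panels, and no ablation physics: the generator
emulates count statistics and marker localization, not the instrument.

The planted drug effects follow the pharmacology the pipeline is meant
to recover, with magnitudes fixed once:

* nocodazole (microtubule depolymerization, mitotic arrest): mitotic
  mixture weight 0.12 versus 0.04 in both controls (threefold), and the
  pHistone3 rate in mitotic cells doubled (60 vs 30 counts/px);
* etoposide (genotoxic): pH2A.X rates scaled fivefold in every class and
  the proliferating `Ki-67+` weight raised to 0.30;
* EGF (growth stimulation): mean cell area scaled by 1.8 and membrane
  marker rates by 1.5;
* DMSO: identical to the nontreated control.

Per-cell rates jitter log-normally (CV 0.3, mean one, so channel means
stay at the profile value). Correlated biology is planted through shared
log-normal latent factors: pHistone3/Ki-67/p4E-BP1 co-vary within
mitotic cells (one factor, log-sd 0.5); the CD adhesion markers share a
second, independent factor in all cells; the two iridium intercalator
isotopes share a factor because they report one reagent; and
pan-keratin/CK19 share one because the antibodies detect co-expressed
isoforms. Under EGF the adhesion factor splits in two (CD98/CD47 versus
the rest), planting the adhesion remodeling that the cross-condition
similarity analysis is designed to expose.

Absolute ion-count scales are fabricated (no instrument values are
published for this panel); they were chosen to sit in the typical range
of IMC antibody channels (tens of counts per pixel for strong markers,
fractions of a count for background). What passing tests show is that
the pipeline recovers planted effects from Poisson-noised, spatially
rendered images; they cannot show robustness to instrument artifacts the
generator does not model (spillover, ablation streaks, tissue-section
crowding, autofluorescence-like background structure).

The default desk-scale ROI is 500 x 500 um (one eighth the linear
dimension of a real acquisition at the same density), with the published
replicate layout: two ROIs per drug, one per control, eight ROIs and
~1200 cells per experiment. All sizes are configurable; the defaults
keep a full experiment near ten seconds to generate.

## Segmentation

Nuclei are segmented from the DNA-intercalator channel (`Ir191-DNA`):
Gaussian smoothing (sigma 1 px) of `log1p` counts, a global two-class
Otsu threshold, hole filling, watershed declumping on the Euclidean
distance transform (minima suppression at half the minimum diameter),
and an equivalent-diameter filter of 6-30 px, matching MCF-7 nuclei at
1 um/px. `log1p` is used because Poisson counts are strongly skewed and
Otsu assumes roughly bimodal intensities; thresholding raw counts moves
the cut into the background tail.

Whole cells grow from the nuclei with the classic two-stage strategy:
the foreground is the Otsu-thresholded smoothed cytoplasmic channel
(`pan-keratin`) united with the nuclei, and each foreground pixel is
assigned to a nucleus by intensity-regularized propagation
(`EBImage::propagate()`), the same seeded region-growing used by
CellProfiler's secondary-object identification. This guarantees the
cell/nucleus label bijection and nucleus-inside-cell containment that
downstream bookkeeping relies on, and both are asserted in the tests.
Segmentation quality is scored as pixel-level binary precision and
recall against the ground-truth masks (`overlap_precision()`); on
default synthetic ROIs nuclei precision is ~0.98 and cell precision
~0.91, against acceptance floors of 0.9 and 0.5.

## Quantification and normalization

`extract_features()` reports, per cell: mean intensity of every channel
over the whole-cell mask (one exported mean per marker, not
compartment-restricted), area (pixel count x pixel area), perimeter (the
boundary-pixel contour length from `EBImage::computeFeatures.shape()`),
major/minor axis lengths and eccentricity from the second-moment
ellipse, and the unweighted pixel centroid (0-based, micrometres).
Whether axis lengths should come from the nucleus or the cell object is
ambiguous in general; the cell object is used because cell-size response
(EGF) is one of the planted effects.

`zscore_cells()` standardizes each channel over the pooled comparison
set (not per ROI, so different ROIs share one scale), after clipping
values above the 99th percentile to that percentile. Clipping before
standardization makes the z-scale robust to hot pixels; it is switchable
(`clip_percentile = 100` disables it) because the percentile cutoff is a
display-robustness choice, not part of the statistic. Constant columns
map to all-zero z-scores by convention.

Condition effects are tested per channel with the Mann-Whitney rank-sum
test, two-tailed: exact by enumeration for pooled samples of at most 12
without ties, otherwise the normal approximation with tie and continuity
corrections (the implementation delegates to `stats::wilcox.test`, whose
exact path matches an explicit enumeration oracle in the test suite). An
unpaired Welch t-test is available through the same interface
(`method = "t_test"`) since both tests are in common use for this
comparison; the rank test is the default because per-cell IMC
intensities are heavily skewed. P values are reported raw -- no
multiple-testing correction is applied, and outputs say so -- because
the downstream use is per-channel effect flagging at P < 0.05, not
discovery-set control.

## Embedding

`tsne_embed()` runs Barnes-Hut t-SNE (perplexity 30, 500 iterations) on
the z-scored marker plus size features, initialized from the first two
principal components and fully seeded, so embeddings are reproducible
and invariant to feature column order (features are canonically sorted
internally). Perplexity, iteration count and initialization are not
dictated by anything in the analysis; they are the common defaults, and
are recorded in the result object.

## Fast Gentle Boosting

The classifier is written from scratch: per class (one-vs-rest, targets
in {-1, +1}), a sequence of regression stumps is fit by weighted least
squares. A stump contributes `b + a * (x_j > theta)`; candidate
thresholds are midpoints between consecutive distinct sorted feature
values, `b` is the weighted mean target below the threshold and `a + b`
the weighted mean above, and each round picks the (feature, threshold)
pair minimizing weighted squared error, breaking ties toward the lowest
feature index and threshold so training is deterministic. Weights then
update multiplicatively, `w <- w * exp(-y * f(x))`, and renormalize --
the gentle variant of boosting, whose per-round training exponential
loss is non-increasing (asserted per round in the tests). Scoring sums
the stumps per class and takes the argmax, with ties broken by class
order and a strict `>` at the threshold.

Defaults: 50 rounds, six classes (the five marker-defined nuclear states
plus `negative`), features = all mean intensities plus the four size
parameters, on raw (non-z) values, since stumps are invariant to
monotone per-feature rescaling. Accuracy is estimated by stratified
5-fold cross-validation pooled into a row-normalized confusion matrix;
a permuted-label control in the test suite checks the diagonal collapses
to 1/6, guarding against information leakage. On synthetic data the
training labels come from the generator's truth classes (an interactive
gating UI is out of scope); when training on segmented rather than truth
objects, each segmented cell inherits the truth class at its centroid.

The mitotic index is the fraction of detected cells classified
`pHistone3+`, pooled over the replicate ROIs of each condition.

## Similarity analysis

Within a classified population (canonically the predicted-mitotic
cells), `pearson_matrix()` correlates raw parameter columns across
cells. Raw rather than z-scored values are used because Pearson r is
scale-invariant, which is what makes the statistic applicable to
non-normalized data. Undefined correlations (constant columns) stay
missing rather than being coerced to zero, and clustering refuses to run
until they are resolved, listing the offending pairs. Parameters are
ordered by complete-linkage agglomeration on the distance `1 - r`
(`hierarchical_order()`), exported as a Newick string, and heatmaps are
drawn in leaf order with color limits fixed to [-1, 1].

Comparing parameters *across* conditions is underdetermined because
cells are unpaired. The package's construction
(`cross_condition_similarity()`) pairs cells across conditions by
within-condition quantile ranks of an anchor parameter: the entry
between (A, p) and (B, q) sorts each condition's cells by the anchor,
samples both at a common grid of quantile ranks, correlates the
pseudo-paired vectors, and averages the two anchor choices (p and q) to
make the matrix symmetric. Two properties motivated this choice over
correlating plain per-parameter quantile curves: within one condition it
reduces exactly to the ordinary cell-level Pearson correlation, and a
condition compared against a copy of itself reproduces its own
within-condition block -- plain quantile curves satisfy neither (any two
monotone curves correlate near 1, which flattens the whole matrix). The
construction is isolated behind this one function and can be swapped
without touching the rest of the analysis.

`edge_bundle_graph()` keeps edges with r strictly above 0.3 (an
`r = 0.3` tie draws no edge) and exports node-link JSON and GraphML for
external bundled-layout rendering; no interactive rendering is bundled.

## Pipeline, seeds, and numerical conventions

`run_pipeline()` validates a YAML/list config fail-fast (unknown keys
are errors), executes the stages in order, and writes a manifest with
the config hash, seed, per-ROI object counts (cell-table rows must equal
cell-mask labels), and a checksum of every numeric artifact; two runs
with the same config are bit-identical. One master seed fans out to
per-stage, per-ROI child seeds by hashing `(seed, stage, roi_id)` into a
32-bit stream (`derive_seed()`), so any stage can be re-run in isolation
with the same draw.

Conventions worth pinning: images are H x W matrices with x = column,
y = row, 0-based pixel-centered coordinates in micrometres; channel
order is panel order everywhere and is never reordered on read; 16-bit
TIFFs store exact integer counts (overflow above 65535 is an error,
never a silent clip) while 32-bit TIFFs store floats against a recorded
scale; masks persist as unsigned 16-bit TIFFs, capping labels at 65535
per ROI; measurement tables persist as CSV (portable and diffable, with
the same per-object schema as a measurements database). Degenerate
inputs resolve as: blank images segment to empty masks (not errors),
empty masks quantify to empty tables, constant columns z-score to zero
but correlate to missing.

## Problem sizes and limitations

The bundled experiment sizes (500 x 500 um ROIs, 600 cells/mm^2, eight
ROIs, ~1200 cells; 5-fold cross-validation at 50 boosting rounds) are
the package's defaults for a complete desk-scale analysis; a full run of
the test suite and the acceptance computation completes in a couple of
minutes on one core. Known limitations: no deep-learning segmentation
and no optimization for densely packed tissue sections (the secondary
stage assumes monolayer geometry); no spillover compensation; no MCD
vendor-format ingestion (TIFF stacks are the boundary); t-SNE only (no
UMAP); no multiple-testing machinery; and the cross-condition similarity
construction, while internally consistent, is one of several defensible
definitions for unpaired populations.
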