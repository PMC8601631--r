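---
title: "Evaluating cell instance segmentation for quantitative wood anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cell instance segmentation for quantitative wood anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qwaseg)
```

## The measurement problem

Quantitative wood anatomy (QWA) extracts cell-level measurements — above all
the lumen area of tracheids and vessels — from transversal section images.
Automated segmenters (classical image analysis or neural networks) produce a
label map: every pixel either background or one of N detected cells. Judging
such output needs two distinct levels:

* **instance level** — was each true cell detected at all? Pixel-wise scores
  hide instance errors: a segmenter that finds 95% of the lumen *pixels* may
  still have missed every small latewood cell.
* **pixel level** — for each detected cell, how accurately was its lumen
  delineated? Instance counts hide systematic under- or over-estimation of
  areas, which propagates directly into derived quantities such as
  theoretical hydraulic conductivity.

Both levels use precision, recall and F1:

$$\mathrm{Recall} = \frac{TP}{TP+FN}, \qquad
  \mathrm{Precision} = \frac{TP}{TP+FP}, \qquad
  F1 = \frac{2 \cdot \mathrm{Precision} \cdot \mathrm{Recall}}
            {\mathrm{Precision}+\mathrm{Recall}}.$$

True negatives are deliberately absent: there is no census of "all cells
that are not target cells" in a wood section, so a TN count at the instance
level is undefined. When a denominator is zero the corresponding statistic
is defined as 0 (conservative: an empty prediction scores 0, not 1).

## Instance matching

`match_instances()` assigns every cell of the ground truth and the
prediction to exactly one category:

1. **Border exclusion.** Cells touching the outermost pixel frame are
   *incomplete*: their true extent is unknowable, so they are excluded from
   all counts. Predictions touching the frame, or with the majority of their
   own pixel mass inside an excluded cell, are excluded symmetrically —
   border clipping must never manufacture false positives.
2. **Greedy IoU matching.** Candidate pairs with intersection-over-union at
   or above the threshold τ are accepted in descending IoU order,
   one-to-one. At the default τ = 0.5 a cell can exceed the threshold with
   at most one prediction (two disjoint predictions cannot each cover more
   than half of the union), so the greedy result provably equals the
   exhaustive optimal assignment; the suite verifies this against a
   brute-force matcher on hundreds of random maps.
3. **Split detection** (*disconnected positive*): an unmatched cell covered
   jointly (union IoU ≥ τ) by ≥ 2 unmatched predictions, each with more
   than κ of its own area inside the cell, is one cell detected as several:
   the fragments count FP, the cell counts FN.
4. **Merge detection** (*merged negative*): the mirror image — one
   prediction jointly covering ≥ 2 cells, each majority-inside it: the cells
   count FN, the prediction FP.
5. Remaining cells are *missed* (FN); remaining predictions *spurious* (FP).

Ties are broken by ascending ids, so results are bit-for-bit reproducible.

Two parameters matter. τ (`iou_threshold`, default 0.5) is the matching
strictness; 0.5 is the conventional choice that guarantees unique matches.
The per-cell reports of the source workflow, however, contain matched pairs
with pixel IoU well below 0.5 (recall 0.28 implies IoU ≤ 0.28), so for
reproducing such per-cell tables a laxer threshold (0.1) is appropriate; the
package treats τ as an explicit analysis choice rather than hard-coding
either. κ (`containment_fraction`, default 0.5) is the majority rule in
split/merge detection; values above 0.5 make fragment sets smaller, values
below admit marginal fragments.

## Per-cell lumen-area accuracy

For each matched pair, pixels in both lumina are TP, prediction-only pixels
FP, ground-truth-only pixels FN; `tp + fn = gt_area` and
`tp + fp = pred_area` hold identically. The canonical per-cell report
columns are Area, Prediction, TP, FP, FN, Precision, Recall, F1:

```{r table4}
gt <- matrix(0L, 60, 80); gt[6:40, 6:54] <- 1L            # 1715-px cell
pred <- matrix(0L, 60, 80)
pred[6:15, 6:53] <- 1L; pred[16, 6:7] <- 1L               # 482-px subset
res <- match_instances(gt, pred, match_config(iou_threshold = 0.1))
round(cell_pixel_metrics(gt, pred, res), 2)
```

High precision with low recall marks an underestimated lumen; the converse
an overestimated one. Arithmetic is kept at full floating precision
internally; rounding to two decimals happens only in display and reports.

Aggregation over images is ambiguous in the field's reporting ("average"
without a stated weighting), so all three modes are explicit:
`macro` (unweighted mean of per-image statistics), `micro` (statistics of
pooled counts) and `per_cell` (mean over matched cells). They genuinely
differ whenever image difficulty varies. Two summaries support model
comparison: `high_accuracy_fraction()` (share of matched cells with F1 ≥
0.9) and `fn_size_histogram()` (missed cells binned by lumen area — small
latewood cells are typically the most affected class). Histogram bins
default to 10 equal-width classes over the observed area range; quantile
binning is available when area distributions are heavy-tailed.

## Error maps

`render_error_map()` colours every instance and every pixel of matched
cells: light green TP, dark green FN and orange FP pixels; blue missed
cells; red spurious predictions; magenta split fragments; cyan merged
cells; gray incomplete cells. The anchored choices are the FN/FP pixel
colours and the blue FN fill; the remaining colours are this package's
defaults and are configurable per category. Painting precedence (later
wins): incomplete → spurious/merged predictions → missed cells and split
victims → split fragments → merged cells → per-pixel classes. With that
order an unblended render is *exactly* auditable: `color_census()` counts
pixels per category and the suite reconciles every count against the
metric sums. Blending over the base image (alpha 0.6) is for human eyes
only — the census refuses blended renders.

## Tiled inference and the dual-scale merge

Backends see fixed-size tiles (default 1000 × 1000 px; the ring-porous
preset 2000 × 3000 px so large earlywood vessels fit a tile). Tiles overlap
by 100 px by default — roughly the largest conifer tracheid diameter at
typical QWA image scales — so every cell lies wholly inside at least one
tile unless it is larger than the overlap. Stitching keeps instances that
are whole in some tile verbatim, deduplicates double detections in overlap
zones (IoU ≥ 0.5 keeps the higher confidence), and resolves tile-clipped
instances by preferring a tile that contains the cell fully, else merging
the clipped pieces by pixel union.

Ring-porous wood needs two scales: latewood vessels are an order of
magnitude smaller than earlywood vessels. The dual-scale scheme runs the
backend a second time on the image downscaled by 2 (same tile size, doubled
field of view), upscales the result, and merges: fine-pass instances below
the size gate plus coarse-pass instances at or above it, with cross-pass
duplicates resolved by confidence and a fine-pass fallback so that a failed
coarse pass never silently drops large cells. The merge rule is this
package's own definition — how the original dual-network outputs were
combined is not documented anywhere we could follow — and it is therefore
stated, parameterized (`size_gate`, `dedup_iou`, `scale_factor`) and tested
against planted vessel counts rather than asserted as anyone else's rule.

`baseline_segment()` provides a weights-free reference backend: automatic
luminance threshold → morphological opening (radius 2) → distance
transform → watershed → area filter, with the normalized distance peak as
confidence. Because wood-section luminance is trimodal (dark walls,
mid-tone tissue, bright lumina) and plain Otsu picks the wall-vs-rest
split, the automatic threshold applies Otsu a second time within the upper
class whenever that class is itself clearly spread out; on genuinely
bimodal images it reduces to plain Otsu. It is a genuine classical segmenter — good enough to exercise
the pipeline end-to-end on synthetic scenes (instance recall ≥ 0.9 on clean
conifer renders is a regression bar of this package, not a claim about real
slides) — and deliberately not a reimplementation of any published tool.

## The synthetic generator and its oracle

`generate_scene()` renders caricature sections for four porosity types:
conifer tracheid lattices whose lumen width shrinks monotonically from
earlywood to latewood within each ring; diffuse-porous fields of uniform
round vessels; semi-diffuse fields with a gradual size transition;
ring-porous rings with a distinct large-vessel row plus scattered small
latewood vessels. Non-targets (rays, pits, resin canals, fiber speckle,
scalariform bars across a vessel) are drawn in the image but never in the
label map — the ground truth marks true target lumina only. Rendering is
dark walls / bright lumina / mid-tone tissue with additive Gaussian noise
(σ = 3 channel units): sufficient contrast structure for a thresholding
baseline, deliberately not photorealistic histology. Consequences for
interpretation: passing tests show the *evaluation machinery* is exact and
the *pipeline plumbing* is consistent; they do not show that any segmenter
generalizes to real slides, where staining variability, out-of-focus
regions and touching lumina are far harsher.

`inject_artifacts()` corrupts the image (dust, folded tissue, stains,
paraffin drops, broken walls, blur, illumination gradients) inside recorded
regions while never touching the label map, mirroring the premise that
ground truth marks true lumina regardless of image quality.

`perturb_labelmap()` is the evaluator's exact oracle: it derives a
prediction whose error categories are known *by construction* —
deletions, spurious background blobs (≥ 2 px clearance from any cell),
splits, merges, erosions and dilations applied to disjoint cell subsets.
The construction is engineered so classification at τ = κ = 0.5 is
unambiguous: split fragments are capped at 0.45 of the parent area (no
fragment alone reaches IoU 0.5, while the fragment union always does);
merge partners are chosen with *equal* pixel areas, which makes the merged
blob's IoU with either partner strictly below 0.5 — a 2:1 size ratio, the
loosest bound one might hope for, does **not** guarantee this (the larger
partner alone can exceed IoU 0.5 with the union), so the generator
restricts itself to the equal-area case rather than emit a probabilistic
oracle; erosion/dilation accepts a cell only if the perturbed cell stays
safely matched (area ratio ≥ 0.55) and connected, and dilation grows into
free background only, never into other cells. Infeasible plans (more
perturbations than interior cells, no bridgeable equal-area pair) fail with
an error instead of degrading silently. The central guarantee — evaluator
category counts equal planned counts exactly — is tested over a hundred
seeded scene/plan combinations and holds with zero mismatches.

## Numerical and format choices

* Coordinates are 0-based (x = column, y = row, origin top-left) in all
  user-facing tables; bounding boxes use inclusive min/max.
* Connected components default to 8-connectivity (hand-drawn annotation
  strokes produce diagonal bridges); 4-connectivity is available. Ids are
  assigned in raster-scan order, making every labelling deterministic.
* Label maps are stored as 16-bit single-channel TIFF: lossless for up to
  65535 instances and round-trip exact. (R's PNG bindings write 8-bit
  only, which would corrupt ids above 255; TIFF avoids per-file bit-depth
  surprises at identical capacity.) Binary-mask annotations are read from
  PNG, with an alpha channel taking precedence over luminance when present
  — masks drawn on a transparent layer carry their information in alpha.
* Reports export as CSV (one file per table) and JSON (single lossless
  round-trip file). Spreadsheet-native export was considered and dropped:
  CSV opens in every spreadsheet tool without an extra dependency.
* The per-cell table's display convention is two decimals; stored values
  are full precision.

## Problem sizes in the test-suite and acceptance script

The property suites run on compact scenes — conifer lattices of 2 rings ×
6 cells × 6 files (72 cells, ~130 × 190 px) for oracle closure (100
scene/plan pairs), duality (50), conservation (12) and census
reconciliation (20); 200 random rectangle maps with ≤ 8 instances per side
for matcher optimality; 2 × 8 × 10-cell scenes with 160 × 160/30-overlap
tiles for pipeline consistency (20). These sizes were chosen so each
property is exercised across hundreds of distinct geometric configurations
while the whole suite stays interactive; all guarantees checked are
size-independent identities, so small scenes lose no generality.

## Known limitations

* The matcher's split/merge rules are operational definitions of this
  package; their parameterization (τ, κ) is exposed precisely because the
  field has no single quantified convention.
* Duality (gt/pred swap symmetry) is exact for the evaluation categories;
  with border exclusion active it additionally requires border cells to
  coincide in both maps, which holds in the perturbation setting but not
  for arbitrary map pairs.
* The synthetic renderer does not model touching lumina (cells are always
  separated by at least a wall pixel), so it cannot exercise a backend's
  ability to split merged *true* contacts — only the evaluator's handling
  of merged *predictions*.
* `aggregate_summary()` offers three weightings because published "average"
  tables rarely state theirs; cross-study comparisons should state which
  mode they used.
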