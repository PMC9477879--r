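---
title: "Quantifying hypoxia-Treg spatial interplay in DCIS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hypoxia-Treg spatial interplay in DCIS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ductcoloc)
```

## The scientific question

Ductal carcinoma in situ (DCIS) is a pre-invasive breast lesion confined
within duct basement membranes. Hypoxia — read out by carbonic anhydrase IX
(CA9) staining of epithelial cells — is thought to recruit regulatory T
cells (Tregs, marked by nuclear FOXP3) and thereby shape an
immunosuppressive microenvironment that may license progression to
invasive ductal carcinoma (IDC). The quantitative question is spatial:
*are FOXP3+ lymphocytes preferentially colocated with CA9+ epithelial
cells, and does that colocalization differ between pure DCIS, the
synchronous DCIS ducts of mixed IDC/DCIS sections, and the invasive
component itself?*

`ductcoloc` implements the analysis layer of that question for single-cell
maps: each cell is a point in microns with one of five classes (CA9+/−
epithelial, FOXP3+/− lymphocyte, stroma), and duct regions are polygon
masks. Everything upstream of that table — staining, scanning, deep
learning detection/classification/segmentation — is out of scope; the
package instead ships the evaluation metrics used to validate such
upstream stages, and a synthetic tissue generator so the whole pipeline is
testable without slide data.

## Colocalization model

### Morisita–Horn over Voronoi quadrats

Colocalization of two cell classes is measured by the Morisita–Horn
overlap index on per-quadrat counts. With counts $x_i$, $y_i$ in quadrat
$i$ and totals $X=\sum_i x_i$, $Y=\sum_i y_i$:

$$
MH(x, y) \;=\; \frac{2\sum_i x_i y_i}
{\left(\dfrac{\sum_i x_i^2}{X^2} + \dfrac{\sum_i y_i^2}{Y^2}\right) X\, Y}
\;\in\; [0, 1],
$$

0 meaning complete spatial segregation (disjoint quadrat support) and 1
maximal colocalization (exactly proportional counts). The quadrats are
Voronoi polygons: the number of seeds is the **cube root of the number of
cells in the region of interest**, and the seeds themselves are the
k-means centroids of the cell coordinates. The cube-root rule fixes only
the seed *count*; seed *placement* is a design choice here, and k-means
centroids were preferred over uniform-random seeds because they adapt
quadrat size to cell density and are reproducible under a fixed seed
(uniform seeds add pure Monte-Carlo variance to the index).

Numerical details that matter:

* the index is evaluated in an integer-product form,
  $2 S_{xy} X Y / (S_{xx} Y^2 + S_{yy} X^2)$, so with count data the
  extremes 0 and 1 are attained *exactly* and the index is exactly
  symmetric in its arguments;
* `seed_count(n)` rounds $n^{1/3}$ to the nearest integer (half away from
  zero) with a floor of 2; fewer than two cells cannot be partitioned and
  return 0, which callers must treat as a degenerate input;
* Voronoi cells are built by half-plane clipping of a convex ROI, so
  polygon areas sum to the ROI area to floating-point accuracy, and each
  cell is assigned to its nearest seed (ties broken by lowest polygon id);
* the default ROI is the convex hull of all cells buffered by 50 µm —
  sections usually arrive without a tissue outline, and the hull-plus-margin
  is a neutral stand-in;
* an absent population ($X=0$ or $Y=0$) yields a flagged `NA`, never an
  exception.

### Abundance

Two abundance fractions accompany every index: FOXP3+ lymphocytes over all
lymphocytes, and CA9+ epithelial cells over all epithelial cells. (The
CA9+ numerator is epithelial by definition; both ratios live in $[0,1]$
and a zero denominator is a flagged null.)

## Component typing in IDC/DCIS sections

Pure DCIS sections get one index per class pair over the whole section.
IDC/DCIS sections are split into components first: the section is
tessellated once, and every Voronoi polygon is typed

* **synchronous DCIS** — composed essentially only of duct content;
* **IDC** — composed predominantly of invasive epithelial cells;
* **mixed** — the DCIS/IDC interface;
* **excluded** — polygons holding no epithelial cells (stroma, artifact,
  empty space), which enter no component.

Typing is by the *composition of a polygon's epithelial cells*: the
fraction $f$ of them lying inside duct polygons, with
$f \ge 0.9 \Rightarrow$ synchronous DCIS, $f \le 0.1 \Rightarrow$ IDC,
otherwise mixed. A purely geometric criterion (fraction of polygon *area*
covered by ducts) was considered and rejected: Voronoi quadrats at
cube-root seed counts are the size of a duct or larger, and even a quadrat
snugly circumscribing a round duct caps below ~91% duct area (the
circle-packing bound), so an area threshold of "mostly duct" can never
fire reliably. Composition-of-content is also what the biological
definition of the components describes. The geometric duct-area fraction
is still computed per polygon — by exact Sutherland–Hodgman clipping of
the duct polygons against each convex quadrat — and reported alongside,
because it is the natural quantity for maps and audits. Both fractions are
monotone inputs to the same rule: raising a polygon's in-duct fraction can
only move it toward synchronous DCIS.

Each pair's index is then computed twice, over the synchronous-DCIS
quadrats and over the IDC quadrats, *filtering* the shared tessellation
rather than re-tessellating per component — this keeps quadrat identity
consistent with the typed map (a `retessellate` switch provides the
alternative). Mixed and excluded polygons contribute to neither component.

**Minimum-data rule.** A component with fewer than 50 cells or fewer than
two quadrats yields a flagged null index for all pairs. Nulls are dropped
(never zero-filled) in group statistics. This operationalizes the
exclusion of sections lacking sufficient synchronous DCIS; the published
analysis excluded such sections without quantifying the cutoff, so the
50-cell floor is this package's choice, switchable via `min_cells`.
Whether mixed polygons should count toward either component is likewise
not settled by the source material; they are excluded from both here.

## Group comparisons

Per-section indices are compared across the three groups (pure DCIS,
synchronous DCIS, IDC) with pairwise Wilcoxon rank-sum tests — exact for
small tie-free samples, tie-corrected normal approximation otherwise (the
`stats::wilcox.test()` default) — and Holm step-down adjustment. The Holm
family is the three group contrasts within one class pair, matching the
row-wise layout in which such results are reported; a joint family across
all class pairs is available by calling `pairwise_wilcoxon_holm()` on the
stacked table.

Covariate adjustment (`adjusted_difference()`) fits an ordinary linear
model `outcome ~ group + covariates` and reports the group coefficient's
p-value; the published analysis names "multivariate regression tests"
without specifying the form, so the linear model is the default and a
rank-transformed variant (`method = "rank"`) is provided for skewed
indices.

## Evaluation metrics

The metrics used to validate upstream deep-learning stages are
self-contained arithmetic and are implemented exactly:

* **Detection** (`match_detections`): predicted and true cell centres are
  matched one-to-one within a radius (default 10 µm ≈ a nucleus diameter
  at 0.5 µm/px) by maximum bipartite matching, so the TP count is optimal
  and order-independent; precision, recall and F1 follow from the counts
  at full precision, rounded only for presentation (half away from zero,
  2 d.p.). Note one published detection row prints precision 0.74 while
  its own counts give 3591/4791 = 0.7495 → 0.75; the package reports the
  recomputed value.
* **Segmentation** (`mask_metrics`): pixelwise Dice, precision,
  recall (= sensitivity) and specificity; vector masks are rasterised at a
  declared resolution first.
* **Classification** (`classification_metrics`): 5×5 confusion counts,
  per-predicted-class correct percentage (diagonal over column sum) and
  overall accuracy.
* **CA9 cross-tab** (`ca9_bin_crosstab`): per-section CA9+ abundance
  binned at the percent scale into $[0,1]$, $(1,5]$, $(5,100]$ — half-open
  upward so every value falls in exactly one bin — against the
  pathologist's Positive/Negative score, with row percentages rounded to
  the nearest integer.

## The synthetic tissue generator

`simulate_section()` generates ground truth with controllable structure:

| parameter | default | meaning |
|---|---|---|
| `field_width/height` | 2000 µm | section extent |
| `n_ducts`, `duct_radius_range` | 8, 120–220 µm | duct polygons (ellipses, optionally lobed), rejection-sampled to non-overlap |
| `n_epithelial / n_lymphocyte / n_stroma` | 1800 / 1700 / 260 | class totals at the annotation-set proportions (epithelium 46%, lymphocytes 47%, stroma 7%) |
| `ca9_pos_fraction` | 0.257 | CA9+ share of epithelium |
| `foxp3_pos_fraction` | 0.087 | FOXP3+ share of lymphocytes |
| `hypoxia_focality` | 3 | CA9+ foci; labels go to the epithelial cells nearest a focus, making hypoxia focal rather than salt-and-pepper |
| `attraction` | 0 | FOXP3+/CA9+ coupling strength |
| `invasive_fraction` | 0.5 (IDC/DCIS) | epithelial share placed in the invasive zone; forced to 0 for pure DCIS |

The attraction mechanism is a mixture, not a pairwise interaction process:
each FOXP3+ lymphocyte is drawn with probability
$w = \text{attraction}/(1+\text{attraction})$ from a Gaussian kernel
(s.d. 50 µm) centred on a random CA9+ cell, otherwise from the uniform
lymphocyte field. At `attraction = 0` FOXP3+ placement is exactly
independent of CA9 status, and the expected FOXP3+/CA9+ index is
non-decreasing in `attraction` — both are property-tested. In IDC/DCIS
sections the ducts occupy the left 45% of the field and invasive
epithelium the right 45%, emulating a duct region adjacent to an invasive
front with a clean interface; duct placement progressively prefers smaller
radii when the field is crowded, so dense layouts mix duct sizes and
always terminate.

`degrade_detections()` turns ground truth into synthetic detector output
(independent dropout, isotropic positional jitter, binomial spurious
detections, optional label confusion) so the detection/classification
metrics can be exercised against known error rates.

**What the generator does not emulate.** Real sections have irregular
tissue outlines, duct morphologies (cribriform/solid/comedo/papillary)
with internal texture, spatially varying cell density, and detector errors
correlated with staining artifacts. Passing tests on this generator
therefore demonstrate correctness of the *statistical machinery* —
count conservation, routing of in-duct cells, monotone response to a known
attraction, nominal test levels — not fidelity of any biological effect
size. No quantitative duct size/density distribution was available to
match; defaults were chosen once for visual and magnitude plausibility.

## Problem sizes and determinism

Simulation-based tests run sections of roughly 600 epithelial + 500
lymphocyte + 90 stromal cells (about 1200 cells, 11 quadrats), with 100
paired replicates for the attraction-recovery experiment and 15 sections
per group for the end-to-end group test — sizes at which every experiment
is reproducible in seconds while leaving the asserted effects far from
marginal. All randomness flows through explicit integer seeds
(`withr::with_seed`), so sections, tessellations and whole pipeline runs
are bit-identical given the same configuration; the run manifest records
the seed and a configuration hash.

## Known limitations

* Quadrat counts at cube-root seeding are few (a 1,000-cell region has 10
  quadrats), so single-section indices are noisy by construction; the
  method is designed for cross-section group comparisons.
* The Voronoi ROI is convex; strongly concave tissue regions will include
  empty space in boundary quadrats.
* Component typing requires epithelial cells in a polygon; a duct region
  detected by the mask but containing no classified epithelial cells is
  excluded rather than synchronous.
* The GeoJSON reader validates and trivially repairs rings (duplicate
  vertices, winding, unclosed rings) but rejects self-intersecting
  exteriors rather than attempting polygon surgery.
* `mask_from_labels()` traces pixel-boundary contours, so areas are exact
  pixel areas; sub-pixel smoothing is deliberately not applied.
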