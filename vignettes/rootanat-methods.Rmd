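---
title: "Methods: automated tissue morphometry of root cross sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tissue morphometry of root cross sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootanat)
```

## The problem

Quantifying root anatomy -- how many cells each tissue holds, how large
and how elongated they are, how traits change with radius -- normally
means hand-labelling every cell in stained cross-section micrographs.
`rootanat` automates the whole chain for cereal roots: segmentation of
the cell-wall network, detection of every enclosed cell, rule-based
classification into epidermis, cortex, endodermis, stele and metaxylem
(plus protoxylem and aerenchyma in maize), and primary and radial
morphometric statistics. The design premise throughout is that
classification should rest on *a-priori anatomy* (relative cell sizes
and positions) rather than on staining intensity, which varies wildly
between preparations.

## Segmentation model

Intensities are first min--max normalized to $[0,1]$. A pixel is
compared with the mean of the $(2w+1)\times(2w+1)$ window centred on
it:

$$\hat I = I - (I \star M), \qquad
(I \star M)(x,y) = \frac{1}{(2w+1)^2}\sum_{i=x-w}^{x+w}\sum_{j=y-w}^{y+w} I(i,j),$$

and is declared a wall (foreground) pixel when $\hat I > T$ (strict
inequality). Because only the *local* deviation matters, the rule is
invariant to any smooth illumination field and to adding a constant to
the image -- exactly the situations in which a single global (Otsu)
threshold collapses. Stained walls are darker than the background in
these micrographs, so the pipeline applies the rule to the negated
image by default (`polarity = "dark_walls"`; a flag covers the
opposite convention).

Numerical choices:

* **Borders.** The window is truncated to its intersection with the
  image and normalized by the number of pixels actually present. A
  fixed $1/(2w+1)^2$ normalization would darken the border frame and
  create a spurious foreground rim.
* **Implementation.** Integral images (running sums), so runtime is
  independent of `w`; the result matches a direct double-loop
  evaluation to $10^{-9}$, which the test suite asserts.

## Cell detection

The binary mask is dilated with a $2\times2$ all-ones kernel anchored
at its top-left element, closing 1--2 px leaks in walls without
destroying the smallest stele cells. Every 4-connected background
component that does not touch the image border is one cell interior
(border components are the outer background and unmeasurable partial
cells). Boundaries come from contour tracing of each component.

Because the anchored dilation grows walls only rightwards and
downwards, it steals a one-pixel rim from the top/left sides of every
interior, a $\sim$10--15% area bias for stele-scale cells. Cell pixels
are therefore *reclaimed*: pixels that were background before dilation
and are adjacent to the component on the stolen sides are returned to
it before areas are measured. With this correction the per-cell area
error on synthetic ground truth is well under 1%.

Dark lateral-root formations attached to the section get detected as
cells; any region whose mean interior intensity falls below one third
of the mean over all regions is removed. The boundary segments of the
surviving outermost cells, together with the wall foreground, form the
initial root boundary $\Gamma_{ini}$ (outer contour of the largest
filled component).

**Recovery pass.** Faintly stained or perforated walls let a cell's
interior leak into the background: the cell is missing from the first
pass and lies outside $\Gamma_{ini}$. The image is re-segmented at
$T/2$ -- far too noisy for direct use -- and a relaxed-pass region is
promoted only when it contains a peak of the first-pass Euclidean
distance transform that lies outside $\Gamma_{ini}$: a cell-scale
cavity the first pass failed to enclose. Peaks are 8-neighbourhood
regional maxima (plateaus included) at least $\sqrt{A_s/\pi}/2$ px
high, i.e. half the radius of the smallest admissible cell. An
explicit h-maxima suppression step would only merge near-equal maxima;
since peaks act purely as membership tests (never counts), plain
regional maxima give the same promotions at lower cost. No first-pass
cell is ever removed, and the boundary is recomputed as
$\Gamma_{final}$ afterwards.

## Classification cascade

All stages are deterministic; ties are broken by ascending cell id.

1. **Epidermis.** Cells on the root perimeter (contour within
   `perimeter_margin` = 6 px of the outer background, about twice the
   wall thickness) are sorted by increasing area; the first 80%
   (`epidermis_fraction`) are epidermis, the rest cortex. The
   percentile rule tolerates the large size variation of epidermal
   cells; its price is that on a perfectly intact root
   $\lceil 20\% \rceil$ of true epidermal cells are called cortex, a
   bounded and known cost visible in the synthetic benchmarks below.
2. **Area classes.** Non-epidermal cells below $A_s$ (50 px$^2$) are
   segmentation noise and leave the analysis; $[A_s, A_l)$ is "small"
   (stele/endodermis scale), $\ge A_l$ (1000 px$^2$) "large" (cortex
   scale). The defaults are for $\sim$1024$^2$ images; both gates
   scale with resolution, the ratio $A_l = 33 A_s$ is a serviceable
   first approximation when only $A_s$ is known, and
   `suggest_A_l()` maps root diameter to $A_l$ via the calibrated
   quadratic $0.0004 d^2 + 0.668 d - 112$ (floored at $A_s$, where the
   polynomial goes negative).
3. **Small-cell cluster.** The small cells' centre of mass
   approximates the stele centre. Their centroid-distance distribution
   is cut by Otsu's method; when the two sides are well separated
   (gap above a quarter of the lower mode's span, and at least 2 px)
   the far mode -- stray small cells in the cortex -- is discarded
   before a normal distribution is fitted (maximum likelihood =
   mean/sd). Cells within $\mu + 3\sigma$ form the stele/endodermis
   candidate cluster.
4. **Metaxylem.** A cell is metaxylem if (a) its centroid lies within
   the *mean* member distance $\mu$ of the cluster centre (metaxylem
   sit near the centre of mass; the $\mu+3\sigma$ extent would reach
   the first cortex ring in an annular tissue layout), (b) all of its
   `k_neighbors` = 5 nearest cells are cluster members or fellow
   candidates ("completely surrounded by small cells"), and (c) it is
   a large-class cell whose area exceeds the member mean by two
   standard deviations. Among candidates, only those within 70% of
   the largest are kept: polyarch metaxylem vessels are mutually
   similar in size, and the homogeneity gate stops smaller vessels
   (protoxylem) at metaxylem-like radii from being absorbed. With
   $\sim$100 cluster cells the $2\sigma$ rule alone always admits a
   couple of jitter outliers, which is why (c) also demands the large
   size class. The metaxylem's area-weighted centre of mass becomes
   the stele centre (cluster centroid as fallback).
5. **Stele candidates.** Every small cell within the cluster extent
   is kept when the distance to the farthest of its 5 nearest small
   cells is at most `neighbor_dist_max` = 50 px; with fewer than 6
   small cells, all available neighbours are used. Everything else
   becomes a cortex candidate.
6. **Refinement.** The approximate endodermis boundary is the outer
   contour of the morphological closing (disc radius
   `neighbor_dist_max`/2) of the candidate union. Then: (i) large
   non-metaxylem cells entirely inside it join the stele set; (ii)
   cells with eccentricity above `ecc_min` = 0.9 whose *centroid* is
   within `boundary_margin` = 10 px of the boundary join too (the
   centroid convention is a choice; the alternative -- nearest
   boundary point -- would loosen the rule by half a cell size);
   (iii) candidates whose nearest cells are mostly cortex (fraction
   > 0.5, votes counted on a snapshot) are handed back.
7. **Endodermis.** Set members whose boundary touches the outer
   contour of the set's union region (within the wall-scale tolerance
   `perimeter_margin`) are endodermis -- the outermost single layer --
   and the rest are stele. A single-member set is endodermis.

**Maize extension.** Large stele cells that are not metaxylem are
protoxylem candidates; the ray from the stele centre through the
candidate's centroid is extended to the stele boundary, and candidates
more than half way along (a scale-invariant ratio of collinear
distances) are protoxylem. Aerenchyma: the areas of large cortex cells
are fitted with a two-component Gaussian mixture and cells above
$\mu_{larger} - \sigma_{larger}$ are relabelled. The EM fit is
deterministic (quartile k-means initialisation, variance floored at
$10^{-3}$ of the data range so singleton components stay finite);
means closer than one pooled standard deviation are treated as
unimodal and no aerenchyma is reported. The general-purpose mixture
packages' default initialisations proved fragile exactly in these
degenerate regimes, so the forty-line EM is part of the package and
fully unit-tested.

## Morphometrics

Eccentricity uses the direct algebraic least-squares ellipse fit
(Halir--Flusser's numerically stable formulation), with the
second-moment ellipse as fallback for degenerate systems;
$E = \sqrt{1 - b^2/a^2}$. Per-tissue statistics convert pixels to
microns only at reporting time (areas by `scale`$^2$). The stele's
*total* area is the area enclosed by the outer endodermis contour --
walls included, matching the visual extent of the vascular cylinder --
while all per-cell areas exclude walls; the convention is stated in
the output header. When a region holds a single cell (the one central
metaxylem of a wheat primary root), "mean" fields are simply that
cell's values.

The "cheesewheel" partitions the stele zone (centre to endodermis
contour) and the cortex zone (endodermis contour to root boundary)
into 6 annuli $\times$ 6 wedges. Annuli interpolate linearly between
the bounding contours along each ray from the stele centre, so they
follow non-circular roots; wedges are 60 degrees of *angle* (not arc
length), anchored at image east and counted counter-clockwise -- both
conventions are arbitrary and fixed. Cells are assigned by centroid,
giving a clean partition of each zone.

## The synthetic generator

`generate_root()` renders what the classifier assumes and the
micrographs exhibit: concentric tissues (a ring of small epidermal
cells, rings of large cortex cells, a flat endodermal ring, a stele
packed with small cells, one central or several orbiting metaxylem),
dark 2 px walls at weak contrast (0.15 against a 0.8 background --
poor staining is the regime the local threshold exists for), an
illumination field made of a linear diagonal ramp plus a large smooth
dark region overlapping one side of the root (the classic global-
threshold failure mode; a ramp alone leaves Otsu's cut inside the
background mass and walls fully recalled), and additive Gaussian
noise. Cells are angularly jittered ring sectors -- the statistical
geometry matters, not growth realism. Ground truth (per-pixel label
image, per-cell tissue table, boundaries, census) is exact by
construction.

Boundary breaks emulate locally failed staining: selected epidermal
cells get a 3--5 px arc of their outer wall re-rendered at contrast
0.06, which fails $T = 0.05$ after local-mean suppression but passes
$T/2$ -- precisely the regime the recovery pass targets. Two-pixel
gaps are closed by the 2$\times$2 dilation by design and cannot
produce a missed cell, so they are not generated; and whenever breaks
are enabled one 5 px break is guaranteed, so recovery always has at
least one genuinely recoverable cell to find. What the generator does
*not* emulate: photorealistic staining texture, sectioning artefacts,
torn or displaced tissue, and root fragments fully separated from the
main body (a known, unsolved failure mode of the boundary estimate).
Passing tests therefore demonstrate correctness of the *rules* under
the stated anatomical assumptions, not robustness to gross specimen
damage.

Default study conditions: wheat roots of radius 190 px (408$^2$
images) with ~190 cells (60 epidermis, 25 cortex, 26 endodermis, ~80
stele, 1 metaxylem of radius 22 px); maize roots of radius 260 px
(548$^2$) with ~390 cells, six metaxylem of radius 28 px on an orbit
at 0.6 of the stele packing radius, protoxylem of radius 22 px, and
six aerenchyma formed by merging adjacent cortex cells. The validation
suite runs 20 wheat seeds for classification, 10 + 10 for detection
and recovery, and 3 for segmentation recall -- sizes chosen so the
whole suite completes in about half a minute while keeping every
proportion of the full-scale images.

## Known limitations

* On a fully intact root the 80% percentile rule misclassifies about
  a fifth of the epidermis as cortex by construction; on the default
  synthetic roots this is the dominant error term (accuracy ~94%, of
  which ~6 points are exactly these cells).
* The metaxylem homogeneity gate assumes vessels within a root differ
  by less than ~30% in area; strongly heterogeneous vessel sizes
  would require loosening it.
* Tissue regions are assumed concentric and star-shaped around the
  stele centre (radius-by-angle interpolation); strongly lobed or
  fragmented roots violate this.
* Lateral-root blobs suppress the local contrast of adjacent epidermal
  walls; cells in their shadow can be lost even though the blob itself
  is filtered out.
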