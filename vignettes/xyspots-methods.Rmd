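---
title: "Methods: quantifying spatial X/Y gametolog dimorphism from RCA spot images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spatial X/Y gametolog dimorphism from RCA spot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

X-chromosome genes with Y gametologs (PCDH11X/PCDH11Y, NLGN4X/NLGN4Y) are
too similar for conventional in situ hybridization: isoforms share roughly
89–99 % sequence identity, so probes cross-react. Padlock probes evade this
by requiring a ligation across a single discriminating nucleotide; rolling
circle amplification (RCA) then turns each recognized transcript into one
bright, sub-micrometre fluorescent spot. A section therefore yields, per
gene channel, a point pattern of transcript detections over a nuclei image.
`xyspots` covers everything downstream of the microscope: spot
quantification, per-cell classification, and the spatial statistics that
ask whether the X and the Y homolog occupy different territory.

## Image quantification

**Nuclei.** A two-class global Otsu threshold on the raw nuclei channel
(log-intensity thresholding is available behind a flag, mirroring the two
CellProfiler variants), followed by 8-connected component labelling.
Components under `min_area` (default 20 px²) are discarded as noise;
labels run 1..K in raster-scan order of each component's first pixel, so
labelling is deterministic. A constant image yields zero nuclei with a
warning rather than an error — an empty field of view is data, not a bug.

**Cells.** Cell territories are the CellProfiler-style fixed-distance
secondary objects: every background pixel within Euclidean distance
`distance` (default 20 px) of a nucleus joins the nearest nucleus (distance
to the nucleus *pixel set*, so large and small nuclei compete fairly).
Exact ties go to the lower label — an arbitrary but deterministic rule.
The implementation (in C++) splats bounded disc neighbourhoods from each
nucleus pixel and keeps the per-pixel argmin, which is exact, and is
property-tested against a brute-force per-pixel oracle.

**Spots.** White top-hat filtering (image minus its morphological opening,
disc structuring element of radius `tophat_radius`) removes smooth
background and leaves small bright structures; pixels above a per-channel
threshold form 8-connected components; each component becomes one spot at
its intensity-weighted centroid, rounded to the nearest pixel. The
threshold is deliberately a manual per-channel parameter with no default:
the original pipelines were tuned per sample, and a universal default would
be a false promise. A threshold ≤ 0 is rejected (it would call every
pixel), as is a top-hat radius < 1. The centroid choice matters only for
the density maps (any interior point of the component would serve for
counting); the weighted centroid is used because it is stable under the
top-hat's shape distortions.

**Assignment.** A spot belongs to the cell whose label sits under its
pixel; background pixels leave it unassigned (`NA`, `-1` in CSV).
Assignment is therefore containment in the expanded-cell map, equivalent
to nearest-nucleus-within-20-px, and is tested against that oracle
directly.

One consequence worth stating plainly: two spots of the same channel
closer than roughly the structuring-element scale merge into a single
detection. Counts are therefore a lower bound in dense cells, while
per-cell *presence* — what the classification consumes — is robust. The
end-to-end recovery test exploits exactly this distinction.

## Per-cell classification

With x and y the per-cell counts of the X and Y homolog:

| category    | condition        |
|-------------|------------------|
| no_signal   | x = 0, y = 0     |
| x_eq_1      | x = 1, y = 0     |
| y_eq_1      | x = 0, y = 1     |
| mixed       | x ≥ 1 and y ≥ 1  |
| x_specific  | x ≥ 2, y = 0     |
| y_specific  | x = 0, y ≥ 2     |

"Mixed" requires at least one transcript of *each* homolog. This is a
design decision: the published per-section tables label the column
"X + Y ≥ 2", which taken literally would overlap the X-specific and
Y-specific columns. Under the both-present reading the six categories are
mutually exclusive and sum exactly to the printed totals — verified in the
tests for every stored section (33 of 33). The three-class view of
expressing cells (X-specific / Y-specific / mixed among cells with ≥ 2
signals) is derived from the same partition, never computed independently.

For four-gene co-expression (PCDH11X/Y + NLGN4X/Y in one section), each
printed multi-gene category "A + B ≥ k" is read as *at least one signal of
each listed gene*. The alternative reading (total ≥ k with either gene
allowed zero) cannot be excluded arithmetically because the published
categories overlap and carry no sum constraint; the adopted semantics is
flagged here and in the function documentation.

Signal counts are normalized to counts per 1000 cells
(`1000 · signals / cells`) to compare sections of different size; a
section with zero cells has no defined rate and errors.

## Density maps, purity, and the permutation null

**KDE.** Each gene's spots form a binary image (one pixel per signal)
convolved with a rotationally symmetric 2-D Gaussian kernel of window 150
pixels and SD 25 pixels — the scale at which maps of spinal cord and
medulla sections were drawn. The window is forced odd (151) so the kernel
is centre-defined; truncation is to the square window, which keeps the
kernel separable (an outer product of two 1-D profiles), and the
convolution is computed by accumulating that outer product per spot with
zero padding and no boundary correction. With unit-mass normalization
(default) the map of n interior spots integrates to n; the tests require
`|mass − n|/n < 1e-6` at n = 200 on a 512×512 field, and linearity
`map(A ∪ B) = map(A) + map(B)` exactly. An unnormalized variant (peak 1)
exists for display.

**Purity.** The per-pixel Y fraction p = Y/(X+Y) ∈ [0, 1]. The published
analysis speaks of a "Y and X pixel intensity ratio" with an "80 % colour
purity" cutoff; raw Y/X and bounded Y/(X+Y) are monotone transforms of one
another, so the dominance sets coincide under matched cutoffs, and the
bounded form is the one on which a symmetric two-sided cutoff is even
expressible. Pixels with total density below `eps` are masked; by default
`eps` is 10⁻³ times the mean positive total density, because the ratio is
meaningless in empty background and the original analysis only ever shows
it inside tissue. Dominance: Y-dominant at p ≥ 0.8, X-dominant at p ≤ 0.2,
boundaries inclusive, remainder mixed. Raising the cutoff can only shrink
the dominant sets (tested).

**Histogram.** 50 equal-width bins on [0, 1] by default; the published
figures do not state their bin count, so it is a parameter. Bin b covers
[(b−1)/50, b/50), with 1.0 closed into the last bin.

**Permutation null.** Spot positions are fixed; gene labels are permuted
uniformly (each randomization preserves both label counts exactly — an
asserted invariant, not an assumption). For each of `n_rand = 100`
randomizations the X density is re-splatted (the total density is
invariant, so Y = total − X, and the background mask is shared between
observed and randomized fields), the purity histogram and the three
dominance proportions recomputed. Reported are: per-bin randomized
mean/SD with signed flags where the observed frequency deviates by more
than 3 SD; and percentile 95 % confidence intervals (2.5/97.5 percentiles
of the 100 randomized values, type-7 quantiles) for each dominance
proportion. With a single label present the null degenerates — every
permutation identical, SD zero, no flags — and is returned as such.
A fixed seed makes the whole summary bit-reproducible; the C++
randomization path is tested to agree with the plain R
density→purity→histogram composition on the identity permutation.

Calibration and power are measured, not assumed. Under the exchangeable
null (500 uniform spots with fair-coin labels in a 600×600 ellipse — about
nine spots per kernel support, enough local sparsity for dominant pixels
to exist at all), the Y-dominant CI test rejects at the nominal 5 % level
within ±3 % over 200 replicate scenes. Against a dimorphic alternative
(X-expressing cells enriched 3× ventrally, Y homogeneous, ≈500 spots), the
combined criterion — CI exceedance plus at least one Y-side bin over
+3 SD — fires in ≥90 % of 50 seeded runs. The scene sizes here were chosen
so the purity field is neither saturated nor vacuous: with many more spots
per kernel support the field flattens toward 0.5 and dominant pixels
disappear; with far fewer, the histogram becomes too discrete for a
percentile CI to mean much.

**Dorsal/ventral comparison.** The border is the line through the
midpoints of two landmark pairs, one pair per side, each spanning the
dorsal-to-ventral extent of the section; mask pixels above the line are
dorsal, on-or-below ventral (rows grow downward, ventral down). Regional
expression is compared as the X:Y count ratio per region; a region without
Y spots has an undefined ratio and is flagged for exclusion. Ratios from
replicate sections are compared with a one-tailed two-sample Welch t-test
(unequal variances, Welch–Satterthwaite df, via `stats::t.test`); two
zero-variance groups are reported as degenerate rather than inventing a
p-value.

## Discriminating-site finder

Input is a pre-computed multiple alignment of X and Y isoform transcripts
(alignment construction is out of scope — standard tools do it better).
A column is a discriminating site when all X isoforms carry one identical
unambiguous base, all Y isoforms carry one identical unambiguous base, and
the two differ; gaps and N never qualify, because a padlock ligation
junction needs a definite base on both sides. Sites are reported in
1-based alignment coordinates together with per-isoform ungapped positions
for probe placement. The finder is order-invariant within each side, can
only lose sites as isoforms are added (tested as a monotone-shrinkage
property), and is validated against a per-column brute-force oracle on
1000 random isoform sets. Percent identity is computed over columns where
neither sequence is gapped. Site *ranking* (the published probes used a
subset of sites chosen by unstated criteria) is deliberately not
implemented — only enumeration.

## The synthetic scene generator

The generator is first-class, tested code: it defines the conditions under
which everything else is validated.

What it emulates: an elliptical (or half-annular, or full-frame) tissue
region; hundreds to thousands of nuclei placed by hard-core rejection
sampling (pairwise centre distance ≥ `min_nucleus_separation`, bounded at
1000·n attempts, then an explicit placement-failure error); per-cell
expression classes in proportions like the published per-section tables
(default 87 % silent, 6 % X-only, 6 % Y-only, 1 % mixed, from the male
spinal-cord rows); per-cell spot counts Poisson(`1.5`) conditioned ≥ 1
(≥ 2 for mixed cells, which must carry both labels; the X/Y split of a
mixed cell is uniform over the compositions with both present); spot
displacement isotropic Gaussian (SD 2–3 px) truncated to the expanded-cell
radius so the true parent is unambiguous; and a `ventral_x_enrichment`
multiplier applied to the X-only probability below the row-midline of the
tissue bounding box, then renormalized per cell — at 1 the labels are
exchangeable with position, which is what the calibration tests rely on.
Rendering adds unit-intensity nucleus discs, Gaussian spot bumps
(`spot_sigma` 1.2–1.5 px, amplitude 0.6 on a 0.05 background — typical
well-exposed RCA contrast on [0, 1] images), and optional Gaussian noise.
All randomness derives from one seed through fixed per-stage offsets
(placement, radii, classes, spots, rendering), so scenes and renders are
bit-reproducible and stages can be regenerated independently.

What it does not emulate: optics. There is no PSF beyond the Gaussian
bump, no chromatic shift, no autofluorescence texture; false positives
exist only as a uniform per-gene Poisson rate (`false_positive_rate`,
default 0 — no quantitative rate was ever published for, e.g., spurious Y
signals in female tissue, so none is baked in). Nuclei are discs, not
nuclei. Consequently, passing tests demonstrate that the *algorithms* are
correct under controlled conditions — exact segmentation at adequate
separation, exact assignment, calibrated inference — not that any
particular threshold will transfer to real microscopy, where the manual
per-channel thresholds remain the analyst's responsibility.

## Numerical choices and degenerate inputs

* Coordinates are 1-based `(row, col)` with pixel centres at integers —
  the native R convention, used consistently in memory and in CSV.
* Expansion ties → lowest label; component labels → raster-scan order of
  first pixel; both make otherwise-arbitrary outputs deterministic.
* Purity at zero total density is masked, never 0/0; computed purity is
  clamped into [0, 1] against last-ulp excursions of Y = total − X.
* Equality tolerances in tests: exact integer identities where the
  quantity is a count (partitions, assignments, site lists); 1e-6 relative
  for KDE mass; 1e-9/1e-12 where only floating-point association order is
  in play.
* Degenerate inputs that return rather than error: constant nuclei image
  (zero nuclei, warning), empty spot set for a density map (zero field),
  single-label permutation null (zero-variance summary). Degenerate
  inputs that error: zero cells for per-1000 normalization, all-masked
  purity field, coincident landmarks, n_rand < 2, non-positive detection
  threshold, impossible nucleus packing.

## Validation problem sizes

The test suite and the acceptance script regenerate everything they
measure: 200 exchangeable scenes (500 spots, 600×600) for calibration and
50 enriched scenes for power; a 2000-cell, 1200×1200 noise-free scene for
end-to-end class recovery (compared against the scene's realized ground
truth within 3 binomial SDs — the generator's own multinomial noise is not
charged to the pipeline); 100 random 256×256 scenes for assignment-oracle
equivalence; 10⁴ random profiles for the partition invariant; 1000 random
isoform sets for the site finder. These sizes were chosen as the smallest
at which each property is sharply testable.

## Known limitations

* Counts saturate in dense cells (spot merging); use presence-based
  categories, as the classification does, when cells are small relative
  to the spot scatter.
* The KDE has no boundary correction: density leaks off the tissue edge,
  so edge pixels are biased low for both homologs; the purity ratio is
  less affected because the bias is shared, and the default masking
  removes the far background.
* Whether the published ±3 SD flags were computed per histogram bin or
  per pixel is ambiguous in the source material; per-bin was adopted
  (the histogram figure shows flagged dots on bins), and `flag_pixels()`
  maps flagged bins back onto the tissue.
* The percentile CI from 100 randomizations has granularity ~1 %; with
  heavy ties (very smooth purity fields) it becomes conservative. The
  calibration test pins its actual level under the conditions above.
* Tile stitching, spectral unmixing and immunostain-based cell typing are
  out of scope; sections enter as single grayscale images per channel.
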