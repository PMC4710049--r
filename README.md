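# xyspots

Quantification and spatial statistics for in situ detection of X/Y
gametolog transcripts in tissue sections.

X-chromosome genes such as *PCDH11X* and *NLGN4X* have Y-chromosome
homologs (*PCDH11Y*, *NLGN4Y*) that are 89–99 % identical at the transcript
level, so ordinary hybridization probes cannot tell them apart. Padlock
probes ligated across a single discriminating nucleotide, amplified by
rolling-circle amplification (RCA), produce one bright sub-micrometre spot
per transcript molecule and make the X/Y distinction visible in tissue.
`xyspots` implements the downstream analysis of such experiments for
developing CNS sections (spinal cord, medulla oblongata):

* **Image quantification** — global Otsu nuclei segmentation, cell borders
  defined by a fixed 20-pixel expansion of each nucleus, spot detection by
  white top-hat filtering plus per-channel manual thresholds, and
  assignment of every spot to its parent cell.
* **Per-cell classification** — each cell falls in exactly one of six
  categories by its X/Y counts: no signal, X = 1, Y = 1, mixed
  (X ≥ 1 and Y ≥ 1), X-specific (X ≥ 2, Y = 0), Y-specific (Y ≥ 2, X = 0);
  signal counts are normalized to counts per 1000 cells; four-gene
  co-expression categories cover simultaneous PCDH11X/Y + NLGN4X/Y probing.
* **Spatial dimorphism statistics** — kernel density maps of each homolog
  (rotationally symmetric Gaussian, 150-pixel window, SD 25), the Y-purity
  field *p* = Y/(X+Y), a purity histogram with 80 %-purity dominance
  categories, and a label-permutation null (100 randomizations holding spot
  positions fixed) giving ±3 SD per-bin flags and percentile 95 %
  confidence intervals for the X-dominant / mixed / Y-dominant pixel
  proportions; plus a landmark-based dorsal/ventral partition with
  one-tailed Welch *t*-tests on regional X:Y ratios.
* **Probe-site discovery** — enumeration of alignment positions where all
  X isoforms carry one base, all Y isoforms another (candidate padlock
  ligation junctions), and exon-style percent identity.
* **Synthetic scenes** — a ground-truthed generator (nuclei placement,
  per-cell expression classes, per-cell Poisson spot counts, optional
  ventral enrichment of X-expressing cells, rendered TIFF channels) so the
  whole pipeline is testable without the original microscopy data.

The permutation null answers the core scientific question: are X and Y
transcripts spatially segregated beyond what exchangeable labelling of the
same spot positions would produce? Under the null, gene labels are permuted
uniformly over the observed positions (preserving both label counts), the
purity field is recomputed each time, and the observed dominance
proportions are compared with the randomized 2.5/97.5 percentiles.

## Worked example

The `analysis/` scripts form the complete workflow on a simulated
male-spinal-cord-like section (2000 cells, X-expressing cells enriched 3×
ventrally, Y homogeneous). Run them in order from the repository root:

```sh
Rscript analysis/01_simulate_scene.R      # scene + rendered TIFFs
Rscript analysis/02_quantify_images.R     # segment, expand, detect, assign
Rscript analysis/03_classify_cells.R      # six-category table, per-1000 rates
Rscript analysis/04_spatial_dimorphism.R  # KDE, permutation test, dorsal/ventral
Rscript analysis/05_probe_sites.R         # discriminating sites, % identity
```

`03_classify_cells.R` prints, for the demonstration section:

```
X/Y cell classification (PCDH11X/PCDH11Y)
 no_signal     x_eq_1     y_eq_1      mixed x_specific y_specific
      1648        188        105         21         26         12
total cells: 2000
     gene n_signals per_1000_cells
1 PCDH11X       264          132.0
2 PCDH11Y       157           78.5
```

All 2000 cells land in exactly one category; the ground truth behind this
scene held 211 X-only, 114 Y-only and 23 mixed cells, so per-cell presence
is recovered almost perfectly even though nearby same-channel spots of one
cell can merge into a single RCA-like detection (264 detections from 439
simulated X spots). `04_spatial_dimorphism.R` then reports the segregation
test and the regional comparison:

```
flagged bins (+3SD): 5  (-3SD): 0
mean X:Y dorsal 0.98, ventral 2.71; Welch one-tailed p = 3.907e-10
```

Five high-purity histogram bins are over-represented by more than 3 SD
relative to the 100 label randomizations — the bin-level signature of
Y-dominant regions where the ventrally clustered X homolog is absent — and
the ventral X:Y count ratio exceeds the dorsal ratio across 12 replicate
sections, exactly the behaviour the generator encodes.

## Conventions

Images are numeric matrices on [0, 1]; coordinates are 1-based `(row, col)`
pixel indices with row 1 at the top (ventral is the larger-row side in
synthetic scenes). Spot tables are CSV with header `row,col,gene,cell_id`
and `-1` for unassigned spots. See `vignettes/xyspots-methods.Rmd` for the
full model description, parameter choices and limitations.
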