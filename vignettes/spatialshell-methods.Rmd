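---
title: "Marker-defined spatial domains and distance-stratified microenvironments"
author: "spatialshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-defined spatial domains and distance-stratified microenvironments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialshell)
```

## The problem

Imaging-based single-cell spatial transcriptomics platforms (10x Xenium
and its relatives) report a few hundred genes per cell together with the
cell centroid in micrometres. Many biological questions about such data
are not about single cells but about *structures* — a tumor nest, a
duct, a follicle — and about how gene expression is organised *around*
those structures: which populations sit at the boundary, which
infiltrate, which are held at a distance.

`spatialshell` answers those questions in five steps:

1. **Gridding.** Cell counts are binned onto a fixed-pitch lattice
   (default 10 µm), trading single-cell resolution for per-square
   marker sensitivity.
2. **Detection.** A spatial domain is the set of squares expressing at
   least one *positive* marker (e.g. *CDH1* or *EPCAM* for carcinoma)
   and no *negative* marker, denoised once with a 3×3 majority
   (median) filter, then split into connected components — the
   individual domains.
3. **Distance.** Every square receives a signed shortest-path distance
   µ to the nearest domain-boundary square on the 8-connected lattice
   graph with edge weights 1 (orthogonal) and √2 (diagonal), computed
   by multi-source Dijkstra with all boundary squares as sources.
   µ < 0 inside, µ = 0 on the boundary, µ > 0 outside.
4. **Stratification.** The field is cut into half-open 30-µm shells
   (x, x+30], x = −120, …, +150. Inner shells are attributed to the
   domain that owns the squares; outer shells are shared space, so each
   domain receives an *exclusive* outer section: the shell restricted
   to the domain's expanded bounding rectangle, minus every square
   claimed by two or more rectangles. Ambiguous squares belong to no
   domain's microenvironment.
5. **Quantification.** Per-domain pseudobulk profiles feed alpha
   diversity (Chao1, Shannon, observed features), Geary's *C* spatial
   autocorrelation, Leiden clustering with UMAP embedding, an abstract
   cluster graph with diffusion pseudotime, per-section expression
   density, a section×group linear model, and a Pearson correlation
   screen against a reference gene's section profile.

## Model detail and conventions

### Gridding

A cell at (x, y) contributes all of its counts to square
(⌊x/p⌋, ⌊y/p⌋) under the half-open convention [kp, (k+1)p); the origin
is the minimum coordinate rounded down to a pitch multiple, and indices
are 0-based. Counts are conserved exactly: the column sums of the grid
equal the column sums of the cell table, and this is asserted in the
tests. Smaller pitches raise spatial resolution but lower per-square
marker sensitivity; 10 µm is the default because a typical epithelial
cell occupies roughly one square at that pitch.

### Detection

The pre-domain rule is a per-square Boolean: Σ positive counts > 0 and
Σ negative counts = 0 (the negative-expressing squares are logically
subtracted from the positive-expressing squares). The majority filter
is applied exactly once with **replicate padding**; padding matters at
the capture-area edge, and replicate padding was chosen because it
neither invents foreground outside the tissue nor erodes a domain
truncated by the capture area more than its own geometry requires. A
corner square of a solid rectangle has only 4 of 9 window votes and is
eroded — this is inherent to the majority rule, not an artifact.

Connectivity is **8-connected everywhere** — components, boundary
detection, and the distance graph — for mutual consistency: two
squares joined only diagonally are one domain, and their distance is
√2 steps, not 2. Component labels are assigned in deterministic raster
order so repeated runs label identically.

The boundary is the set of domain squares with at least one of eight
neighbours in the background, with the lattice border itself counted
as background so that truncated domains keep a closed contour for the
distance transform.

### Distance field

The domain is *not* an obstacle: paths may traverse any square, so the
multi-source distance equals the octile metric to the nearest source,
and the implementation (a binary-heap Dijkstra in C++) is checked in
the tests against both an independent O(V²) Dijkstra and the
closed-form octile distance p·(max(|Δc|,|Δr|) + (√2−1)·min(|Δc|,|Δr|)).
Distances are reported in µm (graph length × pitch), because the shell
boundaries are specified in µm.

### Stratification

Shell membership is x < µ ≤ x+30. Note the consequences at the edges:
boundary squares (µ = 0) fall in (−30, 0], and a square exactly 30 µm
out falls in (0, 30]. For the exclusive outer sections, each domain's
bounding rectangle is expanded by **x + 30 µm per side** at level x so
that the rectangle geometrically contains the (x, x+30] shell; an
`expand_by_x` switch restores the narrower reading (expansion by x
only). The pairwise-intersection union is removed from *every*
domain's section at the level being computed, and sections are
recomputed per level. Section expression is the unweighted mean count
per square; an empty section propagates as missing, never as zero.

### Clustering and trajectory

The pseudobulk pipeline is log1p → PCA (50 components, clipped to the
data) → kNN graph (k = 15) → Leiden (modularity objective, resolution
1.0) → UMAP, all seeded; defaults for k and resolution are exposed as
configuration because no single choice fits every tissue. Labels are
relabeled by decreasing cluster size so they are stable across runs.
If every profile is identical the pipeline short-circuits to a single
cluster rather than letting community detection partition an
arbitrary kNN graph of zero-distance points.

The cluster-level graph scores each cluster pair by observed
inter-cluster kNN edges over the degree-preserving expectation
d_i·d_j/2m, capped at 1. Pseudotime is diffusion pseudotime: a
Gaussian kernel with adaptive bandwidth (distance to the k-th
neighbour) on PC scores, density-normalised, eigendecomposed; the
pseudotime of unit u is the diffusion distance
√Σ_i (λ_i/(1−λ_i))²(ψ_i(u)−ψ_i(root))² over the non-trivial
components, scaled to [0, 1]. Both are implemented in the package
itself. The root *unit* inside the chosen root cluster is the domain
nearest the cluster centroid in PC space — a deterministic rule,
since only a root cluster is meaningful input. Eigenvalues within
1e−10 of 1 (one per connected component) are excluded from the sum so
disconnected neighbourhoods yield finite pseudotime.

### Statistics

* **Chao1** uses the bias-corrected form S_obs + F₁(F₁−1)/(2(F₂+1));
  the classic F₁²/(2F₂) form is available by flag. **Shannon** defaults
  to bits (base 2); the base is a parameter.
* **Geary's C** is computed on user-supplied units and weights; the
  convenience wrapper uses lattice squares of selected domains with
  binary 8-adjacency. C is undefined (an error, not NA) for constant
  fields or empty weight matrices.
* **Expression density** is total counts over number of squares —
  area-normalised, not cell-normalised, because sections are geometric
  objects. The section×group model is `density ~ section * group` with
  a Gaussian identity-link GLM by default (Poisson/log offered);
  sections are coded ordinally by interval midpoint by default, with a
  categorical flag, because peaked interactions can favour either
  coding. Wald 95 % intervals are reported.
* The **correlation screen** reports Pearson r of each gene's section
  density profile against a reference gene per group, and the set with
  r ≥ 0.75 (threshold configurable). Zero-variance profiles are
  excluded, not scored zero.

## The synthetic tissue generator

`simulate_tissue()` emulates the input shape of a Xenium run: cells
scattered over a 2000 × 1500 µm field by an inhomogeneous Poisson
point process, counts drawn Poisson per gene with compartment rates.
The default layout plants 40 non-overlapping disks of radius 60 µm on
a regular lattice, alternating *baseline* and *infiltrated*
phenotypes. Compartments and defaults:

| compartment | geometry | cell density (µm⁻²) | signature rate |
|---|---|---|---|
| core | inside a disk | 0.05 | `EPCAM` 5 |
| ring | (0, 20] µm outside | 0.03 | `ACTA2` 5 |
| shell | (30, 60] µm outside | 0.01 | `CD8A` 5 |
| stroma | elsewhere | 0.005 | background only |

Marker leak outside the home compartment is 0.02, background genes run
at 0.5 everywhere, the negative marker `SFTPB` at 0. Infiltrated cores
raise `PECAM1` from 0.2 to 2.0; *staged* cores ramp `PRG1` up and
`PRG2` down with a latent stage in [0, 1]. The core density (≈5 cells
per 10-µm square) represents densely packed carcinoma epithelium and
is deliberately high enough that a marker-positive square is almost
never missing inside a domain; at sparser, more stroma-like densities
the detector's mask necessarily becomes speckled and agreement with
geometric truth degrades — that regime is a sensitivity limit of
grid-based detection itself, discussed below.

Two ground-truth rasterizations are provided. `rasterize_truth()`
marks squares whose centre lies inside a planted disk and backs the
analytic disk-area check. `truth_mask()` marks squares that contain at
least one planted core *cell*, using exactly the analysis binning; it
is the reference for detection agreement, because squares straddling
the disk edge are genuinely ambiguous under any geometric rule while
the realized cells are not. Truth labels derive from the planted
compartments, not from the drawn marker counts, so comparing detection
against them is not circular.

What the generator does **not** emulate: segmentation errors,
cell-shape effects, transcript diffusion between neighbouring cells,
overdispersion beyond Poisson (a negative-binomial flag is the obvious
extension), irregular domain shapes, and panel-scale correlation
structure. Passing the planted-recovery tests therefore demonstrates
the pipeline's internal correctness and its behaviour under idealised
conditions, not performance on real tissue.

## Validation scale and determinism

The test suite validates each operation against an independent oracle
(brute-force Dijkstra on 50×50 lattices, sliding-window majority on
64×64 lattices, union-find components, set-algebra evaluation of the
exclusive-section formula, direct formula evaluation for the
statistics) and runs the full pipeline on one ~48,000-cell simulated
section with 40 domains and 20 genes; clustering and trajectory
recovery use 60-unit profile sets, and GLM coverage uses 100
replicates of n = 200. These sizes keep a full run in well under a
minute per module while leaving the statistical checks adequately
powered. All stochastic stages consume explicit seeds; reruns with the
same configuration produce byte-identical artifacts, which the
pipeline test verifies by checksum.

## Known limitations

* Thin structures (monolayers ~one cell wide) are at the mercy of the
  pitch: a 10-µm grid can drop them entirely, and a finer grid dilutes
  marker counts per square. The pitch/sensitivity trade-off is the
  user's to set per panel and tissue.
* The exclusion rule discards squares claimed by two expanded
  rectangles, so densely packed domains can have small exclusive outer
  sections at high levels; this is the intended conservative
  behaviour, not data loss.
* Geary's C is offered with binary 8-adjacency weights on lattice
  squares; other unit/weight choices (domains, kNN) are possible via
  the generic `gearys_c()` but no guidance is built in.
* Multi-sample integration concatenates profiles without batch
  correction; sample-specific depth effects propagate to clustering
  unless handled upstream.
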