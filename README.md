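# spatialshell

Marker-defined spatial domains and distance-stratified microenvironments
for imaging-based spatial transcriptomics (Xenium-style cell tables and
cell×gene count matrices).

Histological structures — tumor nests, ducts, follicles — organise gene
expression not only inside themselves but in concentric bands around
them: myoepithelium hugging a duct, immune cells held 30–60 µm out,
vasculature infiltrating some nests and not others. `spatialshell`
makes that organisation quantitative for anyone working with in situ
panels of a few hundred genes: pathology-adjacent analysts who want
per-structure readouts, and methodologists who need a deterministic,
oracle-tested reference for grid-based microenvironment analysis.

## Method

1. **Grid.** Cell counts are binned onto a 10-µm lattice:
   cell (x, y) → square (⌊x/p⌋, ⌊y/p⌋), counts conserved exactly.
2. **Detect.** A spatial domain mask is
   `Σ positive counts > 0 ∧ Σ negative counts = 0` per square,
   denoised once with a 3×3 majority (median) filter; 8-connected
   components are the individual domains *S_d*.
3. **Distance.** Signed shortest-path distance µ from the domain
   boundary on the 8-connected lattice graph (weights 1 / √2), by
   multi-source Dijkstra over all boundary squares; µ < 0 inside,
   0 on the boundary, > 0 outside, in µm.
4. **Stratify.** Half-open 30-µm shells P_(x, x+30], x = −120 … 150.
   Each domain's exclusive outer section at level x is

   PS_d = P_(x,x+30] ∧ R_d ∧ ¬⋃_{i<j} (R_i ∧ R_j)

   where R_d is the domain's bounding rectangle expanded by x+30 µm
   per side — shared squares belong to no domain. Section expression
   is the mean count per square.
5. **Quantify.** Pseudobulk domain profiles → alpha diversity (Chao1,
   Shannon, observed features), Geary's C, Leiden clustering + UMAP,
   cluster graph + diffusion pseudotime, per-section expression
   density with a `density ~ section * group` GLM, and a Pearson
   correlation screen (r ≥ 0.75) against a reference gene.

A synthetic tissue generator (`simulate_tissue()`, `simulate_cohort()`)
plants disk domains, boundary rings, shell-localised populations,
progression gradients and multi-sample cohorts with known ground
truth, so the whole pipeline is testable offline.

## Worked example

```r
library(spatialshell)

sim  <- simulate_tissue(tissue_spec(), seed = 7)   # ~47k cells, 40 planted domains
grid <- build_grid(sim$cells, pitch = 10)
mask <- detect_domain(grid, marker_spec(positive = "EPCAM", negative = "SFTPB"))
lab  <- segment_domains(mask)
jaccard(mask, truth_mask(sim, grid))

field    <- compute_distance_field(mask, pitch = 10)
shells   <- stratify_shells(field)                 # (-120,-90] ... (120,150]
sections <- stratify_domains(lab, shells, pitch = 10)
dens     <- expression_density(grid, sections, genes = c("ACTA2", "CD8A"))
aggregate(density ~ lower + gene, dens, mean)
```

Output:

```
<expression_grid> 200 cols x 150 rows at 10 um pitch; 20 genes; 702029 total counts
<domain_labeling> 40 domain(s), 5041 foreground square(s)
[1] 0.965                       # mask vs planted ground truth (Jaccard)
 lower density.ACTA2 density.CD8A
   -60    0.24481360   0.28589370
   -30    2.13705404   0.24250008
     0    8.07323775   0.59710003
    30    0.04788884   4.58192473
    60    0.02568612   0.34805625
    90    0.02549271   0.02747699
```

Reading the table: the boundary-ring marker *ACTA2* peaks in the
(0, +30] shell just outside the domains and the immune marker *CD8A*
in (+30, +60] — exactly where the generator planted those
populations; inside the domains (negative `lower`) both fall to
background. Per-domain profiles then feed the downstream analytics:

```r
profiles <- domain_expression(grid, lab)
cl <- cluster_domains(profiles, seed = 1)          # log1p → PCA → kNN → Leiden → UMAP
tr <- trajectory(profiles, cl, root_cluster = 1)   # cluster graph + diffusion pseudotime
colMeans(alpha_diversity(profiles$expr))
#>    chao1  shannon observed
#>    19.00     3.36    19.00
```

A command-line wrapper is installed with the package
(`system.file("cli", "spatialshell.R", package = "spatialshell")`),
with subcommands `run` (YAML-configured full pipeline), `simulate`,
`grid`, and `detect`.

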