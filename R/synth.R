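#' Synthetic in situ tissue with planted domains and shell populations
#'
#' Generates Xenium-style cell tables for end-to-end validation: cells
#' are placed by an inhomogeneous Poisson point process whose intensity
#' depends on the compartment (tumor disk, boundary ring just outside
#' the disk, a stratified shell band, far stroma), and per-gene counts
#' are drawn from Poisson rates per compartment. Domain phenotypes
#' (baseline, infiltrated, staged) perturb rates inside their disk, so
#' detection, stratification, group comparison, clustering and
#' trajectory recovery can all be checked against known ground truth.
#'
#' @name synth
#' @keywords internal
NULL

#' Default gene panel and compartment rate model
#'
#' Twenty genes: a tumor-positive marker (`EPCAM`), an unexpressed
#' negative marker (`SFTPB`), a boundary-ring marker (`ACTA2`), a
#' shell-band immune marker (`CD8A`), an endothelial marker (`PECAM1`)
#' whose intratumoral rate depends on the domain phenotype, two
#' progression genes (`PRG1` up, `PRG2` down with stage), and thirteen
#' background genes. Rates are mean Poisson counts per cell.
#'
#' @return list with `genes`, `rates` (genes x compartments: `core`,
#'   `ring`, `shell`, `stroma`), `endo` (gene + per-phenotype core
#'   rates), `staged` (up/down genes and their rate ranges).
#' @export
default_gene_model <- function() {
  genes <- c("EPCAM", "SFTPB", "ACTA2", "CD8A", "PECAM1", "PRG1", "PRG2",
             sprintf("BG%02d", 1:13))
  rates <- matrix(0.5, nrow = length(genes), ncol = 4,
                  dimnames = list(genes, c("core", "ring", "shell", "stroma")))
  rates["EPCAM", ] <- c(5, 0.02, 0.02, 0.02)
  rates["SFTPB", ] <- 0
  rates["ACTA2", ] <- c(0.05, 5, 0.05, 0.05)
  rates["CD8A", ]  <- c(0.05, 0.05, 5, 0.05)
  rates["PECAM1", ] <- c(0.2, 0.2, 0.5, 0.5)
  rates["PRG1", ] <- c(0.3, 0.3, 0.5, 0.5)
  rates["PRG2", ] <- c(5, 0.5, 0.5, 0.5)
  list(genes = genes, rates = rates,
       endo = list(gene = "PECAM1",
                   core_rate = c(baseline = 0.2, infiltrated = 2.0)),
       staged = list(up = list(gene = "PRG1", from = 0.3, to = 5),
                     down = list(gene = "PRG2", from = 5, to = 0.3)))
}

#' Layout of non-overlapping tumor disks on a regular lattice
#'
#' @param n_domains number of disks.
#' @param field c(width, height) in um.
#' @param radius disk radius, um.
#' @param phenotype `"baseline"`, `"infiltrated"`, `"alternate"`
#'   (default: alternate the two), or `"staged"` (stage ramps 0..1 over
#'   the disks).
#' @return data.frame `x`, `y`, `radius`, `phenotype`, `stage`.
#' @export
default_domains <- function(n_domains = 40, field = c(2000, 1500),
                            radius = 60, phenotype = "alternate") {
  ncol_ <- ceiling(sqrt(n_domains * field[1] / field[2]))
  nrow_ <- ceiling(n_domains / ncol_)
  gx <- field[1] / ncol_; gy <- field[2] / nrow_
  i <- seq_len(n_domains) - 1L
  x <- (i %% ncol_ + 0.5) * gx
  y <- (i %/% ncol_ + 0.5) * gy
  ph <- switch(phenotype,
               alternate = rep(c("baseline", "infiltrated"), length.out = n_domains),
               staged = rep("staged", n_domains),
               rep(phenotype, n_domains))
  stage <- if (identical(phenotype, "staged"))
    seq(0, 1, length.out = n_domains) else rep(NA_real_, n_domains)
  data.frame(x = x, y = y, radius = radius, phenotype = ph, stage = stage)
}

#' Specification of a synthetic tissue
#'
#' @param field c(width, height) in um.
#' @param domains data.frame `x`, `y`, `radius`, `phenotype`
#'   (`"baseline"`, `"infiltrated"` or `"staged"`), optional `stage` in
#'   \[0,1\]; disks must not overlap.
#' @param densities cells per um^2 by compartment
#'   (`core`, `ring`, `shell`, `stroma`).
#' @param ring_width width of the boundary ring just outside each disk,
#'   um (default 20).
#' @param shell_band c(lo, hi) of the planted shell population, um
#'   outside the disk boundary (default c(30, 60)).
#' @param gene_model rate model, see [default_gene_model()].
#' @return object of class `tissue_spec`.
#' @export
tissue_spec <- function(field = c(2000, 1500),
                        domains = default_domains(field = field),
                        densities = c(core = 0.05, ring = 0.03,
                                      shell = 0.01, stroma = 0.005),
                        ring_width = 20, shell_band = c(30, 60),
                        gene_model = default_gene_model()) {
  stopifnot(length(field) == 2, all(field > 0), all(domains$radius > 0))
  need <- c("core", "ring", "shell", "stroma")
  if (!all(need %in% names(densities))) stop("densities must name: ",
                                             paste(need, collapse = ", "))
  if (nrow(domains) > 1L) {
    dd <- as.matrix(stats::dist(domains[, c("x", "y")]))
    rr <- outer(domains$radius, domains$radius, "+")
    diag(dd) <- Inf
    if (any(dd <= rr)) stop("domain disks overlap; adjust the layout")
  }
  if (is.null(domains$stage)) domains$stage <- NA_real_
  structure(list(field = field, domains = domains,
                 densities = densities[need], ring_width = ring_width,
                 shell_band = shell_band, gene_model = gene_model),
            class = "tissue_spec")
}

# signed Euclidean distance from each point to the nearest disk edge
# (negative inside) and the nearest domain id
nearest_disk <- function(x, y, domains) {
  n <- length(x)
  best <- rep(Inf, n); who <- rep(NA_integer_, n)
  for (d in seq_len(nrow(domains))) {
    s <- sqrt((x - domains$x[d])^2 + (y - domains$y[d])^2) - domains$radius[d]
    upd <- s < best
    best[upd] <- s[upd]; who[upd] <- d
  }
  list(signed = best, domain = who)
}

point_compartment <- function(signed, spec) {
  comp <- rep("stroma", length(signed))
  comp[signed <= 0] <- "core"
  comp[signed > 0 & signed <= spec$ring_width] <- "ring"
  comp[signed > spec$shell_band[1] & signed <= spec$shell_band[2]] <- "shell"
  comp
}

#' Simulate one tissue section
#'
#' Cells are placed by thinning a homogeneous Poisson process at the
#' maximum compartment density; counts are Poisson with compartment
#' rates, adjusted per domain phenotype (endothelial rate for
#' infiltrated cores, progression genes ramped with stage). Fully
#' reproducible from `seed`.
#'
#' @param spec a [tissue_spec()].
#' @param seed integer seed.
#' @return list with `cells` (a [cell_table()]), `spec`, and `truth`
#'   (data.frame of per-cell `signed_distance`, `compartment`, `domain`).
#' @export
simulate_tissue <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "tissue_spec"))
  gm <- spec$gene_model
  with_seed(seed, {
    area <- spec$field[1] * spec$field[2]
    dmax <- max(spec$densities)
    n0 <- stats::rpois(1, dmax * area)
    x <- stats::runif(n0, 0, spec$field[1])
    y <- stats::runif(n0, 0, spec$field[2])
    nd <- if (nrow(spec$domains)) nearest_disk(x, y, spec$domains)
    else list(signed = rep(Inf, n0), domain = rep(NA_integer_, n0))
    comp <- point_compartment(nd$signed, spec)
    keep <- stats::runif(n0) < spec$densities[comp] / dmax
    x <- x[keep]; y <- y[keep]
    comp <- comp[keep]; dom <- nd$domain[keep]; sgn <- nd$signed[keep]
    n <- length(x)
    if (n == 0L) stop("no cells generated; increase densities or field")

    rates <- gm$rates[, comp, drop = FALSE]   # genes x cells
    in_core <- comp == "core"
    if (any(in_core) && nrow(spec$domains)) {
      ph <- spec$domains$phenotype[dom]
      st <- spec$domains$stage[dom]
      infil <- in_core & ph == "infiltrated"
      rates[gm$endo$gene, infil] <- gm$endo$core_rate[["infiltrated"]]
      staged <- in_core & ph == "staged" & !is.na(st)
      if (any(staged)) {
        up <- gm$staged$up; dn <- gm$staged$down
        rates[up$gene, staged] <- up$from + (up$to - up$from) * st[staged]
        rates[dn$gene, staged] <- dn$from + (dn$to - dn$from) * st[staged]
      }
    }
    counts <- matrix(stats::rpois(length(rates), as.vector(rates)),
                     nrow = nrow(rates))
    cells <- cell_table(cell_id = sprintf("cell_%06d", seq_len(n)),
                        x = x, y = y, counts = t(counts),
                        gene_names = gm$genes)
    list(cells = cells, spec = spec,
         truth = data.frame(cell_id = cells$cell_id,
                            signed_distance = sgn, compartment = comp,
                            domain = dom))
  })
}

#' Ground-truth domain mask rasterized onto an analysis grid
#'
#' A lattice square is true when its centre lies inside any planted
#' disk; the binning convention (origin, pitch) is taken from the grid
#' itself, so truth and detection are always aligned.
#'
#' @param spec a `tissue_spec`.
#' @param grid the `expression_grid` built from the simulated cells.
#' @return logical `n_rows x n_cols` mask.
#' @export
rasterize_truth <- function(spec, grid) {
  stopifnot(inherits(spec, "tissue_spec"), inherits(grid, "expression_grid"))
  cx <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$pitch
  cy <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$pitch
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (d in seq_len(nrow(spec$domains))) {
    dx2 <- outer(rep(1, grid$n_rows), (cx - spec$domains$x[d])^2)
    dy2 <- outer((cy - spec$domains$y[d])^2, rep(1, grid$n_cols))
    mask <- mask | (dx2 + dy2 <= spec$domains$radius[d]^2)
  }
  mask
}

#' Cell-realized ground-truth mask on an analysis grid
#'
#' A lattice square is true when it contains at least one planted
#' tumor-core cell, binned with exactly the convention of
#' [build_grid()]. This is the ground truth the detector can in
#' principle recover (it reflects where tumor cells actually landed);
#' [rasterize_truth()] gives the idealised geometric disk instead.
#'
#' @param sim result of [simulate_tissue()].
#' @param grid the `expression_grid` built from `sim$cells`.
#' @return logical `n_rows x n_cols` mask.
#' @export
truth_mask <- function(sim, grid) {
  stopifnot(inherits(grid, "expression_grid"))
  core <- sim$truth$compartment == "core"
  col <- floor((sim$cells$x[core] - grid$origin[1]) / grid$pitch)
  row <- floor((sim$cells$y[core] - grid$origin[2]) / grid$pitch)
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[cbind(row + 1L, col + 1L)] <- TRUE
  m
}

#' Ground-truth phenotype of each detected domain
#'
#' Matches detected domain centroids (lattice coordinates) to the
#' nearest planted disk centre.
#'
#' @param spec a `tissue_spec`.
#' @param grid the `expression_grid`.
#' @param labeling a `domain_labeling` of the detected mask.
#' @return character vector of phenotypes, one per detected domain.
#' @export
match_truth_phenotype <- function(spec, grid, labeling) {
  st <- labeling$stats
  cx <- grid$origin[1] + (st$centroid_col + 0.5) * grid$pitch
  cy <- grid$origin[2] + (st$centroid_row + 0.5) * grid$pitch
  nd <- nearest_disk(cx, cy, spec$domains)
  spec$domains$phenotype[nd$domain]
}

#' Simulate a multi-sample cohort
#'
#' All samples share the gene panel and the phenotype rate effects;
#' each sample gets its own seed and, optionally, a sample-specific
#' log-normal nuisance factor applied to every rate (library-depth-like
#' shift).
#'
#' @param n_samples number of sections (>= 2).
#' @param base_spec the shared [tissue_spec()].
#' @param phenotypes optional list of per-sample phenotype vectors
#'   (length `nrow(base_spec$domains)`) overriding the layout.
#' @param nuisance_sd sd of the per-sample log-normal depth factor
#'   (default 0 = none).
#' @param seed integer seed.
#' @return list of per-sample results as in [simulate_tissue()], with
#'   `sample_id` and `patient_id` added.
#' @export
simulate_cohort <- function(n_samples, base_spec = tissue_spec(),
                            phenotypes = NULL, nuisance_sd = 0, seed = 1) {
  if (n_samples < 2L) stop("a cohort needs at least two samples")
  with_seed(seed, {
    depth <- exp(stats::rnorm(n_samples, 0, nuisance_sd))
    seeds <- sample.int(.Machine$integer.max, n_samples)
    lapply(seq_len(n_samples), function(i) {
      sp <- base_spec
      if (!is.null(phenotypes)) sp$domains$phenotype <- phenotypes[[i]]
      sp$gene_model$rates <- sp$gene_model$rates * depth[i]
      sp$gene_model$endo$core_rate <- sp$gene_model$endo$core_rate * depth[i]
      res <- simulate_tissue(sp, seed = seeds[i])
      res$sample_id <- sprintf("sample_%02d", i)
      res$patient_id <- sprintf("patient_%02d", i)
      res
    })
  })
}

#' Planted two-population domain profiles
#'
#' Two well-separated Gaussian profile groups for clustering-recovery
#' checks.
#'
#' @param n_per_group units per group.
#' @param n_genes panel size.
#' @param shift mean separation between the groups (default 4).
#' @param noise_sd within-group sd (default 0.5).
#' @param seed integer seed.
#' @return list with `expr` (matrix) and `label` (1/2 per unit).
#' @export
simulate_profile_groups <- function(n_per_group = 30, n_genes = 20,
                                    shift = 4, noise_sd = 0.5, seed = 1) {
  with_seed(seed, {
    mu1 <- stats::runif(n_genes, 1, 3)
    dir_ <- sample(c(-1, 1), n_genes, replace = TRUE)
    mu2 <- pmax(0, mu1 + dir_ * shift)
    n <- 2L * n_per_group
    expr <- rbind(
      matrix(stats::rnorm(n_per_group * n_genes, rep(mu1, each = n_per_group),
                          noise_sd), n_per_group),
      matrix(stats::rnorm(n_per_group * n_genes, rep(mu2, each = n_per_group),
                          noise_sd), n_per_group))
    expr <- pmax(expr, 0)
    dimnames(expr) <- list(paste0("u", seq_len(n)),
                           sprintf("G%02d", seq_len(n_genes)))
    list(expr = expr, label = rep(1:2, each = n_per_group))
  })
}

#' Planted 1-D progression profiles
#'
#' Units ordered by a latent stage in \[0,1\]; half the genes ramp up
#' with stage, half down, plus Gaussian noise. Used to check that
#' pseudotime recovers the planted ordering.
#'
#' @param n units.
#' @param n_genes panel size.
#' @param noise_sd noise sd (default 0.3).
#' @param seed integer seed.
#' @return list with `expr`, `stage`.
#' @export
simulate_progression_profiles <- function(n = 60, n_genes = 20,
                                          noise_sd = 0.3, seed = 1) {
  with_seed(seed, {
    stage <- seq(0, 1, length.out = n)
    slope <- rep(c(3, -3), length.out = n_genes)
    base <- ifelse(slope > 0, 1, 4)
    expr <- outer(stage, slope) + rep(base, each = n) +
      matrix(stats::rnorm(n * n_genes, 0, noise_sd), n)
    expr <- pmax(expr, 0)
    dimnames(expr) <- list(paste0("u", seq_len(n)),
                           sprintf("G%02d", seq_len(n_genes)))
    list(expr = expr, stage = stage)
  })
}
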