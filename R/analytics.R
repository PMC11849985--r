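#' Pseudobulk clustering, abstract cluster graph and diffusion pseudotime
#'
#' Domain profiles are log-transformed, reduced to principal components,
#' connected by a k-nearest-neighbour graph, partitioned with Leiden
#' community detection and embedded in 2-D. Trajectories are summarised
#' at the cluster level by the ratio of observed to expected
#' inter-cluster kNN edges, and at the domain level by diffusion
#' pseudotime anchored at a root unit inside the chosen root cluster.
#' Every stage is deterministic under a fixed seed.
#'
#' @name analytics
#' @keywords internal
NULL

# run code under a temporary RNG state so library calls stay
# reproducible without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

profile_matrix <- function(profiles) {
  if (inherits(profiles, "domain_profiles")) profiles$expr
  else as.matrix(profiles)
}

# log1p -> PCA scores (centered, unscaled), n_pcs clipped to what the
# data supports
pca_scores <- function(expr, n_pcs) {
  x <- log1p(expr)
  n_pcs <- max(1L, min(n_pcs, nrow(x) - 1L, ncol(x)))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  s <- p$x
  # sign convention: largest-magnitude loading positive, so scores do not
  # flip between runs on permuted input
  for (j in seq_len(ncol(s))) {
    l <- p$rotation[, j]
    if (l[which.max(abs(l))] < 0) s[, j] <- -s[, j]
  }
  s
}

# undirected kNN graph; returns igraph with vertices in row order
knn_graph <- function(scores, k) {
  n <- nrow(scores)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(scores, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  edges <- unique(t(apply(edges, 1, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Cluster domain profiles
#'
#' Pipeline: `log1p` -> PCA (`n_pcs` components) -> kNN graph
#' (`k_neighbors`) -> Leiden community detection (modularity objective,
#' `resolution`) -> 2-D embedding. Clusters are relabeled `1..K` by
#' decreasing size (ties by first member) so labels are stable.
#'
#' @param profiles a `domain_profiles` or plain units x genes matrix.
#' @param n_pcs number of principal components (default 50; clipped to
#'   the data).
#' @param k_neighbors kNN graph degree (default 15; clipped with a
#'   warning when fewer units are available).
#' @param resolution Leiden resolution (default 1).
#' @param seed integer seed controlling every stochastic stage.
#' @param embedding `"umap"` (default) or `"pca"` (first two components).
#'   The embedding backend never affects cluster labels.
#' @return object of class `clustering_result`: list with `cluster`
#'   (named integer vector), `embedding` (units x 2), `scores` (PC
#'   scores), `params`, `seed`.
#' @export
cluster_domains <- function(profiles, n_pcs = 50, k_neighbors = 15,
                            resolution = 1.0, seed = 0,
                            embedding = c("umap", "pca")) {
  embedding <- match.arg(embedding)
  expr <- profile_matrix(profiles)
  if (nrow(expr) < 2L) stop("need at least two units to cluster")
  if (k_neighbors >= nrow(expr)) {
    warning("k_neighbors clipped to n - 1")
    k_neighbors <- nrow(expr) - 1L
  }
  scores <- pca_scores(expr, n_pcs)
  if (all(abs(sweep(scores, 2, scores[1, ])) < 1e-12)) {
    # zero-variance input: every unit identical, one cluster by definition
    emb <- matrix(0, nrow(expr), 2,
                  dimnames = list(rownames(expr), c("dim1", "dim2")))
    return(structure(list(cluster = stats::setNames(rep(1L, nrow(expr)),
                                                    rownames(expr)),
                          embedding = emb, scores = scores,
                          params = list(n_pcs = ncol(scores),
                                        k_neighbors = k_neighbors,
                                        resolution = resolution,
                                        embedding = embedding),
                          seed = seed),
                     class = "clustering_result"))
  }
  g <- knn_graph(scores, k_neighbors)
  cl <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity",
    resolution = resolution, n_iterations = 10L))
  memb <- igraph::membership(cl)
  # stable relabeling: by decreasing size, ties by first occurrence
  sizes <- tabulate(memb)
  first <- vapply(split(seq_along(memb), memb), min, numeric(1))
  ord <- order(-sizes, first)
  relab <- integer(length(ord)); relab[ord] <- seq_along(ord)
  cluster <- stats::setNames(relab[memb], rownames(expr))

  emb <- if (embedding == "umap") {
    nn <- min(k_neighbors, nrow(scores) - 1L)
    with_seed(seed + 1L,
              uwot::umap(scores, n_neighbors = max(2L, nn), n_threads = 1,
                         n_sgd_threads = 0))
  } else scores[, 1:2, drop = FALSE]
  rownames(emb) <- rownames(expr)
  colnames(emb) <- c("dim1", "dim2")

  structure(list(cluster = cluster, embedding = emb, scores = scores,
                 params = list(n_pcs = ncol(scores), k_neighbors = k_neighbors,
                               resolution = resolution, embedding = embedding),
                 seed = seed),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d unit(s), %d cluster(s) (resolution %g, seed %d)\n",
              length(x$cluster), max(x$cluster), x$params$resolution, x$seed))
  invisible(x)
}

# cluster-level abstract graph: observed inter-cluster kNN edges over the
# expectation under a degree-preserving random graph, capped at 1
cluster_graph <- function(g, cluster) {
  deg <- igraph::degree(g)
  m2 <- sum(deg)                       # 2m
  el <- igraph::as_edgelist(g, names = FALSE)
  ci <- cluster[el[, 1]]; cj <- cluster[el[, 2]]
  K <- max(cluster)
  dtot <- vapply(split(deg, cluster), sum, numeric(1))[as.character(seq_len(K))]
  dtot[is.na(dtot)] <- 0
  out <- list(); n <- 0L
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    e_ab <- sum((ci == a & cj == b) | (ci == b & cj == a))
    if (e_ab == 0L) next
    expected <- dtot[a] * dtot[b] / m2
    n <- n + 1L
    out[[n]] <- data.frame(from = a, to = b,
                           connectivity = min(1, e_ab / expected))
  }
  if (n == 0L) data.frame(from = integer(), to = integer(),
                          connectivity = numeric())
  else do.call(rbind, out)
}

# diffusion map of PC scores: adaptive Gaussian kernel on the kNN
# neighbourhood, density-normalised, symmetric eigendecomposition
diffusion_map <- function(scores, k = 15, n_comps = 15) {
  n <- nrow(scores)
  k <- min(k, n - 1L)
  nn <- FNN::get.knn(scores, k = k)
  sigma <- nn$nn.dist[, k]
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-10)
  i <- rep(seq_len(n), k); j <- as.vector(nn$nn.index)
  d2 <- as.vector(nn$nn.dist)^2
  # canonicalise undirected pairs; the kernel is symmetric in (i, j) so
  # a pair seen from both ends carries the same weight
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]; d2 <- d2[keep]
  w <- exp(-d2 / (sigma[lo] * sigma[hi]))
  W <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                            dims = c(n, n))
  q <- Matrix::rowSums(W); q[q == 0] <- 1
  W <- W / outer(q, q)                 # density normalisation (alpha = 1)
  d <- Matrix::rowSums(W); d[d == 0] <- 1
  S <- as.matrix(W / sqrt(outer(d, d)))    # D^-1/2 W D^-1/2, symmetric
  eg <- eigen(S, symmetric = TRUE)
  m <- min(n_comps + 1L, n)
  lambda <- eg$values[seq_len(m)]
  phi <- eg$vectors[, seq_len(m), drop = FALSE] / sqrt(d)  # right eigenvectors
  list(lambda = lambda, phi = phi)
}

#' Abstract cluster graph and diffusion pseudotime
#'
#' Builds the cluster-level graph whose edge confidences compare observed
#' inter-cluster kNN connectivity with the degree-preserving expectation,
#' then computes diffusion pseudotime from a root unit: the domain
#' nearest the root cluster's centroid in PC space. Pseudotime is the
#' diffusion distance to the root, scaled to `[0, 1]`; the root unit has
#' pseudotime 0.
#'
#' @param profiles a `domain_profiles` or matrix (as clustered).
#' @param clustering a `clustering_result` from [cluster_domains()].
#' @param root_cluster id of the root cluster.
#' @param n_dcs number of diffusion components (default 15).
#' @return object of class `trajectory_result`: list with `graph`
#'   (data.frame `from`, `to`, `connectivity`), `pseudotime` (named
#'   vector in \[0,1\]), `root_cluster`, `root_unit`.
#' @export
trajectory <- function(profiles, clustering, root_cluster, n_dcs = 15) {
  stopifnot(inherits(clustering, "clustering_result"))
  cluster <- clustering$cluster
  if (max(cluster) < 2L) stop("trajectory needs at least two clusters")
  if (!root_cluster %in% cluster) stop("root_cluster not present")
  scores <- clustering$scores
  k <- clustering$params$k_neighbors
  g <- knn_graph(scores, k)
  graph <- cluster_graph(g, cluster)

  members <- which(cluster == root_cluster)
  centroid <- colMeans(scores[members, , drop = FALSE])
  root_unit <- members[which.min(colSums((t(scores[members, , drop = FALSE]) -
                                            centroid)^2))]

  dm <- diffusion_map(scores, k = k, n_comps = n_dcs)
  lambda <- dm$lambda; phi <- dm$phi
  keep <- which(lambda < 1 - 1e-10 & lambda > 1e-12)
  scale <- lambda[keep] / (1 - lambda[keep])
  diff_root <- sweep(phi[, keep, drop = FALSE],
                     2, phi[root_unit, keep], "-")
  dpt <- sqrt(rowSums(sweep(diff_root, 2, scale, "*")^2))
  if (max(dpt) > 0) dpt <- dpt / max(dpt)
  names(dpt) <- names(cluster)

  structure(list(graph = graph, pseudotime = dpt,
                 root_cluster = root_cluster,
                 root_unit = names(cluster)[root_unit]),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> root cluster %s (unit %s); %d cluster-graph edge(s)\n",
              x$root_cluster, x$root_unit, nrow(x$graph)))
  invisible(x)
}

#' Gene-by-domain heatmap matrix along a trajectory path
#'
#' Restricts domains to an ordered list of path clusters, orders them by
#' pseudotime, and min-max scales each gene to `[0, 1]`. Genes constant
#' along the path scale to an all-zero row and are listed in the
#' `flat_genes` attribute.
#'
#' @param profiles a `domain_profiles` or matrix.
#' @param clustering a `clustering_result`.
#' @param pseudotime named pseudotime vector (e.g. from [trajectory()]).
#' @param path_clusters clusters making up the path.
#' @param genes genes (rows) to include.
#' @return genes x domains matrix, columns in pseudotime order, with
#'   attributes `pseudotime` and `flat_genes`.
#' @export
path_heatmap <- function(profiles, clustering, pseudotime, path_clusters,
                         genes) {
  expr <- profile_matrix(profiles)
  stopifnot(inherits(clustering, "clustering_result"))
  missing_cl <- setdiff(path_clusters, clustering$cluster)
  if (length(missing_cl)) stop("path cluster(s) absent: ",
                               paste(missing_cl, collapse = ", "))
  j <- match(genes, colnames(expr))
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  on_path <- names(clustering$cluster)[clustering$cluster %in% path_clusters]
  if (!length(on_path)) stop("empty path")
  ord <- on_path[order(pseudotime[on_path])]
  m <- t(expr[ord, j, drop = FALSE])
  rownames(m) <- genes
  flat <- character()
  for (r in seq_len(nrow(m))) {
    rng <- range(m[r, ])
    if (diff(rng) == 0) { m[r, ] <- 0; flat <- c(flat, genes[r]) }
    else m[r, ] <- (m[r, ] - rng[1]) / diff(rng)
  }
  attr(m, "pseudotime") <- pseudotime[ord]
  attr(m, "flat_genes") <- flat
  m
}

#' Concatenate per-sample domain profiles for integrated analysis
#'
#' Columns are restricted to the shared gene panel (intersection, with
#' dropped genes reported); rows are concatenated with sample and
#' optional patient provenance so downstream clustering runs unchanged
#' on the combined matrix.
#'
#' @param profile_list list of `domain_profiles` (or matrices).
#' @param sample_ids one id per list element (default list names).
#' @param patient_ids optional, one per element.
#' @return a `domain_profiles` whose `meta` carries `sample_id` (and
#'   `patient_id`), rownames `"<sample>.d<k>"`.
#' @export
integrate_samples <- function(profile_list, sample_ids = names(profile_list),
                              patient_ids = NULL) {
  stopifnot(length(profile_list) >= 1L)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(profile_list))
  exprs <- lapply(profile_list, profile_matrix)
  panel <- Reduce(intersect, lapply(exprs, colnames))
  if (!length(panel)) stop("empty shared gene panel across samples")
  dropped <- unique(unlist(lapply(exprs, function(e) setdiff(colnames(e), panel))))
  if (length(dropped))
    message("integrate_samples: dropped ", length(dropped),
            " gene(s) outside the shared panel")
  rows <- list(); metas <- list()
  for (i in seq_along(exprs)) {
    e <- exprs[[i]][, panel, drop = FALSE]
    rownames(e) <- paste(sample_ids[i], rownames(e) %||% seq_len(nrow(e)),
                         sep = ".")
    meta <- if (inherits(profile_list[[i]], "domain_profiles"))
      profile_list[[i]]$meta
    else data.frame(domain = seq_len(nrow(e)))
    meta$sample_id <- sample_ids[i]
    if (!is.null(patient_ids)) meta$patient_id <- patient_ids[i]
    rownames(meta) <- rownames(e)
    rows[[i]] <- e; metas[[i]] <- meta
  }
  common_cols <- Reduce(intersect, lapply(metas, names))
  meta <- do.call(rbind, lapply(metas, `[`, common_cols))
  structure(list(expr = do.call(rbind, rows), meta = meta,
                 gene_names = panel),
            class = "domain_profiles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
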