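test_that("identical duplicated profiles collapse to a single cluster", {
  expr <- matrix(rep(c(1, 2, 3, 4, 5), each = 20), 20,
                 dimnames = list(paste0("u", 1:20), paste0("G", 1:5)))
  cl <- cluster_domains(expr, n_pcs = 3, k_neighbors = 5, seed = 1,
                        embedding = "pca")
  expect_equal(max(cl$cluster), 1L)
})

test_that("two planted profile populations are recovered exactly", {
  sim <- simulate_profile_groups(n_per_group = 30, seed = 2)
  cl <- cluster_domains(sim$expr, seed = 7)
  expect_equal(max(cl$cluster), 2L)
  expect_equal(ari(cl$cluster, sim$label), 1.0)
})

test_that("clustering is deterministic under a fixed seed", {
  sim <- simulate_profile_groups(n_per_group = 20, shift = 2, seed = 3)
  a <- cluster_domains(sim$expr, seed = 11)
  b <- cluster_domains(sim$expr, seed = 11)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$embedding, b$embedding)
})

test_that("k_neighbors larger than the data is clipped with a warning", {
  sim <- simulate_profile_groups(n_per_group = 5, seed = 4)
  expect_warning(cl <- cluster_domains(sim$expr, k_neighbors = 50, seed = 1,
                                       embedding = "pca"),
                 "clipped")
  expect_equal(length(cl$cluster), 10L)
})

test_that("cluster count is non-decreasing in resolution", {
  sim <- simulate_profile_groups(n_per_group = 25, shift = 2.5, seed = 5)
  ks <- vapply(c(0.25, 0.5, 1, 2, 4), function(res)
    max(cluster_domains(sim$expr, resolution = res, seed = 9,
                        embedding = "pca")$cluster), numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("pseudotime is anchored at zero inside the root cluster", {
  sim <- simulate_profile_groups(n_per_group = 30, seed = 6)
  cl <- cluster_domains(sim$expr, seed = 13)
  tr <- trajectory(sim$expr, cl, root_cluster = 1)
  expect_equal(min(tr$pseudotime), 0)
  root_members <- names(cl$cluster)[cl$cluster == 1]
  expect_true(names(which.min(tr$pseudotime)) %in% root_members)
  expect_equal(unname(tr$pseudotime[tr$root_unit]), 0)
  expect_true(all(is.finite(tr$pseudotime)))
})

test_that("planted 1-D progression is recovered by pseudotime", {
  sim <- simulate_progression_profiles(n = 60, seed = 8)
  cl <- cluster_domains(sim$expr, resolution = 1, seed = 21)
  root <- cl$cluster[[which.min(sim$stage)]]
  tr <- trajectory(sim$expr, cl, root_cluster = root)
  rho <- abs(cor(tr$pseudotime, sim$stage, method = "spearman"))
  expect_gte(rho, 0.9)
})

test_that("pseudotime is invariant to gene order, row order and cluster relabeling", {
  sim <- simulate_progression_profiles(n = 40, seed = 9)
  cl <- cluster_domains(sim$expr, seed = 5)
  tr <- trajectory(sim$expr, cl, root_cluster = 1)

  # permute gene columns
  perm <- sample(ncol(sim$expr))
  cl_g <- cluster_domains(sim$expr[, perm], seed = 5)
  tr_g <- trajectory(sim$expr[, perm], cl_g, root_cluster = 1)
  expect_equal(tr_g$pseudotime, tr$pseudotime, tolerance = 1e-8)

  # relabel clusters by permutation: same members, renamed root
  relab <- max(cl$cluster) + 1L - cl$cluster   # reverse the labels
  cl2 <- cl; cl2$cluster <- stats::setNames(relab, names(cl$cluster))
  tr2 <- trajectory(sim$expr, cl2, root_cluster = max(cl$cluster))
  expect_equal(tr2$pseudotime, tr$pseudotime, tolerance = 1e-12)
})

test_that("trajectory rejects degenerate clusterings", {
  expr <- matrix(rep(c(1, 2), each = 12), 12,
                 dimnames = list(paste0("u", 1:12), c("A", "B")))
  cl <- cluster_domains(expr, k_neighbors = 4, seed = 2, embedding = "pca")
  expect_equal(max(cl$cluster), 1L)
  expect_error(trajectory(expr, cl, root_cluster = 1), "two clusters")
})

test_that("cluster graph edges report observed/expected connectivity in (0, 1]", {
  sim <- simulate_profile_groups(n_per_group = 30, shift = 2, seed = 10)
  cl <- cluster_domains(sim$expr, seed = 3)
  if (max(cl$cluster) >= 2) {
    tr <- trajectory(sim$expr, cl, root_cluster = 1)
    expect_true(all(tr$graph$connectivity > 0 & tr$graph$connectivity <= 1))
    expect_true(all(tr$graph$from < tr$graph$to))
  }
})

test_that("path heatmap orders columns by pseudotime and scales rows to [0,1]", {
  sim <- simulate_progression_profiles(n = 50, seed = 12)
  expr <- cbind(sim$expr, FLAT = 2)
  cl <- cluster_domains(expr, seed = 4)
  root <- cl$cluster[[1]]
  tr <- trajectory(expr, cl, root_cluster = root)
  hm <- path_heatmap(expr, cl, tr$pseudotime,
                     path_clusters = sort(unique(cl$cluster)),
                     genes = c("G01", "G02", "FLAT"))
  pt <- attr(hm, "pseudotime")
  expect_false(is.unsorted(pt))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_equal(attr(hm, "flat_genes"), "FLAT")
  expect_true(all(hm["FLAT", ] == 0))
  # a planted monotone gene stays monotone after scaling, up to noise
  expect_gte(abs(cor(hm["G01", ], seq_along(pt), method = "spearman")), 0.8)
  expect_error(path_heatmap(expr, cl, tr$pseudotime, 99, "G01"), "absent")
})

test_that("sample integration concatenates rows over the shared panel", {
  a <- simulate_profile_groups(10, n_genes = 8, seed = 1)$expr
  b <- simulate_profile_groups(12, n_genes = 8, seed = 2)$expr
  both <- integrate_samples(list(s1 = a, s2 = b))
  expect_equal(nrow(both$expr), nrow(a) + nrow(b))
  expect_equal(both$meta$sample_id, rep(c("s1", "s2"), c(nrow(a), nrow(b))))

  colnames(b)[1:2] <- c("X1", "X2")
  expect_message(part <- integrate_samples(list(s1 = a, s2 = b)), "dropped")
  expect_equal(ncol(part$expr), 6)

  colnames(b) <- paste0("Z", 1:8)
  expect_error(integrate_samples(list(s1 = a, s2 = b)), "empty")
})

test_that("integrated planted cohort clusters by phenotype, not by sample", {
  base <- small_spec(n_domains = 9, field = c(900, 900), radius = 60)
  cohort <- simulate_cohort(2, base_spec = base,
                            phenotypes = list(
                              rep(c("baseline", "infiltrated"), length.out = 9),
                              rep(c("infiltrated", "baseline"), length.out = 9)),
                            seed = 33)
  profs <- lapply(cohort, function(s) {
    g <- build_grid(s$cells, 10)
    lab <- segment_domains(detect_domain(g, marker_spec("EPCAM")))
    pr <- domain_expression(g, lab)
    pr$meta$phenotype <- match_truth_phenotype(s$spec, g, lab)
    pr
  })
  merged <- integrate_samples(profs, sample_ids = c("s1", "s2"))
  cl <- cluster_domains(merged, k_neighbors = 5, seed = 19, embedding = "pca")
  pheno_ari <- ari(cl$cluster, merged$meta$phenotype)
  sample_ari <- ari(cl$cluster, merged$meta$sample_id)
  expect_gte(pheno_ari, 0.8)
  expect_lt(sample_ari, pheno_ari)
})
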