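# density table built by hand: 2 domains x 2 sections x 2 genes
toy_density <- function() {
  data.frame(domain = rep(1:2, each = 4),
             lower = rep(c(0, 0, 30, 30), 2),
             upper = rep(c(30, 30, 60, 60), 2),
             n_grids = 4,
             gene = rep(c("A", "B"), 4),
             density = c(2, 1, 4, 2, 3, 1.5, 6, 3),
             group = rep(c("g1", "g2"), each = 4))
}

test_that("expression density is total counts over squares, empty sections missing", {
  set.seed(9)
  nr <- 8; nc <- 8
  counts <- matrix(rpois(nr * nc * 2, 3), nr * nc,
                   dimnames = list(NULL, c("A", "B")))
  g <- structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                      n_cols = nc, n_rows = nr, pitch = 10, origin = c(0, 0),
                      gene_names = c("A", "B")),
                 class = "expression_grid")
  sections <- data.frame(domain = 1, lower = 0, upper = 30,
                         col = c(0, 1, 2, 3), row = c(0, 0, 1, 1))
  d <- expression_density(g, sections)
  gids <- grid_index(sections$col, sections$row, nc)
  expect_equal(d$density[d$gene == "A"], sum(counts[gids, "A"]) / 4)
  expect_equal(d$density[d$gene == "B"], sum(counts[gids, "B"]) / 4)
  expect_equal(unique(d$n_grids), 4L)

  # a section of 4 squares with total count 8 has density 2
  g2 <- g
  g2$counts[gids, "A"] <- 2
  expect_equal(expression_density(g2, sections)$density[1], 2)
})

test_that("density equals brute-force sum/size on random fixtures", {
  set.seed(40)
  for (rep in 1:5) {
    nr <- 10; nc <- 12
    counts <- matrix(rpois(nr * nc, 2), nr * nc, dimnames = list(NULL, "A"))
    g <- structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                        n_cols = nc, n_rows = nr, pitch = 10, origin = c(0, 0),
                        gene_names = "A"),
                   class = "expression_grid")
    n_sq <- sample(3:10, 1)
    pick <- sample(nr * nc, n_sq)
    sections <- data.frame(domain = 1, lower = 0, upper = 30,
                           col = (pick - 1) %% nc, row = (pick - 1) %/% nc)
    d <- expression_density(g, sections)
    gids <- grid_index(sections$col, sections$row, nc)
    expect_equal(d$density, sum(counts[gids, 1]) / n_sq)
  }
})

test_that("noiseless data with no group effect gives exactly zero group terms", {
  # density depends on section only: y = 1 + 0.5 * section for both groups
  sec <- rep(c(15, 45, 75), times = 4)
  grp <- rep(c("a", "b"), each = 6)
  d <- data.frame(domain = rep(1:4, each = 3), lower = sec - 15, upper = sec + 15,
                  n_grids = 1, gene = "A", density = 1 + 0.5 * sec, group = grp)
  fit <- fit_section_glm(d, "A")
  s <- fit$summary
  expect_equal(s$estimate[s$term == "section"], 0.5, tolerance = 1e-10)
  expect_equal(s$estimate[s$term == "groupb"], 0, tolerance = 1e-10)
  expect_equal(s$estimate[s$term == "section:groupb"], 0, tolerance = 1e-10)
})

test_that("planted slope and interaction are recovered to machine precision without noise", {
  sec <- rep(c(15, 45, 75, 105), times = 6)
  grp <- rep(c("a", "b"), each = 12)
  y <- 2 + 0.3 * sec + ifelse(grp == "b", 1.5 + 0.2 * sec, 0)
  d <- data.frame(domain = rep(1:6, each = 4), lower = sec - 15, upper = sec + 15,
                  n_grids = 1, gene = "A", density = y, group = grp)
  s <- fit_section_glm(d, "A")$summary
  expect_equal(s$estimate[s$term == "section"], 0.3, tolerance = 1e-10)
  expect_equal(s$estimate[s$term == "groupb"], 1.5, tolerance = 1e-8)
  expect_equal(s$estimate[s$term == "section:groupb"], 0.2, tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  d <- toy_density()
  d1 <- d[d$lower == 0, ]
  expect_error(fit_section_glm(d1, "A"), "section")
  d2 <- d; d2$group <- "same"
  expect_error(fit_section_glm(d2, "A"), "two groups")
})

test_that("planted effects fall inside their own 95% CIs at the nominal rate", {
  # reduced version of the coverage study (full run in the acceptance suite)
  set.seed(123)
  hits_beta <- 0; hits_gamma <- 0; n_rep <- 25
  for (r in 1:n_rep) {
    n <- 200
    sec <- sample(c(15, 45, 75, 105), n, replace = TRUE)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    y <- 1 + 0.02 * sec + ifelse(grp == "b", 0.01 * sec + 0.5, 0) + rnorm(n, 0, 0.5)
    d <- data.frame(domain = seq_len(n), lower = sec - 15, upper = sec + 15,
                    n_grids = 1, gene = "A", density = y, group = grp)
    s <- fit_section_glm(d, "A")$summary
    b <- s[s$term == "section", ]
    g <- s[s$term == "section:groupb", ]
    hits_beta <- hits_beta + (b$ci_lo <= 0.02 && 0.02 <= b$ci_hi)
    hits_gamma <- hits_gamma + (g$ci_lo <= 0.01 && 0.01 <= g$ci_hi)
  }
  expect_gte(hits_beta, 21)
  expect_gte(hits_gamma, 21)
})

test_that("correlation screen reproduces brute-force Pearson and the threshold filter", {
  set.seed(55)
  n_sec <- 6
  genes <- sprintf("G%02d", 1:20)
  prof <- matrix(rnorm(n_sec * 20, 5), n_sec, dimnames = list(NULL, genes))
  prof[, "G02"] <- prof[, "G01"] * 2 + 1          # r = 1 with G01
  prof[, "G03"] <- -prof[, "G01"]                 # r = -1
  d <- do.call(rbind, lapply(genes, function(g)
    data.frame(domain = 1, lower = seq(0, by = 30, length.out = n_sec),
               upper = seq(30, by = 30, length.out = n_sec),
               n_grids = 1, gene = g, density = prof[, g])))
  scr <- correlate_with_reference(d, "G01", threshold = 0.75)
  ct <- scr$correlations
  for (g in genes)
    expect_equal(ct$r[ct$gene == g], cor(prof[, g], prof[, "G01"]),
                 tolerance = 1e-12)
  expect_true("G02" %in% scr$passing)
  expect_false("G03" %in% scr$passing)
  expect_false("G01" %in% scr$passing)            # reference excluded
  brute <- setdiff(genes[apply(prof, 2, function(v)
    cor(v, prof[, "G01"])) >= 0.75], "G01")
  expect_setequal(scr$passing, brute)
  # self-correlation is reported as exactly 1
  expect_equal(ct$r[ct$gene == "G01"], 1)
})

test_that("zero-variance genes are excluded from the screen, not scored", {
  d <- toy_density()
  d$density[d$gene == "B"] <- 2               # constant profile
  scr <- correlate_with_reference(d, "A", threshold = 0.5)
  expect_false("B" %in% scr$correlations$gene)
})

test_that("Kruskal-Wallis comparison behaves under null and shifted alternatives", {
  set.seed(71)
  # type-I error near the nominal level
  rejects <- 0; n_sim <- 400
  for (r in seq_len(n_sim)) {
    v <- rnorm(30)
    cl <- rep(1:3, each = 10)
    if (compare_sections(v, cl)$p < 0.05) rejects <- rejects + 1
  }
  expect_lt(abs(rejects / n_sim - 0.05), 0.035)

  # strong shift at n = 20/cluster is detected
  v <- c(rnorm(20), rnorm(20), rnorm(20) + 10)
  cl <- rep(1:3, each = 20)
  res <- compare_sections(v, cl, n_tests = 5)
  expect_lt(res$p, 0.001)
  expect_equal(res$p_bonferroni, min(1, res$p * 5))

  expect_error(compare_sections(rnorm(10), rep(1, 10)), "two clusters")
  expect_error(compare_sections(rnorm(3), c(1, 2, 2)), "at least two observations")
})
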