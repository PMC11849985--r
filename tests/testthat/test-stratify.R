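# a small field with two square domains and a known distance field
two_domain_fixture <- function() {
  m <- matrix(FALSE, 30, 40)
  m[8:13, 6:11] <- TRUE
  m[18:23, 26:31] <- TRUE
  b <- extract_boundary(m)
  f <- compute_distance_field(m, b, pitch = 10)
  list(mask = m, boundary = b, field = f, labeling = segment_domains(m))
}

test_that("half-open shell edges: mu = 0 and mu = width fall below, interiors inside", {
  fx <- two_domain_fixture()
  sh <- stratify_shells(fx$field)
  lab0 <- sh$levels$label[sh$index[fx$field$mu == 0][1]]
  expect_equal(lab0, "(-30,0]")
  # synthesize exact values to probe interval edges
  f <- fx$field
  f$mu[1, 1] <- 30; f$mu[1, 2] <- 30.0001; f$mu[1, 3] <- 10 * sqrt(2)
  sh2 <- stratify_shells(f)
  expect_equal(sh2$levels$label[sh2$index[1, 1]], "(0,30]")
  expect_equal(sh2$levels$label[sh2$index[1, 2]], "(30,60]")
  expect_equal(sh2$levels$label[sh2$index[1, 3]], "(0,30]")
})

test_that("shells partition exactly the in-range squares on random fields", {
  set.seed(99)
  for (rep in 1:20) {
    m <- random_mask(25, 25, p = runif(1, 0.1, 0.5))
    if (!any(m)) next
    f <- compute_distance_field(m, pitch = 10)
    sh <- stratify_shells(f)
    in_range <- f$mu > -120 & f$mu <= 150
    expect_identical(!is.na(sh$index), in_range)
    # brute-force interval assignment agrees square by square
    assigned <- sh$index[in_range]
    mu <- f$mu[in_range]
    expect_true(all(mu > sh$levels$lower[assigned] & mu <= sh$levels$upper[assigned]))
  }
})

test_that("shell range must be divisible by the width", {
  fx <- two_domain_fixture()
  expect_error(stratify_shells(fx$field, width = 30, lower = -100, upper = 150),
               "divisible")
  expect_error(stratify_shells(fx$field, width = -30), "positive")
})

test_that("a single domain keeps its full shell-in-rectangle section", {
  m <- matrix(FALSE, 30, 30); m[13:18, 13:18] <- TRUE
  lab <- segment_domains(m)
  f <- compute_distance_field(m, pitch = 10)
  sh <- stratify_shells(f)
  ps <- exclusive_outer_sections(lab, sh, x = 0, pitch = 10)
  # with one domain the exclusion term is empty: PS = P intersect R
  shell <- !is.na(sh$index) & sh$levels$lower[sh$index] == 0
  rect <- spatialshell:::domain_rectangles(lab, 0, 30, 10)
  in_rect <- matrix(FALSE, 30, 30)
  in_rect[(rect$row_min:rect$row_max) + 1, (rect$col_min:rect$col_max) + 1] <- TRUE
  expect_equal(sort(which(shell & in_rect)), sort(ps$col * 30 + ps$row + 1))
  expect_true(all(ps$domain == 1))
})

test_that("far-apart domains lose no squares to the exclusion term", {
  m <- matrix(FALSE, 40, 80)
  m[5:10, 5:10] <- TRUE
  m[30:35, 65:70] <- TRUE
  lab <- segment_domains(m)
  f <- compute_distance_field(m, pitch = 10)
  sh <- stratify_shells(f)
  ps <- exclusive_outer_sections(lab, sh, x = 0, pitch = 10)
  # both domains present, and each PS equals its own P-in-rectangle
  rects <- spatialshell:::domain_rectangles(lab, 0, 30, 10)
  shell <- !is.na(sh$index) & sh$levels$lower[sh$index] == 0
  for (d in 1:2) {
    in_rect <- matrix(FALSE, 40, 80)
    in_rect[(rects$row_min[d]:rects$row_max[d]) + 1,
            (rects$col_min[d]:rects$col_max[d]) + 1] <- TRUE
    expect_equal(sum(ps$domain == d), sum(shell & in_rect))
  }
})

test_that("three adjacent domains match brute-force evaluation of the set formula", {
  m <- matrix(FALSE, 30, 60)
  m[12:17, 6:11] <- TRUE       # S1
  m[12:17, 24:29] <- TRUE      # S2
  m[12:17, 42:47] <- TRUE      # S3
  lab <- segment_domains(m)
  f <- compute_distance_field(m, pitch = 10)
  sh <- stratify_shells(f)
  for (x in c(0, 30)) {
    ps <- exclusive_outer_sections(lab, sh, x = x, pitch = 10)
    lev <- which(sh$levels$lower == x)
    shell <- !is.na(sh$index) & sh$index == lev
    rects <- spatialshell:::domain_rectangles(lab, x, 30, 10)
    oracle <- oracle_ps(shell, rects)
    for (d in 1:3) {
      got <- matrix(FALSE, 30, 60)
      rows <- ps[ps$domain == d, ]
      got[cbind(rows$row + 1, rows$col + 1)] <- TRUE
      expect_identical(got, oracle[[d]])
    }
  }
})

test_that("exclusive sections are pairwise disjoint and shrink as domains are added", {
  set.seed(4)
  m <- matrix(FALSE, 35, 35)
  m[4:9, 4:9] <- TRUE; m[4:9, 20:25] <- TRUE; m[24:29, 12:17] <- TRUE
  lab <- segment_domains(m)
  f <- compute_distance_field(m, pitch = 10)
  sh <- stratify_shells(f)
  ps <- exclusive_outer_sections(lab, sh, x = 0, pitch = 10)
  key <- paste(ps$col, ps$row)
  expect_false(anyDuplicated(key) > 0)

  # removing one domain from the picture can only grow the others
  m2 <- m; m2[24:29, 12:17] <- FALSE
  lab2 <- segment_domains(m2)
  f2 <- compute_distance_field(m2, pitch = 10)
  sh2 <- stratify_shells(f2)
  ps2 <- exclusive_outer_sections(lab2, sh2, x = 0, pitch = 10)
  for (d in 1:2) {
    k1 <- paste(ps$col[ps$domain == d], ps$row[ps$domain == d])
    k2 <- paste(ps2$col[ps2$domain == d], ps2$row[ps2$domain == d])
    expect_true(all(k1 %in% k2))
  }
})

test_that("inner sections are the domain's own squares, disjoint across domains", {
  fx <- two_domain_fixture()
  sh <- stratify_shells(fx$field)
  inner <- inner_sections(fx$labeling, sh)
  expect_true(all(inner$upper <= 0))
  for (i in seq_len(nrow(inner)))
    expect_equal(fx$labeling$labels[inner$row[i] + 1, inner$col[i] + 1],
                 inner$domain[i])
  expect_equal(nrow(inner), sum(fx$mask))
})

test_that("section means match direct summation and empty sections are missing", {
  set.seed(60)
  counts <- matrix(rpois(200 * 3, 2), 200)
  colnames(counts) <- c("A", "B", "C")
  grid <- structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                         n_cols = 20, n_rows = 10, pitch = 10,
                         origin = c(0, 0), gene_names = colnames(counts)),
                    class = "expression_grid")
  sec <- data.frame(col = c(0, 1, 5), row = c(0, 0, 3))
  got <- section_expression(grid, sec)
  gids <- grid_index(sec$col, sec$row, 20)
  expect_equal(unname(got), unname(colMeans(counts[gids, ])))

  empty <- section_expression(grid, data.frame(col = integer(), row = integer()))
  expect_true(all(is.na(empty)))

  const <- structure(list(counts = Matrix::Matrix(matrix(7, 50, 1,
                            dimnames = list(NULL, "A")), sparse = TRUE),
                          n_cols = 10, n_rows = 5, pitch = 10,
                          origin = c(0, 0), gene_names = "A"),
                     class = "expression_grid")
  expect_equal(unname(section_expression(const, data.frame(col = 0:3, row = 0))["A"]), 7)
})
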