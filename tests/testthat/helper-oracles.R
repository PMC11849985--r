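# Independent brute-force oracles. Each is written as directly as
# possible from the definition it checks, and shares no code with the
# package implementation.

# double-loop binning: counts per (col, row, gene) from first principles
oracle_bin <- function(x, y, counts, pitch) {
  x0 <- floor(min(x) / pitch) * pitch
  y0 <- floor(min(y) / pitch) * pitch
  out <- list()
  for (i in seq_along(x)) {
    key <- paste(floor((x[i] - x0) / pitch), floor((y[i] - y0) / pitch))
    out[[key]] <- if (is.null(out[[key]])) counts[i, ] else out[[key]] + counts[i, ]
  }
  out
}

# sliding-window binary median with replicate padding
oracle_median <- function(mask, kernel = 3L) {
  h <- kernel %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- logical(0)
    for (di in -h:h) for (dj in -h:h) {
      ii <- min(max(i + di, 1L), nr)
      jj <- min(max(j + dj, 1L), nc)
      vals <- c(vals, mask[ii, jj])
    }
    out[i, j] <- median(vals) > 0.5
  }
  out
}

# 8-neighbour scan: boundary = mask square with a background neighbour
# (lattice border counts as background)
oracle_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj])
        out[i, j] <- TRUE
    }
  }
  out
}

# union-find connected components under 8-connectivity, labeled in
# raster order of each component's first square
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- seq_len(nr * nc)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  at <- function(i, j) (j - 1L) * nr + i
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj])
        union_(at(i, j), at(ii, jj))
    }
  }
  labels <- matrix(0L, nr, nc)
  nxt <- 0L; seen <- integer(0)
  # raster order: rows outer, cols inner
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    r <- find(at(i, j))
    k <- match(r, seen)
    if (is.na(k)) { seen <- c(seen, r); nxt <- nxt + 1L; k <- nxt }
    labels[i, j] <- k
  }
  labels
}

# O(V^2) Dijkstra without a priority queue on the full 8-connected
# lattice; returns distances (pitch units) from the nearest source
oracle_dijkstra <- function(nr, nc, src_rc) {
  n <- nr * nc
  dist <- rep(Inf, n)
  at <- function(r, c) (r - 1L) * nc + c
  for (k in seq_len(nrow(src_rc))) dist[at(src_rc[k, 1], src_rc[k, 2])] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    d2 <- dist; d2[done] <- Inf
    u <- which.min(d2)
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    r <- (u - 1L) %/% nc + 1L; c <- (u - 1L) %% nc + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      w <- if (dr != 0 && dc != 0) sqrt(2) else 1
      v <- at(rr, cc)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc, byrow = TRUE)
}

# closed-form octile metric from a single source on an obstacle-free
# lattice
oracle_octile <- function(nr, nc, r0, c0) {
  m <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dr <- abs(r - r0); dc <- abs(c - c0)
    m[r, c] <- max(dr, dc) + (sqrt(2) - 1) * min(dr, dc)
  }
  m
}

# brute-force evaluation of the exclusive-section set formula on
# explicit grid sets; rects is a data.frame of 0-based inclusive boxes
oracle_ps <- function(shell_mask, rects) {
  nr <- nrow(shell_mask); nc <- ncol(shell_mask)
  in_rect <- function(d, i, j)   # i, j are 1-based matrix indices
    (j - 1) >= rects$col_min[d] && (j - 1) <= rects$col_max[d] &&
    (i - 1) >= rects$row_min[d] && (i - 1) <= rects$row_max[d]
  D <- nrow(rects)
  pairwise <- matrix(FALSE, nr, nc)
  if (D >= 2) for (a in 1:(D - 1)) for (b in (a + 1):D)
    for (i in seq_len(nr)) for (j in seq_len(nc))
      if (in_rect(a, i, j) && in_rect(b, i, j)) pairwise[i, j] <- TRUE
  out <- list()
  for (d in seq_len(D)) {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc))
      m[i, j] <- shell_mask[i, j] && in_rect(d, i, j) && !pairwise[i, j]
    out[[d]] <- m
  }
  out
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random binary lattice with tunable fill
random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# tiny tissue spec that keeps simulation fast in unit tests
small_spec <- function(n_domains = 4, field = c(600, 600), radius = 60,
                       phenotype = "alternate") {
  tissue_spec(field = field,
              domains = default_domains(n_domains, field, radius, phenotype))
}
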