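#' Marker-defined spatial-domain detection
#'
#' A spatial domain is the set of lattice squares expressing at least one
#' positive marker and no negative marker, denoised with a single 3x3
#' median (majority) filter, then split into connected components under
#' 8-connectivity. Masks are logical `n_rows x n_cols` matrices aligned
#' with the `expression_grid` they were derived from.
#'
#' @name domain_detect
#' @keywords internal
NULL

#' Marker specification
#'
#' @param positive nonempty character vector of positive marker genes.
#' @param negative character vector of negative marker genes (may be empty).
#' @return object of class `marker_spec`.
#' @export
marker_spec <- function(positive, negative = character()) {
  positive <- as.character(positive); negative <- as.character(negative)
  if (length(positive) == 0L) stop("at least one positive marker is required")
  both <- intersect(positive, negative)
  if (length(both)) stop("markers listed as both positive and negative: ",
                         paste(both, collapse = ", "))
  structure(list(positive = positive, negative = negative),
            class = "marker_spec")
}

check_markers <- function(grid, markers) {
  unknown <- setdiff(c(markers$positive, markers$negative), grid$gene_names)
  if (length(unknown))
    stop("marker gene(s) absent from grid: ", paste(unknown, collapse = ", "))
}

#' Pre-domain mask from marker logic
#'
#' True where the summed positive-marker count is > 0 and the summed
#' negative-marker count is 0 (logical subtraction of the
#' negative-expressing squares from the positive-expressing squares).
#'
#' @param grid an `expression_grid`.
#' @param markers a [marker_spec()].
#' @return logical `n_rows x n_cols` mask.
#' @export
detect_pre_domain <- function(grid, markers) {
  stopifnot(inherits(grid, "expression_grid"), inherits(markers, "marker_spec"))
  check_markers(grid, markers)
  pos <- Matrix::rowSums(grid$counts[, markers$positive, drop = FALSE])
  neg <- if (length(markers$negative))
    Matrix::rowSums(grid$counts[, markers$negative, drop = FALSE]) else 0
  v <- pos > 0 & neg == 0
  matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Median (majority) denoising of a binary mask
#'
#' Each square is replaced by the majority value of its `kernel x kernel`
#' window, with replicate padding at the lattice border; applied once.
#' For a binary image this is exactly the median blur used on label
#' images in image-processing pipelines.
#'
#' @param mask logical matrix.
#' @param kernel odd window size >= 3 (default 3).
#' @return denoised logical mask of the same dimensions.
#' @export
median_denoise <- function(mask, kernel = 3L) {
  stopifnot(is.matrix(mask))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) stop("kernel must be odd and >= 3")
  h <- kernel %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  # replicate-pad then accumulate shifted windows
  pi <- pmin(pmax(seq_len(nr + 2L * h) - h, 1L), nr)
  pj <- pmin(pmax(seq_len(nc + 2L * h) - h, 1L), nc)
  pad <- matrix(as.integer(mask[pi, pj]), nrow = nr + 2L * h)
  acc <- matrix(0L, nr, nc)
  for (di in 0:(kernel - 1L)) for (dj in 0:(kernel - 1L))
    acc <- acc + pad[di + seq_len(nr), dj + seq_len(nc)]
  acc * 2L > kernel * kernel
}

#' Boundary squares of a domain mask
#'
#' A domain square belongs to the boundary when at least one of its eight
#' neighbours is background; the lattice border counts as background, so
#' domains truncated by the capture area keep a closed contour.
#'
#' @param mask logical matrix.
#' @return logical matrix marking boundary squares (a subset of `mask`).
#' @export
extract_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  # zero-pad (border = background), then count in-mask neighbours
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  nb <- matrix(0L, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1L && dj == 1L) next
    nb <- nb + pad[di + seq_len(nr), dj + seq_len(nc)]
  }
  mask & nb < 8L
}

#' Segment a mask into individual spatial domains
#'
#' Connected components under 8-connectivity, labeled `1..D` in
#' deterministic raster order (order of each component's first square,
#' row-major). Per-domain area, bounding box (0-based, inclusive) and
#' centroid are populated.
#'
#' @param mask logical matrix.
#' @return object of class `domain_labeling`: list with `labels` (integer
#'   matrix, 0 = background), `n_domains`, and `stats` (data.frame:
#'   `domain`, `area`, `col_min`, `col_max`, `row_min`, `row_max`,
#'   `centroid_col`, `centroid_row`).
#' @export
segment_domains <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)                      # column-major positions of true squares
  if (length(idx)) {
    row <- (idx - 1L) %% nr               # 0-based
    col <- (idx - 1L) %/% nr
    key <- row * nc + col                 # raster order key
    pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
    edges <- mask_adjacency_edges(mask, pos)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    # relabel components by raster order of their first square
    first_key <- vapply(split(key, comp), min, numeric(1))
    relab <- integer(length(first_key))
    relab[order(first_key)] <- seq_along(first_key)
    lab <- relab[comp]
    labels[idx] <- lab
    stats <- data.frame(
      domain = seq_len(max(lab)),
      area = as.integer(tabulate(lab)),
      col_min = vapply(split(col, lab), min, numeric(1)),
      col_max = vapply(split(col, lab), max, numeric(1)),
      row_min = vapply(split(row, lab), min, numeric(1)),
      row_max = vapply(split(row, lab), max, numeric(1)),
      centroid_col = vapply(split(col, lab), mean, numeric(1)),
      centroid_row = vapply(split(row, lab), mean, numeric(1)),
      row.names = NULL)
  } else {
    stats <- data.frame(domain = integer(), area = integer(),
                        col_min = numeric(), col_max = numeric(),
                        row_min = numeric(), row_max = numeric(),
                        centroid_col = numeric(), centroid_row = numeric())
  }
  structure(list(labels = labels, n_domains = nrow(stats), stats = stats),
            class = "domain_labeling")
}

#' @export
print.domain_labeling <- function(x, ...) {
  cat(sprintf("<domain_labeling> %d domain(s), %d foreground square(s)\n",
              x$n_domains, sum(x$labels > 0L)))
  invisible(x)
}

# Edge list (as a 2-column matrix of 1..n indices into the true squares)
# linking 8-adjacent true squares of `mask`; pos maps matrix positions to
# the 1..n ordering.
mask_adjacency_edges <- function(mask, pos) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- vector("list", 4L)
  k <- 0L
  # four forward directions cover all 8 neighbours of an undirected graph
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    di <- d[1]; dj <- d[2]
    i1 <- max(1L, 1L - di):min(nr, nr - di)
    j1 <- max(1L, 1L - dj):min(nc, nc - dj)
    a <- mask[i1, j1, drop = FALSE] & mask[i1 + di, j1 + dj, drop = FALSE]
    w <- which(a)
    if (length(w)) {
      ii <- i1[(w - 1L) %% length(i1) + 1L]
      jj <- j1[(w - 1L) %/% length(i1) + 1L]
      from <- pos[(jj - 1L) * nr + ii]
      to <- pos[(jj + dj - 1L) * nr + ii + di]
      k <- k + 1L
      out[[k]] <- cbind(from, to)
    }
  }
  if (k == 0L) matrix(integer(), ncol = 2L) else do.call(rbind, out[seq_len(k)])
}

#' Jaccard agreement between two masks
#'
#' \eqn{|A \cap B| / |A \cup B|}; defined as 1 when both masks are empty.
#' Used to compare domain calls between methods or against ground truth.
#'
#' @param mask_a,mask_b logical matrices of identical dimensions.
#' @return numeric in \[0, 1\].
#' @export
jaccard <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must have identical dimensions")
  u <- sum(mask_a | mask_b)
  if (u == 0L) return(1)
  sum(mask_a & mask_b) / u
}

#' Full detection pass: marker logic then median denoise
#'
#' @inheritParams detect_pre_domain
#' @param kernel odd median window (default 3).
#' @return denoised logical domain mask.
#' @export
detect_domain <- function(grid, markers, kernel = 3L) {
  median_denoise(detect_pre_domain(grid, markers), kernel = kernel)
}

#' Write a mask or labeling as a delimited long table
#'
#' @param m logical mask or integer label matrix.
#' @param path output path; columns `col`, `row` (0-based) and `value`
#'   for the nonzero squares.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path) {
  idx <- which(m != 0)
  nr <- nrow(m)
  dt <- data.table::data.table(col = (idx - 1L) %/% nr,
                               row = (idx - 1L) %% nr,
                               value = as.integer(m[idx]))
  data.table::setorder(dt, row, col)
  data.table::fwrite(dt, path)
  invisible(path)
}
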