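#' Cell tables and the expression lattice
#'
#' Imaging-based in situ platforms (e.g. 10x Xenium) deliver a per-cell
#' coordinate table and a cell-by-gene count matrix. All downstream domain
#' detection operates on a fixed-pitch lattice ("grid") onto which cell
#' counts are binned, so the first step is to join the two files and bin.
#'
#' @name grid_io
#' @keywords internal
NULL

#' Construct a cell table
#'
#' @param cell_id character vector of unique cell identifiers.
#' @param x,y numeric centroid coordinates in micrometres (non-negative).
#' @param counts cell-by-gene count matrix (dense or `dgCMatrix`), rows
#'   aligned with `cell_id`.
#' @param gene_names character vector naming the columns of `counts`.
#' @return An object of class `cell_table`: a list with elements
#'   `cell_id`, `x`, `y`, `counts` (sparse `dgCMatrix`), `gene_names`.
#' @export
cell_table <- function(cell_id, x, y, counts, gene_names = colnames(counts)) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("cell_id values must be unique")
  if (length(x) != length(cell_id) || length(y) != length(cell_id))
    stop("x/y length must match cell_id")
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(cell_id))
    stop("counts must have one row per cell")
  if (is.null(gene_names)) stop("gene_names required")
  if (length(gene_names) != ncol(counts))
    stop("gene_names length must match ncol(counts)")
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  dimnames(counts) <- list(cell_id, gene_names)
  structure(
    list(cell_id = cell_id, x = as.numeric(x), y = as.numeric(y),
         counts = counts, gene_names = as.character(gene_names)),
    class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells x %d genes; x in [%.1f, %.1f], y in [%.1f, %.1f] um\n",
              length(x$cell_id), length(x$gene_names),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Load cells from a count matrix and a coordinate table
#'
#' Reads a cell-by-gene count matrix (MatrixMarket triplet with gene and
#' cell index files, or a delimited dense table with a cell-id column) and
#' a Xenium-style coordinate CSV (`cell_id`, `x_centroid`, `y_centroid`),
#' and joins them on cell identifier. Gzip input is accepted transparently.
#'
#' Cells present in only one of the two sources are dropped with a logged
#' count; if the dropped fraction exceeds `max_mismatch` of the union the
#' join is considered corrupt and loading aborts.
#'
#' @param matrix_source path to `matrix.mtx[.gz]` (with sibling
#'   `features.tsv`/`genes.tsv` and `barcodes.tsv`, possibly gzipped) or to
#'   a delimited dense counts table whose first column is the cell id.
#' @param coords_source path to the coordinates CSV.
#' @param max_mismatch maximum tolerated fraction of cells missing from
#'   either source (default 0.5).
#' @return A [cell_table()].
#' @export
load_cells <- function(matrix_source, coords_source, max_mismatch = 0.5) {
  coords <- data.table::fread(coords_source)
  need <- c("cell_id", "x_centroid", "y_centroid")
  if (!all(need %in% names(coords)))
    stop("coords file must contain columns: ", paste(need, collapse = ", "))
  cm <- read_count_matrix(matrix_source)

  ids_m <- rownames(cm)
  ids_c <- as.character(coords$cell_id)
  common <- intersect(ids_m, ids_c)
  n_union <- length(union(ids_m, ids_c))
  dropped <- n_union - length(common)
  if (length(common) == 0L || dropped / n_union > max_mismatch)
    stop(sprintf("cell id mismatch between matrix and coords: only %d of %d ids shared",
                 length(common), n_union))
  if (dropped > 0L)
    message(sprintf("load_cells: dropped %d cell(s) missing from one source", dropped))

  coords <- coords[match(common, ids_c), ]
  cell_table(cell_id = common,
             x = coords$x_centroid, y = coords$y_centroid,
             counts = cm[common, , drop = FALSE])
}

# Reads MTX triplet (+ index files) or a dense delimited table into a
# cells x genes sparse matrix with cell ids as rownames.
read_count_matrix <- function(path) {
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    m <- Matrix::readMM(if (grepl("\\.gz$", path)) gzfile(path) else path)
    dir <- dirname(path)
    feat <- sibling_file(dir, c("features.tsv", "genes.tsv"))
    barc <- sibling_file(dir, "barcodes.tsv")
    genes <- data.table::fread(feat, header = FALSE)
    cells <- data.table::fread(barc, header = FALSE)
    gene_names <- as.character(genes[[min(2L, ncol(genes))]])
    cell_ids <- as.character(cells[[1L]])
    # CellRanger-style MTX is genes x cells; transpose to cells x genes
    if (nrow(m) == length(gene_names) && ncol(m) == length(cell_ids)) {
      m <- Matrix::t(m)
    } else if (!(nrow(m) == length(cell_ids) && ncol(m) == length(gene_names))) {
      stop("MTX dimensions do not match index files")
    }
    m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                     "CsparseMatrix")
    dimnames(m) <- list(cell_ids, gene_names)
    m
  } else {
    dt <- data.table::fread(path)
    ids <- as.character(dt[[1L]])
    m <- Matrix::Matrix(as.matrix(dt[, -1L, drop = FALSE]), sparse = TRUE)
    rownames(m) <- ids
    m
  }
}

sibling_file <- function(dir, stems) {
  for (s in stems) for (f in file.path(dir, c(s, paste0(s, ".gz"))))
    if (file.exists(f)) return(f)
  stop("missing index file next to matrix: ", paste(stems, collapse = " or "))
}

#' Bin a cell table onto a fixed-pitch expression lattice
#'
#' Each cell contributes all of its counts to the grid square containing
#' its centroid, under the half-open bin convention
#' \eqn{[k \cdot pitch, (k+1) \cdot pitch)}. Grid indices are 0-based; the
#' lattice origin is the minimum cell coordinate rounded down to a pitch
#' multiple, and is stored so lattice coordinates can be mapped back to
#' micrometres.
#'
#' @param cells a [cell_table()].
#' @param pitch grid pitch in micrometres (default 10).
#' @return An object of class `expression_grid`: list with `counts`
#'   (sparse grid-by-gene `dgCMatrix`, one row per lattice square in
#'   raster order), `n_cols`, `n_rows`, `pitch`, `origin` (c(x0, y0) um),
#'   `gene_names`.
#' @export
build_grid <- function(cells, pitch = 10) {
  stopifnot(inherits(cells, "cell_table"))
  if (pitch <= 0) stop("pitch must be positive")
  if (length(cells$cell_id) == 0L) stop("empty cell table")
  x0 <- floor(min(cells$x) / pitch) * pitch
  y0 <- floor(min(cells$y) / pitch) * pitch
  col <- as.integer(floor((cells$x - x0) / pitch))
  row <- as.integer(floor((cells$y - y0) / pitch))
  n_cols <- max(col) + 1L
  n_rows <- max(row) + 1L
  gid <- grid_index(col, row, n_cols)
  # aggregate cell rows landing on the same grid square
  agg <- Matrix::sparseMatrix(i = gid, j = seq_along(gid), x = 1,
                              dims = c(n_cols * n_rows, length(gid)))
  counts <- methods::as(methods::as(methods::as(agg %*% cells$counts,
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  colnames(counts) <- cells$gene_names
  structure(
    list(counts = counts, n_cols = n_cols, n_rows = n_rows,
         pitch = pitch, origin = c(x0, y0), gene_names = cells$gene_names),
    class = "expression_grid")
}

#' @export
print.expression_grid <- function(x, ...) {
  cat(sprintf("<expression_grid> %d cols x %d rows at %g um pitch; %d genes; %s total counts\n",
              x$n_cols, x$n_rows, x$pitch, length(x$gene_names),
              format(sum(x$counts))))
  invisible(x)
}

#' Linear raster index of a lattice square
#'
#' Maps 0-based `(col, row)` to the 1-based row index of the grid-by-gene
#' count matrix (raster order: row-major, column fastest).
#' @param col,row 0-based lattice coordinates.
#' @param n_cols lattice width.
#' @return integer indices.
#' @export
grid_index <- function(col, row, n_cols) as.integer(row) * n_cols + as.integer(col) + 1L

#' Inverse of [grid_index()]
#' @param gid 1-based linear index.
#' @param n_cols lattice width.
#' @return data.frame with 0-based `col`, `row`.
#' @export
grid_coords <- function(gid, n_cols) {
  gid0 <- as.integer(gid) - 1L
  data.frame(col = gid0 %% n_cols, row = gid0 %/% n_cols)
}

#' Total counts of one gene per lattice square, as a matrix
#'
#' @param grid an `expression_grid`.
#' @param gene gene name.
#' @return numeric `n_rows x n_cols` matrix (row r, col c holds grid
#'   (c-1, r-1)).
#' @export
gene_matrix <- function(grid, gene) {
  stopifnot(inherits(grid, "expression_grid"))
  j <- match(gene, grid$gene_names)
  if (is.na(j)) stop("unknown gene: ", gene)
  v <- as.numeric(grid$counts[, j])
  matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Write an expression grid as a long table plus JSON sidecar
#'
#' The long table has columns `col`, `row` (0-based), `gene`, `count` and
#' contains only nonzero entries; the sidecar records pitch, origin and
#' dimensions so [read_grid()] can reproduce the object exactly.
#'
#' @param grid an `expression_grid`.
#' @param path output path for the delimited table; the sidecar is written
#'   next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "expression_grid"))
  tm <- methods::as(grid$counts, "TsparseMatrix")
  cr <- grid_coords(tm@i + 1L, grid$n_cols)
  dt <- data.table::data.table(col = cr$col, row = cr$row,
                               gene = grid$gene_names[tm@j + 1L],
                               count = tm@x)
  data.table::setorder(dt, row, col, gene)
  data.table::fwrite(dt, path)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(pitch = grid$pitch, origin = grid$origin,
         n_cols = grid$n_cols, n_rows = grid$n_rows,
         gene_names = grid$gene_names),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an expression grid written by [write_grid()]
#' @param path path to the delimited long table (sidecar expected beside it).
#' @return an `expression_grid`.
#' @export
read_grid <- function(path) {
  side <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dt <- data.table::fread(path)
  gj <- match(dt$gene, meta$gene_names)
  if (anyNA(gj)) stop("grid table contains genes absent from sidecar")
  counts <- Matrix::sparseMatrix(
    i = grid_index(dt$col, dt$row, meta$n_cols), j = gj, x = dt$count,
    dims = c(meta$n_cols * meta$n_rows, length(meta$gene_names)),
    dimnames = list(NULL, meta$gene_names))
  structure(
    list(counts = counts, n_cols = meta$n_cols, n_rows = meta$n_rows,
         pitch = meta$pitch, origin = meta$origin, gene_names = meta$gene_names),
    class = "expression_grid")
}

#' Write a cell table in the MTX + coordinates dialect read by [load_cells()]
#'
#' @param cells a [cell_table()].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` and `cells.csv`.
#' @return `dir`, invisibly.
#' @export
write_cells <- function(cells, dir) {
  stopifnot(inherits(cells, "cell_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # genes x cells, CellRanger orientation
  Matrix::writeMM(Matrix::t(cells$counts), file.path(dir, "matrix.mtx"))
  writeLines(paste(cells$gene_names, cells$gene_names, "Gene Expression",
                   sep = "\t"), file.path(dir, "features.tsv"))
  writeLines(cells$cell_id, file.path(dir, "barcodes.tsv"))
  data.table::fwrite(
    data.table::data.table(cell_id = cells$cell_id,
                           x_centroid = cells$x, y_centroid = cells$y),
    file.path(dir, "cells.csv"))
  invisible(dir)
}
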