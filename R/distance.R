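#' Signed boundary-distance field
#'
#' Every lattice square is connected to its eight neighbours with edge
#' weight 1 (orthogonal) or \eqn{\sqrt 2} (diagonal), in pitch units. The
#' distance of a square is the shortest weighted path length to the
#' nearest boundary square, computed by multi-source Dijkstra with all
#' boundary squares as sources, then scaled to micrometres and signed:
#' negative strictly inside the domain, zero on the boundary, positive
#' outside. Paths may traverse any square; the domain is not an obstacle.
#'
#' @param mask logical domain mask.
#' @param boundary logical boundary mask, a subset of `mask`; defaults to
#'   [extract_boundary()] of `mask`.
#' @param pitch lattice pitch in micrometres (default 10).
#' @return object of class `distance_field`: list with `mu` (numeric
#'   `n_rows x n_cols` signed distance in um), `pitch`, and `degenerate`
#'   (TRUE when the mask was empty, in which case `mu` is all `+Inf`).
#' @export
compute_distance_field <- function(mask, boundary = extract_boundary(mask),
                                   pitch = 10) {
  stopifnot(is.matrix(mask), identical(dim(mask), dim(boundary)))
  if (any(boundary & !mask)) stop("boundary must be a subset of the mask")
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) {
    return(structure(list(mu = matrix(Inf, nr, nc), pitch = pitch,
                          degenerate = TRUE), class = "distance_field"))
  }
  if (!any(boundary)) stop("boundary empty for a nonempty mask")
  idx <- which(boundary)                       # column-major
  src0 <- ((idx - 1L) %/% nr) + ((idx - 1L) %% nr) * nc   # 0-based raster
  d <- lattice_msd(nr, nc, as.integer(src0))
  mu <- matrix(d, nrow = nr, ncol = nc, byrow = TRUE) * pitch
  inside <- mask & !boundary
  mu[inside] <- -mu[inside]
  structure(list(mu = mu, pitch = pitch, degenerate = FALSE),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  if (x$degenerate) cat("<distance_field> degenerate (empty mask)\n")
  else cat(sprintf("<distance_field> mu in [%.1f, %.1f] um at pitch %g\n",
                   min(x$mu), max(x$mu), x$pitch))
  invisible(x)
}

#' Write a distance field as a delimited long table
#' @param field a `distance_field`.
#' @param path output path; columns `col`, `row` (0-based), `mu` (um).
#' @return `path`, invisibly.
#' @export
write_distance_field <- function(field, path) {
  stopifnot(inherits(field, "distance_field"))
  nr <- nrow(field$mu); nc <- ncol(field$mu)
  dt <- data.table::data.table(
    col = rep(0:(nc - 1L), each = nr),
    row = rep(0:(nr - 1L), nc),
    mu = as.numeric(field$mu))
  data.table::setorder(dt, row, col)
  data.table::fwrite(dt, path)
  invisible(path)
}
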