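#' Distance-stratified shells and exclusive per-domain sections
#'
#' The signed distance field is cut into half-open 30-um shells
#' \eqn{P_{(x, x+30]}} spanning (-120, +150] um by default. Inner shells
#' (upper bound <= 0) are attributed to domains by intersecting with each
#' domain's own squares. Outer shells are shared space, so each domain
#' gets an exclusive outer section: the shell restricted to the domain's
#' bounding rectangle expanded to contain the shell, minus every square
#' claimed by two or more expanded rectangles. Ambiguous squares belong
#' to no domain's microenvironment.
#'
#' @name stratify
#' @keywords internal
NULL

#' Cut a distance field into half-open shells
#'
#' Each square with \eqn{\mu \in (lower, upper]} is assigned to exactly
#' one shell by the rule \eqn{x < \mu \le x + width}; squares outside the
#' range stay unassigned.
#'
#' @param field a `distance_field`.
#' @param width shell width in um (default 30).
#' @param lower,upper range covered, um; `upper - lower` must be a
#'   multiple of `width` (defaults -120 and +150).
#' @return object of class `shell_map`: list with `levels` (data.frame
#'   `lower`, `upper`, `label`), `index` (integer matrix of level row
#'   numbers, NA outside the range), `width`.
#' @export
stratify_shells <- function(field, width = 30, lower = -120, upper = 150) {
  stopifnot(inherits(field, "distance_field"))
  if (width <= 0) stop("width must be positive")
  if (lower >= upper) stop("lower must be below upper")
  k <- (upper - lower) / width
  if (abs(k - round(k)) > 1e-9) stop("(upper - lower) must be divisible by width")
  breaks <- seq(lower, upper, by = width)
  levels <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L])
  levels$label <- sprintf("(%g,%g]", levels$lower, levels$upper)
  idx <- matrix(findInterval(field$mu, breaks, left.open = TRUE),
                nrow(field$mu), ncol(field$mu))
  idx[idx < 1L | idx > nrow(levels) | !is.finite(field$mu)] <- NA_integer_
  # findInterval(left.open=TRUE) puts mu == lower bound into the interval
  # below, giving exactly x < mu <= x + width
  structure(list(levels = levels, index = idx, width = width),
            class = "shell_map")
}

#' @export
print.shell_map <- function(x, ...) {
  cat(sprintf("<shell_map> %d shells of %g um: %s .. %s; %d assigned square(s)\n",
              nrow(x$levels), x$width, x$levels$label[1],
              x$levels$label[nrow(x$levels)], sum(!is.na(x$index))))
  invisible(x)
}

# 0-based expanded, clipped bounding rectangles for every domain at an
# outer level x (expansion (x + width) um per side by default; the
# literal "enlarge by x" reading is available via expand_by_x).
domain_rectangles <- function(labeling, x, width, pitch, expand_by_x = FALSE) {
  st <- labeling$stats
  e <- if (expand_by_x) x / pitch else (x + width) / pitch
  e <- as.integer(ceiling(e - 1e-9))
  nr <- nrow(labeling$labels); nc <- ncol(labeling$labels)
  data.frame(domain = st$domain,
             col_min = pmax(0L, st$col_min - e),
             col_max = pmin(nc - 1L, st$col_max + e),
             row_min = pmax(0L, st$row_min - e),
             row_max = pmin(nr - 1L, st$row_max + e))
}

#' Exclusive outer sections at one shell level
#'
#' For outer level `x` (shell \eqn{(x, x+width]}), each domain's bounding
#' rectangle is expanded by `x + width` um per side and clipped to the
#' lattice, giving \eqn{R_d}. The exclusive section of domain `d` is the
#' shell intersected with \eqn{R_d}, minus the union of all pairwise
#' rectangle intersections \eqn{R_i \cap R_j} (i < j) at this level, so
#' no square is attributed to two domains.
#'
#' @param labeling a `domain_labeling`.
#' @param shells a `shell_map` from [stratify_shells()].
#' @param x lower edge of the outer level in um (0, 30, 60, ...).
#' @param pitch lattice pitch in um (default 10).
#' @param expand_by_x expand rectangles by `x` um instead of `x + width`
#'   (the narrower literal reading; default FALSE).
#' @return data.frame with columns `domain`, `col`, `row` (0-based) of
#'   every square in some domain's exclusive section at this level.
#' @export
exclusive_outer_sections <- function(labeling, shells, x, pitch = 10,
                                     expand_by_x = FALSE) {
  stopifnot(inherits(labeling, "domain_labeling"), inherits(shells, "shell_map"))
  lev <- which(abs(shells$levels$lower - x) < 1e-9)
  if (!length(lev)) stop("no shell level starts at x = ", x)
  if (x < 0) stop("exclusive sections are defined for outer levels (x >= 0)")
  nr <- nrow(shells$index); nc <- ncol(shells$index)
  empty <- data.frame(domain = integer(), col = integer(), row = integer())
  if (labeling$n_domains == 0L) return(empty)
  shell <- !is.na(shells$index) & shells$index == lev
  rects <- domain_rectangles(labeling, x, shells$width, pitch, expand_by_x)

  # squares covered by >= 2 expanded rectangles (union of pairwise
  # intersections): accumulate coverage counts rectangle by rectangle
  cover <- matrix(0L, nr, nc)
  for (d in seq_len(nrow(rects))) {
    ri <- (rects$row_min[d]:rects$row_max[d]) + 1L
    ci <- (rects$col_min[d]:rects$col_max[d]) + 1L
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  contested <- cover >= 2L

  out <- vector("list", nrow(rects))
  for (d in seq_len(nrow(rects))) {
    m <- matrix(FALSE, nr, nc)
    ri <- (rects$row_min[d]:rects$row_max[d]) + 1L
    ci <- (rects$col_min[d]:rects$col_max[d]) + 1L
    m[ri, ci] <- TRUE
    ps <- which(shell & m & !contested)
    if (length(ps))
      out[[d]] <- data.frame(domain = rects$domain[d],
                             col = (ps - 1L) %/% nr, row = (ps - 1L) %% nr)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$domain, res$row, res$col), , drop = FALSE]
}

#' Per-domain inner sections
#'
#' Inner shells (upper bound <= 0) intersected with each domain's own
#' squares; domains are disjoint components, so no exclusion logic is
#' needed.
#'
#' @inheritParams exclusive_outer_sections
#' @return data.frame `domain`, `lower`, `upper`, `col`, `row`.
#' @export
inner_sections <- function(labeling, shells) {
  stopifnot(inherits(labeling, "domain_labeling"), inherits(shells, "shell_map"))
  nr <- nrow(shells$index)
  inner_lev <- which(shells$levels$upper <= 1e-9)
  keep <- which(labeling$labels > 0L & !is.na(shells$index) &
                  shells$index %in% inner_lev)
  res <- data.frame(domain = labeling$labels[keep],
                    lower = shells$levels$lower[shells$index[keep]],
                    upper = shells$levels$upper[shells$index[keep]],
                    col = (keep - 1L) %/% nr, row = (keep - 1L) %% nr)
  res[order(res$domain, res$lower, res$row, res$col), , drop = FALSE]
}

#' All stratified sections of every domain
#'
#' Combines [inner_sections()] with [exclusive_outer_sections()] run at
#' every outer level of the shell map.
#'
#' @inheritParams exclusive_outer_sections
#' @return data.frame `domain`, `lower`, `upper`, `col`, `row` (0-based).
#' @export
stratify_domains <- function(labeling, shells, pitch = 10, expand_by_x = FALSE) {
  inner <- inner_sections(labeling, shells)
  outer_x <- shells$levels$lower[shells$levels$lower >= -1e-9]
  outer <- lapply(outer_x, function(x) {
    ps <- exclusive_outer_sections(labeling, shells, x, pitch, expand_by_x)
    if (nrow(ps)) cbind(ps[, "domain", drop = FALSE],
                        lower = x, upper = x + shells$width,
                        ps[, c("col", "row")])
    else NULL
  })
  outer <- outer[!vapply(outer, is.null, logical(1))]
  res <- rbind(inner, if (length(outer)) do.call(rbind, outer))
  rownames(res) <- NULL
  res
}

#' Mean per-gene expression of a set of squares
#'
#' The expression of a stratified section is the arithmetic mean count
#' per square for every gene. An empty section has no defined mean and
#' yields `NA` for every gene (never zero).
#'
#' @param grid an `expression_grid`.
#' @param section data.frame with 0-based `col`, `row` columns (any extra
#'   columns ignored), or a logical mask.
#' @return named numeric vector, one mean per gene.
#' @export
section_expression <- function(grid, section) {
  stopifnot(inherits(grid, "expression_grid"))
  gids <- section_gids(grid, section)
  if (length(gids) == 0L)
    return(stats::setNames(rep(NA_real_, length(grid$gene_names)),
                           grid$gene_names))
  stats::setNames(Matrix::colMeans(grid$counts[gids, , drop = FALSE]),
                  grid$gene_names)
}

section_gids <- function(grid, section) {
  if (is.matrix(section) && is.logical(section)) {
    idx <- which(section)
    nr <- nrow(section)
    grid_index((idx - 1L) %/% nr, (idx - 1L) %% nr, grid$n_cols)
  } else {
    stopifnot(all(c("col", "row") %in% names(section)))
    grid_index(section$col, section$row, grid$n_cols)
  }
}

#' Mean expression of every (domain, level) section
#'
#' @param grid an `expression_grid`.
#' @param sections data.frame from [stratify_domains()].
#' @param genes genes to report (default all).
#' @return data.frame `domain`, `lower`, `upper`, `n_grids`, one column
#'   per gene holding the section mean.
#' @export
section_expression_table <- function(grid, sections, genes = grid$gene_names) {
  stopifnot(inherits(grid, "expression_grid"))
  j <- match(genes, grid$gene_names)
  if (anyNA(j)) stop("unknown gene(s): ", paste(genes[is.na(j)], collapse = ", "))
  gids <- grid_index(sections$col, sections$row, grid$n_cols)
  key <- interaction(sections$domain, sections$lower, drop = TRUE)
  groups <- split(gids, key)
  meta <- sections[!duplicated(key), c("domain", "lower", "upper")]
  meta <- meta[order(meta$domain, meta$lower), ]
  ord <- match(interaction(meta$domain, meta$lower, drop = TRUE), names(groups))
  means <- vapply(groups[ord], function(g)
    Matrix::colMeans(grid$counts[g, j, drop = FALSE]),
    numeric(length(j)))
  means <- if (length(j) == 1L) matrix(means, ncol = 1L) else t(means)
  out <- cbind(meta,
               n_grids = lengths(groups[ord])[seq_len(nrow(meta))],
               as.data.frame(means))
  names(out)[-(1:4)] <- genes
  rownames(out) <- NULL
  out
}
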