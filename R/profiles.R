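#' Domain pseudobulk profiles, alpha diversity and spatial autocorrelation
#'
#' Each spatial domain is summarised as its mean per-square expression
#' vector (a pseudobulk profile); these profiles are the unit for
#' clustering, trajectory inference and diversity comparison. Diversity
#' uses the classic count-based alpha indices; spatial structure within
#' clusters is measured with Geary's C on the lattice adjacency.
#'
#' @name profiles
#' @keywords internal
NULL

#' Per-domain mean expression profiles
#'
#' One row per domain; value = mean count per square over the domain's
#' squares, for every gene.
#'
#' @param grid an `expression_grid`.
#' @param labeling a `domain_labeling` aligned to `grid`.
#' @return object of class `domain_profiles`: list with `expr` (domains x
#'   genes numeric matrix, rownames `d<k>`), `meta` (data.frame `domain`,
#'   `area`, `centroid_col`, `centroid_row`, plus `sample_id` /
#'   `patient_id` when known), `gene_names`.
#' @export
domain_expression <- function(grid, labeling) {
  stopifnot(inherits(grid, "expression_grid"), inherits(labeling, "domain_labeling"))
  if (!all(dim(labeling$labels) == c(grid$n_rows, grid$n_cols)))
    stop("labeling dimensions do not match grid")
  idx <- which(labeling$labels > 0L)
  lab <- labeling$labels[idx]
  nr <- grid$n_rows
  gids <- grid_index((idx - 1L) %/% nr, (idx - 1L) %% nr, grid$n_cols)
  D <- labeling$n_domains
  ind <- Matrix::sparseMatrix(i = lab, j = gids,
                              x = 1 / labeling$stats$area[lab],
                              dims = c(D, nrow(grid$counts)))
  expr <- as.matrix(ind %*% grid$counts)
  dimnames(expr) <- list(paste0("d", seq_len(D)), grid$gene_names)
  meta <- data.frame(domain = seq_len(D),
                     area = labeling$stats$area,
                     centroid_col = labeling$stats$centroid_col,
                     centroid_row = labeling$stats$centroid_row,
                     row.names = rownames(expr))
  structure(list(expr = expr, meta = meta, gene_names = grid$gene_names),
            class = "domain_profiles")
}

#' @export
print.domain_profiles <- function(x, ...) {
  cat(sprintf("<domain_profiles> %d domain(s) x %d genes", nrow(x$expr),
              ncol(x$expr)))
  extra <- setdiff(names(x$meta),
                   c("domain", "area", "centroid_col", "centroid_row"))
  if (length(extra)) cat("; meta: ", paste(extra, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Bias-corrected Chao1 richness
#'
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}, where \eqn{S_{obs}} is
#' the number of detected features, \eqn{F_1} the number of singletons
#' and \eqn{F_2} the number of doubletons. The classic (uncorrected)
#' estimator \eqn{S_{obs} + F_1^2 / (2 F_2)} is available via
#' `bias_corrected = FALSE`.
#'
#' @param counts nonnegative count vector.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return richness estimate (0 for an all-zero vector).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs
}

#' Shannon entropy of a count vector
#'
#' \eqn{-\sum p_i \log_b p_i} over the nonzero proportions; base 2
#' (bits) by default.
#'
#' @param counts nonnegative vector with positive total.
#' @param base logarithm base (default 2).
#' @return entropy.
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("shannon undefined for zero total count")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Number of detected features
#'
#' @param counts nonnegative vector.
#' @return number of strictly positive entries.
#' @export
observed_features <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  sum(counts > 0)
}

#' Alpha diversity of every row of a profile or count matrix
#'
#' @param m units x features nonnegative matrix.
#' @return data.frame with `chao1`, `shannon`, `observed` per row.
#' @export
alpha_diversity <- function(m) {
  m <- as.matrix(m)
  data.frame(chao1 = apply(m, 1, chao1),
             shannon = apply(m, 1, function(v) if (sum(v) > 0) shannon(v) else NA_real_),
             observed = apply(m, 1, observed_features),
             row.names = rownames(m))
}

#' Geary's C spatial autocorrelation
#'
#' \deqn{C = \frac{(n-1) \sum_i \sum_j w_{ij} (x_i - x_j)^2}
#'            {2 W \sum_i (x_i - \bar x)^2}}
#' with \eqn{W = \sum_{ij} w_{ij}}. Values below 1 indicate positive
#' spatial autocorrelation. The statistic is undefined for a constant
#' field or an empty weight matrix.
#'
#' @param values numeric vector (one value per spatial unit).
#' @param weights symmetric nonnegative matrix (or `dgCMatrix`) of
#'   spatial weights; typically binary adjacency.
#' @return Geary's C.
#' @export
gearys_c <- function(values, weights) {
  n <- length(values)
  if (n < 2L) stop("need at least two units")
  if (!all(dim(weights) == n)) stop("weights must be n x n")
  ss <- sum((values - mean(values))^2)
  if (ss == 0) stop("constant field: Geary's C undefined")
  W <- sum(weights)
  if (W == 0) stop("no edges: Geary's C undefined")
  if (inherits(weights, "sparseMatrix")) {
    tm <- methods::as(weights, "TsparseMatrix")
    num <- sum(tm@x * (values[tm@i + 1L] - values[tm@j + 1L])^2)
  } else {
    num <- sum(weights * outer(values, values, "-")^2)
  }
  (n - 1) * num / (2 * W * ss)
}

#' Binary 8-adjacency weights for a set of lattice squares
#'
#' @param col,row 0-based lattice coordinates of the units.
#' @return sparse symmetric binary adjacency matrix.
#' @export
grid_adjacency <- function(col, row) {
  n <- length(col)
  stopifnot(length(row) == n)
  key <- paste(col, row)
  lookup <- stats::setNames(seq_len(n), key)
  from <- integer(); to <- integer()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- lookup[paste(col + d[1], row + d[2])]
    hit <- which(!is.na(nb))
    from <- c(from, hit); to <- c(to, nb[hit])
  }
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                       dims = c(n, n))
}

#' Geary's C of one gene over the squares of selected domains
#'
#' Units are the lattice squares of the given domains; weights are the
#' binary 8-adjacency among those squares.
#'
#' @param grid an `expression_grid`.
#' @param labeling a `domain_labeling`.
#' @param gene gene name.
#' @param domains domain ids to include (default all).
#' @return Geary's C.
#' @export
domain_gearys_c <- function(grid, labeling, gene, domains = NULL) {
  stopifnot(inherits(grid, "expression_grid"), inherits(labeling, "domain_labeling"))
  lab <- labeling$labels
  keep <- if (is.null(domains)) which(lab > 0L) else which(lab %in% domains)
  nr <- nrow(lab)
  col <- (keep - 1L) %/% nr; row <- (keep - 1L) %% nr
  j <- match(gene, grid$gene_names)
  if (is.na(j)) stop("unknown gene: ", gene)
  vals <- as.numeric(grid$counts[grid_index(col, row, grid$n_cols), j])
  gearys_c(vals, grid_adjacency(col, row))
}

#' Write domain profiles as a delimited table
#' @param profiles a `domain_profiles`.
#' @param path output path; metadata columns precede gene columns.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "domain_profiles"))
  data.table::fwrite(cbind(profiles$meta, as.data.frame(profiles$expr)), path)
  invisible(path)
}
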