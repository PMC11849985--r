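#' Section-level expression density and group comparisons
#'
#' Microenvironment composition is quantified as expression density per
#' stratified section (total counts divided by the number of lattice
#' squares in the section) and compared between groups with a linear
#' model containing section, group and their interaction, with a Pearson
#' correlation screen against a reference gene's section profile, and
#' with Kruskal-Wallis omnibus tests across clusters.
#'
#' @name micro_stats
#' @keywords internal
NULL

#' Expression density per (unit, section, gene)
#'
#' Density is the summed count of a gene over the section's squares
#' divided by the number of squares (counts per square). Empty sections
#' have no density and are returned as missing, never as zero.
#'
#' @param grid an `expression_grid`.
#' @param sections data.frame from [stratify_domains()] (columns
#'   `domain`, `lower`, `upper`, `col`, `row`).
#' @param genes genes to tabulate (default all).
#' @param groups optional named vector mapping domain id to a group
#'   label (e.g. histology); joined onto the output.
#' @return data.frame `domain`, `lower`, `upper`, `n_grids`, `gene`,
#'   `density` (+ `group` when supplied), one row per (domain, section,
#'   gene) with a nonempty section.
#' @export
expression_density <- function(grid, sections, genes = grid$gene_names,
                               groups = NULL) {
  tab <- section_expression_table(grid, sections, genes)
  long <- do.call(rbind, lapply(genes, function(g)
    data.frame(domain = tab$domain, lower = tab$lower, upper = tab$upper,
               n_grids = tab$n_grids, gene = g, density = tab[[g]])))
  # mean per square == total / n_grids, the density definition
  if (!is.null(groups)) long$group <- unname(groups[as.character(long$domain)])
  rownames(long) <- NULL
  long[!is.na(long$density), , drop = FALSE]
}

#' Linear model of density on section, group and their interaction
#'
#' Fits `density ~ section * group` for one gene, with sections coded
#' either ordinally (interval midpoint in um, default) or categorically.
#' The Gaussian family with identity link is the default; a Poisson/log
#' alternative is available for count-like densities.
#'
#' @param density data.frame from [expression_density()] with a `group`
#'   column (exactly two levels).
#' @param gene gene to model.
#' @param section_coding `"ordinal"` (midpoint, default) or `"categorical"`.
#' @param family a [stats::family] object (default `gaussian()`).
#' @return object of class `section_glm`: list with `fit` (the `glm`
#'   object) and `summary` (data.frame `term`, `estimate`, `ci_lo`,
#'   `ci_hi`, `p` — Wald 95% intervals).
#' @export
fit_section_glm <- function(density, gene,
                            section_coding = c("ordinal", "categorical"),
                            family = stats::gaussian()) {
  section_coding <- match.arg(section_coding)
  d <- density[density$gene == gene & !is.na(density$density), , drop = FALSE]
  if (!nrow(d)) stop("no density rows for gene ", gene)
  if (is.null(d$group)) stop("density table has no group column")
  if (length(unique(d$group)) != 2L) stop("exactly two groups are required")
  if (length(unique(d$lower)) < 2L)
    stop("rank-deficient design: only one section present")
  d$section <- if (section_coding == "ordinal") (d$lower + d$upper) / 2
  else factor(sprintf("(%g,%g]", d$lower, d$upper))
  d$group <- factor(d$group)
  fit <- stats::glm(density ~ section * group, data = d, family = family)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint.default(fit, level = 0.95))
  structure(list(
    fit = fit,
    summary = data.frame(term = rownames(cf), estimate = cf[, 1],
                         ci_lo = ci[, 1], ci_hi = ci[, 2],
                         p = cf[, 4], row.names = NULL)),
    class = "section_glm")
}

#' @export
print.section_glm <- function(x, ...) {
  s <- x$summary
  cat("<section_glm> density ~ section * group\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-28s %8.4f [%.4f, %.4f]  p = %.3g\n",
                s$term[i], s$estimate[i], s$ci_lo[i], s$ci_hi[i], s$p[i]))
  invisible(x)
}

#' Correlation screen against a reference gene's section profile
#'
#' Computes the Pearson correlation between every gene's section-density
#' profile and the reference gene's, per group when a `group` column is
#' present, and reports the genes passing `r >= threshold`. Zero-variance
#' profiles yield a missing correlation and are excluded.
#'
#' @param density data.frame from [expression_density()]; profiles are
#'   aligned on (unit, section) pairs.
#' @param reference reference gene name.
#' @param threshold passing threshold on r (default 0.75).
#' @param include_reference keep the reference in the passing set
#'   (default FALSE).
#' @return object of class `correlation_screen`: list with `correlations`
#'   (data.frame `gene`, `group`, `r`, `pass`, sorted by decreasing r)
#'   and `passing` (character vector of genes passing in any group).
#' @export
correlate_with_reference <- function(density, reference, threshold = 0.75,
                                     include_reference = FALSE) {
  if (!reference %in% density$gene) stop("reference gene absent: ", reference)
  grp <- if (is.null(density$group)) rep("all", nrow(density)) else density$group
  out <- list(); n <- 0L
  for (g in unique(grp)) {
    d <- density[grp == g, , drop = FALSE]
    key <- paste(d$domain, d$lower)
    wide <- tapply(d$density, list(key, d$gene), identity)
    ref <- wide[, reference]
    if (stats::sd(ref, na.rm = TRUE) == 0 || all(is.na(ref)))
      stop("reference profile has zero variance in group ", g)
    for (gene in colnames(wide)) {
      v <- wide[, gene]
      ok <- stats::complete.cases(v, ref)
      r <- if (sum(ok) >= 2L && stats::sd(v[ok]) > 0)
        stats::cor(v[ok], ref[ok]) else NA_real_
      n <- n + 1L
      out[[n]] <- data.frame(gene = gene, group = g, r = r)
    }
  }
  cor_tab <- do.call(rbind, out)
  cor_tab <- cor_tab[!is.na(cor_tab$r), , drop = FALSE]
  cor_tab$pass <- cor_tab$r >= threshold
  if (!include_reference)
    cor_tab$pass[cor_tab$gene == reference] <- FALSE
  cor_tab <- cor_tab[order(-cor_tab$r), , drop = FALSE]
  rownames(cor_tab) <- NULL
  structure(list(correlations = cor_tab,
                 passing = unique(cor_tab$gene[cor_tab$pass]),
                 reference = reference, threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> reference %s, threshold %g: %d passing gene(s)\n",
              x$reference, x$threshold, length(x$passing)))
  if (length(x$passing)) cat("  ", paste(x$passing, collapse = ", "), "\n")
  invisible(x)
}

#' Kruskal-Wallis omnibus test across clusters within one section
#'
#' @param values numeric outcome (e.g. section mean expression per
#'   domain).
#' @param clusters cluster label per value (>= 2 clusters, each with
#'   >= 2 observations).
#' @param n_tests optional number of tests for a Bonferroni-corrected p.
#' @return list with `statistic` (H), `p`, `p_bonferroni` (when
#'   `n_tests` given), `df`.
#' @export
compare_sections <- function(values, clusters, n_tests = NULL) {
  clusters <- factor(clusters)
  if (nlevels(clusters) < 2L)
    stop("need at least two clusters to compare")
  if (any(table(clusters) < 2L))
    stop("every cluster needs at least two observations")
  kt <- stats::kruskal.test(values, clusters)
  out <- list(statistic = unname(kt$statistic), p = kt$p.value,
              df = unname(kt$parameter))
  if (!is.null(n_tests)) out$p_bonferroni <- min(1, kt$p.value * n_tests)
  out
}
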