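# Rank-level aggregation and taxa screens: per-taxon ANOVA with pairwise
# Bonferroni t-tests and compact letter display, Pearson taxon-taxon
# correlation, fold-change flagging, and the Glomeromycetes order mapping.

GLOMEROMYCETES_ORDERS <- c("glomerales", "diversisporales",
                           "archaeosporales", "paraglomerales",
                           # variant spelling seen in the literature
                           "paraglomorerales")

#' Aggregate OTU relative abundances to a taxonomic rank
#'
#' Sums OTU percents by the value of the chosen rank; OTUs with an empty
#' rank are pooled into `"unassigned"`. Column sums are conserved.
#'
#' @param rel Relative abundance matrix (OTU x sample, percent).
#' @param taxonomy A `taxonomy_table` covering the matrix OTUs.
#' @param rank One of domain, phylum, class, order, family, genus.
#' @return A `taxa_matrix`: taxon x sample matrix with attribute `rank`.
#' @export
aggregate_taxa <- function(rel, taxonomy, rank = "phylum") {
  if (!rank %in% TAXONOMY_RANKS)
    .stopf("unknown rank '%s'; must be one of: %s", rank,
           paste(TAXONOMY_RANKS, collapse = ", "))
  idx <- match(rownames(rel), taxonomy$otu_id)
  if (anyNA(idx))
    .stopf("OTU(s) without a taxonomy entry: %s",
           paste(rownames(rel)[is.na(idx)], collapse = ", "))
  labels <- taxonomy[[rank]][idx]
  labels[labels == ""] <- "unassigned"
  out <- rowsum(as.matrix(rel), group = labels)
  structure(out, rank = rank, class = c("taxa_matrix", class(out)))
}

#' OTUs belonging to the Glomeromycetes class
#'
#' OTUs whose order matches (case-insensitively) one of Glomerales,
#' Diversisporales, Archaeosporales or Paraglomerales are treated as
#' Glomeromycetes.
#'
#' @param taxonomy A `taxonomy_table`.
#' @return Character vector of OTU ids.
#' @export
glomeromycetes_mask <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  taxonomy$otu_id[tolower(taxonomy$order) %in% GLOMEROMYCETES_ORDERS]
}

#' Per-taxon group tests with compact letter display
#'
#' For every taxon (row): one-way ANOVA F and p across the factor levels,
#' all pairwise two-sided Welch t-tests with Bonferroni correction, and a
#' compact letter display at `alpha` (levels sharing a letter are not
#' significantly different).
#'
#' @param taxa A `taxa_matrix` (taxon x sample).
#' @param meta A `sample_frame` covering the samples.
#' @param factor Metadata column defining the groups.
#' @param alpha Significance level for the letter display.
#' @return List with `tests` (data.frame: taxon, F, p) , `pairwise`
#'   (data.frame per taxon and pair: p_raw, p_bonferroni), `letters`
#'   (data.frame: taxon, level, mean, se, letters).
#' @export
group_tests <- function(taxa, meta, factor = "d_genome", alpha = 0.05) {
  stopifnot(inherits(meta, "sample_frame"))
  if (!factor %in% names(meta)) .stopf("unknown factor '%s'", factor)
  idx <- match(colnames(taxa), meta$sample_id)
  if (anyNA(idx)) .stopf("sample(s) absent from metadata")
  g <- as.character(meta[[factor]][idx])
  sizes <- table(g)
  if (length(sizes) < 2L) .stopf("need >= 2 factor levels")
  if (any(sizes < 2L))
    .stopf("factor level(s) with n < 2: %s",
           paste(names(sizes)[sizes < 2L], collapse = ", "))
  levels <- sort(unique(g))
  pairs <- utils::combn(levels, 2L)
  n_pairs <- ncol(pairs)
  tests <- list(); pairwise <- list(); letters <- list()
  for (tx in rownames(taxa)) {
    x <- as.numeric(taxa[tx, ])
    if (stats::var(x) == 0) {
      f_stat <- 0; p_anova <- 1
    } else {
      an <- summary(stats::aov(x ~ base::factor(g)))[[1L]]
      f_stat <- an$`F value`[1L]; p_anova <- an$`Pr(>F)`[1L]
    }
    tests[[tx]] <- data.frame(taxon = tx, F = f_stat, p = p_anova,
                              stringsAsFactors = FALSE)
    p_adj <- matrix(1, length(levels), length(levels),
                    dimnames = list(levels, levels))
    for (k in seq_len(n_pairs)) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      p_raw <- .welch_p(x[g == a], x[g == b])
      p_bon <- min(1, p_raw * n_pairs)
      p_adj[a, b] <- p_adj[b, a] <- p_bon
      pairwise[[length(pairwise) + 1L]] <- data.frame(
        taxon = tx, group_a = a, group_b = b, p_raw = p_raw,
        p_bonferroni = p_bon, stringsAsFactors = FALSE)
    }
    means <- vapply(levels, function(l) mean(x[g == l]), numeric(1L))
    ses <- vapply(levels, function(l)
      stats::sd(x[g == l]) / sqrt(sum(g == l)), numeric(1L))
    letters[[tx]] <- data.frame(
      taxon = tx, level = levels, n = as.integer(sizes[levels]),
      mean = means, se = ses,
      letters = compact_letters(p_adj, means, alpha = alpha)[levels],
      stringsAsFactors = FALSE)
  }
  list(tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pairwise, list(make.row.names = FALSE))),
       letters = do.call(rbind, c(letters, list(make.row.names = FALSE))))
}

#' Compact letter display from a pairwise significance matrix
#'
#' Greedy insert-absorb algorithm over the non-significance graph,
#' deterministic: levels are processed in order of decreasing mean; each
#' level joins every existing letter group it is non-significantly
#' different from all members of, or founds a new group. Two levels share a
#' letter iff their adjusted p >= alpha.
#'
#' @param p_adj Symmetric matrix of adjusted pairwise p-values with level
#'   dimnames.
#' @param means Named vector of group means (ordering only).
#' @param alpha Significance level.
#' @return Named character vector: level -> letters.
#' @export
compact_letters <- function(p_adj, means, alpha = 0.05) {
  levels <- rownames(p_adj)
  ord <- levels[order(-means[levels])]
  groups <- list(ord[1L])  # conflict-free letter groups (insert-and-absorb)
  for (lv in ord[-1L]) {
    staged <- list()
    joined <- FALSE
    for (gi in seq_along(groups)) {
      compat <- groups[[gi]][p_adj[lv, groups[[gi]]] >= alpha]
      if (length(compat) == length(groups[[gi]])) {
        groups[[gi]] <- c(groups[[gi]], lv)
        joined <- TRUE
      } else if (length(compat)) {
        staged[[length(staged) + 1L]] <- c(compat, lv)
      }
    }
    if (!joined && !length(staged)) staged <- list(lv)
    groups <- c(groups, staged)
    # absorb groups that are subsets of another group
    keep <- rep(TRUE, length(groups))
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i != j && keep[i] && keep[j] && all(groups[[i]] %in% groups[[j]]) &&
            (length(groups[[i]]) < length(groups[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    groups <- groups[keep]
  }
  out <- setNames(rep("", length(levels)), levels)
  for (gi in seq_along(groups)) {
    for (lv in groups[[gi]]) out[lv] <- paste0(out[lv], letters[gi])
  }
  out
}

#' Pearson correlation between two taxa
#'
#' Product-moment correlation of two taxa's relative abundances, computed
#' either across samples or across genotype means (the default unit for
#' comparing plant lines).
#'
#' @param taxa A `taxa_matrix`.
#' @param taxon_a,taxon_b Row names of `taxa`.
#' @param meta A `sample_frame` (required for `unit = "genotype-mean"`).
#' @param unit `"genotype-mean"` or `"sample"`.
#' @return List with `r`, `n` (units used) and `unit`; `r` is `NA` with a
#'   warning if either taxon has zero variance.
#' @export
taxon_correlation <- function(taxa, taxon_a, taxon_b, meta = NULL,
                              unit = c("genotype-mean", "sample")) {
  unit <- match.arg(unit)
  for (tx in c(taxon_a, taxon_b))
    if (!tx %in% rownames(taxa)) .stopf("taxon '%s' not in matrix", tx)
  a <- as.numeric(taxa[taxon_a, ]); b <- as.numeric(taxa[taxon_b, ])
  if (unit == "genotype-mean") {
    if (is.null(meta)) .stopf("metadata required for genotype means")
    idx <- match(colnames(taxa), meta$sample_id)
    if (anyNA(idx)) .stopf("sample(s) absent from metadata")
    gt <- as.character(meta$genotype[idx])
    a <- tapply(a, gt, mean); b <- tapply(b, gt, mean)
    b <- b[names(a)]
  }
  if (length(a) < 3L) .stopf("need >= 3 units for a correlation")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = length(a), unit = unit))
  }
  list(r = stats::cor(a, b), n = length(a), unit = unit)
}

#' Fold-change screen across factor levels
#'
#' For each taxon and level, the fold is the level's mean abundance divided
#' by the unweighted mean of the other levels' means; taxa with fold >=
#' `threshold` are flagged. A zero denominator with a positive numerator is
#' flagged with an infinite fold.
#'
#' @param taxa A `taxa_matrix`.
#' @param meta A `sample_frame`.
#' @param factor Metadata column defining the levels (default species).
#' @param threshold Fold threshold (default 2: "doubled abundance").
#' @return Data frame: taxon, level, mean, others_mean, fold, flagged.
#' @export
fold_change_screen <- function(taxa, meta, factor = "species", threshold = 2) {
  stopifnot(inherits(meta, "sample_frame"))
  idx <- match(colnames(taxa), meta$sample_id)
  if (anyNA(idx)) .stopf("sample(s) absent from metadata")
  g <- as.character(meta[[factor]][idx])
  levels <- sort(unique(g))
  if (length(levels) < 2L) .stopf("need >= 2 factor levels")
  rows <- list()
  for (tx in rownames(taxa)) {
    x <- as.numeric(taxa[tx, ])
    lv_means <- vapply(levels, function(l) mean(x[g == l]), numeric(1L))
    for (l in levels) {
      others <- mean(lv_means[setdiff(levels, l)])
      fold <- if (others == 0) {
        if (lv_means[l] > 0) Inf else 1
      } else lv_means[l] / others
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, level = l, mean = lv_means[l], others_mean = others,
        fold = fold, flagged = fold >= threshold, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
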