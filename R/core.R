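# Core microbiota membership and Venn partition. An OTU is stably
# associated with a plant species when it is present in every line of that
# species, in at least a minimum fraction (default 25%) of each line's
# biological replicates.

#' Per-species core OTU sets
#'
#' An OTU belongs to the core of species `s` iff, for every line (genotype)
#' of `s`, the OTU is present (value > 0) in at least
#' `ceiling(min_rep_frac * n_replicates(line))` of that line's samples.
#' Presence is evaluated on the matrix as given (normally post depth
#' standardization).
#'
#' @param mat Numeric OTU x sample matrix (counts or relative abundance), or
#'   a `count_matrix`.
#' @param meta A `sample_frame` covering the matrix's samples.
#' @param min_rep_frac Minimum fraction of replicates per line, in (0, 1\].
#' @param species Optional character vector restricting the species
#'   considered (default: all planted species in `meta`).
#' @return Named list: species -> character vector of core OTU ids.
#' @export
species_core <- function(mat, meta, min_rep_frac = 0.25, species = NULL) {
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  stopifnot(inherits(meta, "sample_frame"))
  if (!(min_rep_frac > 0 && min_rep_frac <= 1))
    .stopf("min_rep_frac must lie in (0, 1]")
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    .stopf("matrix sample(s) absent from metadata")
  if (is.null(species))
    species <- setdiff(unique(meta$species), "unplanted")
  present <- mat > 0
  out <- lapply(species, function(s) {
    lines <- unique(meta$genotype[meta$species == s])
    if (!length(lines)) .stopf("species '%s' has no lines in the metadata", s)
    in_core <- rep(TRUE, nrow(mat))
    for (ln in lines) {
      cols <- which(meta$genotype == ln)
      need <- ceiling(min_rep_frac * length(cols))
      hits <- rowSums(present[, cols, drop = FALSE])
      in_core <- in_core & (hits >= need)
    }
    rownames(mat)[in_core]
  })
  names(out) <- species
  out
}

#' Venn partition of per-species core sets
#'
#' @param cores Named list of per-species core OTU sets (>= 2 species).
#' @return A `core_sets` list with `cores`, `shared_core` (intersection over
#'   all species), `specific` (per species: core OTUs in no other species'
#'   core) and `regions` (data.frame over all 2^k - 1 Venn regions:
#'   membership pattern, n_otus, otu ids).
#' @export
venn_partition <- function(cores) {
  if (length(cores) < 2L) .stopf("need cores for >= 2 species")
  sp <- names(cores)
  shared <- Reduce(intersect, cores)
  specific <- lapply(sp, function(s)
    setdiff(cores[[s]], unique(unlist(cores[setdiff(sp, s)]))))
  names(specific) <- sp
  all_otus <- unique(unlist(cores))
  membership <- vapply(sp, function(s) all_otus %in% cores[[s]],
                       logical(length(all_otus)))
  if (length(all_otus) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, sp))
  pattern <- apply(membership, 1L, function(b) paste(sp[b], collapse = "&"))
  regions <- data.frame(region = pattern, otu_id = all_otus,
                        stringsAsFactors = FALSE)
  region_tab <- as.data.frame(table(region = regions$region),
                              stringsAsFactors = FALSE)
  names(region_tab)[2L] <- "n_otus"
  structure(list(cores = cores, shared_core = shared, specific = specific,
                 regions = regions, region_sizes = region_tab),
            class = "core_sets")
}

#' @export
print.core_sets <- function(x, ...) {
  cat(sprintf("core_sets over %d species: shared core %d OTUs\n",
              length(x$cores), length(x$shared_core)))
  for (s in names(x$cores))
    cat(sprintf("  %-15s core %4d, specific %4d\n", s,
                length(x$cores[[s]]), length(x$specific[[s]])))
  invisible(x)
}

#' Mean relative-abundance share of an OTU set
#'
#' For each sample in scope, sums the relative abundances (percent) of the
#' set members, then averages over samples.
#'
#' @param rel Relative abundance matrix (OTU x sample, percent).
#' @param otu_set Character vector of OTU ids (subset of the matrix rows).
#' @param samples Character vector of sample ids in scope.
#' @return List with `mean` (percent), `se`, `per_sample` (named vector).
#' @export
abundance_share <- function(rel, otu_set, samples = colnames(rel)) {
  bad <- setdiff(otu_set, rownames(rel))
  if (length(bad)) .stopf("OTU(s) not in matrix: %s", paste(bad, collapse = ", "))
  if (!length(samples)) .stopf("empty sample scope")
  missing <- setdiff(samples, colnames(rel))
  if (length(missing)) .stopf("sample(s) not in matrix: %s", paste(missing, collapse = ", "))
  sub <- rel[otu_set, samples, drop = FALSE]
  per_sample <- if (length(otu_set)) colSums(sub) else setNames(numeric(length(samples)), samples)
  list(mean = mean(per_sample),
       se = if (length(samples) > 1L) stats::sd(per_sample) / sqrt(length(samples)) else NA_real_,
       per_sample = per_sample)
}

#' Core / shared / specific summary table
#'
#' Convenience wrapper: per-species cores, Venn partition and the
#' abundance share of each set within the relevant samples. Presence is
#' evaluated on the matrix as given (counts or percents); shares are
#' always computed on per-sample percents (columns rescaled to 100).
#'
#' @param rel OTU x sample matrix: depth-standardized counts or relative
#'   abundance percents.
#' @param meta A `sample_frame`.
#' @param min_rep_frac Passed to [species_core()].
#' @param fraction Fraction scope (e.g. `"rhizosphere"`); only samples of
#'   this fraction are used.
#' @return List with `venn` (a `core_sets`) and `summary` (data.frame:
#'   set, species, n_otus, share_pct, share_se).
#' @export
core_summary <- function(rel, meta, min_rep_frac = 0.25, fraction = "rhizosphere") {
  keep <- meta$sample_id[meta$fraction == fraction]
  keep <- intersect(colnames(rel), keep)
  if (!length(keep)) .stopf("no samples of fraction '%s' in the matrix", fraction)
  sub <- rel[, keep, drop = FALSE]
  sub_meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
  cores <- species_core(sub, sub_meta, min_rep_frac = min_rep_frac)
  vp <- venn_partition(cores)
  tot <- colSums(sub)
  share_mat <- sweep(sub, 2L, ifelse(tot > 0, tot, 1), "/") * 100
  rows <- list()
  add <- function(set_name, sp, otus, samples) {
    sh <- abundance_share(share_mat, otus, samples)
    rows[[length(rows) + 1L]] <<- data.frame(
      set = set_name, species = sp, n_otus = length(otus),
      share_pct = sh$mean, share_se = sh$se, stringsAsFactors = FALSE)
  }
  all_planted <- sub_meta$sample_id[sub_meta$species != "unplanted"]
  add("shared_core", "all", vp$shared_core, all_planted)
  for (s in names(cores)) {
    s_samples <- sub_meta$sample_id[sub_meta$species == s]
    add("species_core", s, cores[[s]], s_samples)
    add("species_specific", s, vp$specific[[s]], s_samples)
  }
  list(venn = vp, summary = do.call(rbind, rows))
}
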