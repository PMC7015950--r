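# Preprocessing, in fixed order: host/organelle OTU removal (before any
# standardization), per-library depth standardization by subsampling without
# replacement, standardization of each sample to a total of 100%, and
# square-root transformation.

#' Remove host-plant and organelle OTUs
#'
#' Drops every OTU flagged `is_host_plant` or `is_organelle` in the taxonomy
#' and reports, per sample, the fraction of reads removed in each category
#' (computed on pre-removal totals). Must run before depth standardization.
#' The per-sample plant fractions from the eukaryote 18S library feed the
#' qPCR host correction.
#'
#' @param counts A `count_matrix`.
#' @param taxonomy A `taxonomy_table` covering every OTU in `counts`.
#' @return List with `counts` (filtered `count_matrix`; samples emptied by
#'   the removal are kept and flagged) and `report` (data.frame: `sample_id`,
#'   `plant_frac`, `organelle_frac`, `emptied`).
#' @export
remove_host_taxa <- function(counts, taxonomy) {
  stopifnot(inherits(counts, "count_matrix"), inherits(taxonomy, "taxonomy_table"))
  missing <- setdiff(otu_ids(counts), taxonomy$otu_id)
  if (length(missing))
    .stopf("OTU(s) without a taxonomy entry: %s", paste(missing, collapse = ", "))
  tax <- taxonomy[match(otu_ids(counts), taxonomy$otu_id), ]
  plant <- tax$is_host_plant
  organ <- tax$is_organelle & !plant
  tot <- colSums(counts$counts)
  frac_of <- function(mask) {
    removed <- if (any(mask)) colSums(counts$counts[mask, , drop = FALSE]) else 0 * tot
    ifelse(tot > 0, removed / tot, 0)
  }
  report <- data.frame(sample_id = sample_ids(counts),
                       plant_frac = unname(frac_of(plant)),
                       organelle_frac = unname(frac_of(organ)),
                       stringsAsFactors = FALSE)
  keep <- !(plant | organ)
  kept <- counts$counts[keep, , drop = FALSE]
  report$emptied <- colSums(kept) == 0 & tot > 0
  if (any(report$emptied))
    wr_log("host/organelle removal emptied sample(s): ",
           paste(report$sample_id[report$emptied], collapse = ", "), level = "WARN")
  list(counts = count_matrix(kept, counts$library, allow_empty_samples = TRUE),
       report = report)
}

#' Standardize sequencing depth by subsampling
#'
#' Every sample whose total exceeds `threshold` is subsampled without
#' replacement to exactly `threshold` reads (rarefaction). Samples at or
#' below the threshold are kept unchanged (`policy = "keep"`, default) or
#' removed (`policy = "drop"`). Subsampling uses one RNG substream per
#' sample, derived from `(seed, sample_id)`, so column order cannot change
#' the result.
#'
#' @param counts A `count_matrix`.
#' @param threshold Positive integer target depth. Defaults to the library's
#'   standard threshold (see [default_depth_thresholds()]).
#' @param seed Integer seed.
#' @param policy `"keep"` or `"drop"` for samples below the threshold.
#' @return A `count_matrix` with standardized depths.
#' @export
standardize_depth <- function(counts,
                              threshold = default_depth_thresholds()[[counts$library]],
                              seed = 1L, policy = c("keep", "drop")) {
  stopifnot(inherits(counts, "count_matrix"))
  policy <- match.arg(policy)
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold <= 0L) .stopf("threshold must be a positive integer")
  m <- counts$counts
  tot <- colSums(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    if (tot[j] > threshold) {
      out[, j] <- with_substream(seed, paste0("rarefy:", colnames(m)[j]),
                                 .subsample_column(m[, j], threshold))
    }
  }
  if (policy == "drop") {
    low <- tot < threshold
    if (any(low)) {
      wr_log("dropping sample(s) below depth threshold ", threshold, ": ",
             paste(colnames(m)[low], collapse = ", "))
      out <- out[, !low, drop = FALSE]
    }
  }
  wr_log("depth standardization [", counts$library, "]: threshold=", threshold,
         ", seed=", seed, ", policy=", policy)
  count_matrix(out, counts$library, allow_empty_samples = TRUE)
}

# Draw `size` reads without replacement from a count vector.
.subsample_column <- function(x, size) {
  idx <- sample.int(sum(x), size)
  cum <- cumsum(x)
  tab <- tabulate(findInterval(idx, cum + 0.5) + 1L, nbins = length(x))
  as.integer(tab)
}

#' Convert counts to relative abundance (percent)
#'
#' Standardizes each sample so the total contribution of all OTUs is 100%.
#' All-zero samples are left at 0 and flagged via the `empty_samples`
#' attribute; they must be excluded from downstream distances.
#'
#' @param counts A `count_matrix` (or non-negative matrix).
#' @return A `rel_abundance` object: matrix of percents with attributes
#'   `library` and `empty_samples`.
#' @export
to_relative <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (any(m < 0)) .stopf("negative values in count matrix")
  tot <- colSums(m)
  rel <- sweep(m, 2L, ifelse(tot > 0, tot, 1), "/") * 100
  structure(rel,
            library = if (inherits(counts, "count_matrix")) counts$library else NA_character_,
            empty_samples = colnames(m)[tot == 0],
            class = c("rel_abundance", class(rel)))
}

#' Square-root transform a relative abundance matrix
#'
#' Element-wise square root of the percent values, damping the influence of
#' dominant OTUs before distance computation. Order-preserving.
#'
#' @param rel A `rel_abundance` matrix (or any non-negative matrix).
#' @return Matrix of the same shape, attributes preserved.
#' @export
sqrt_transform <- function(rel) {
  if (any(rel < 0)) .stopf("negative values passed to sqrt_transform")
  out <- sqrt(rel)
  attributes(out) <- attributes(rel)
  out
}

#' Run the full preprocessing chain for one library
#'
#' Fixed order: host/organelle removal -> depth standardization -> relative
#' abundance -> square root. Returns every intermediate.
#'
#' @param counts A `count_matrix`.
#' @param taxonomy A `taxonomy_table`.
#' @param threshold Depth threshold (default: the library's standard value).
#' @param seed Integer seed for subsampling.
#' @param policy Below-threshold sample policy, see [standardize_depth()].
#' @return List with `host_report`, `filtered`, `standardized`, `rel`,
#'   `transformed`.
#' @export
preprocess_library <- function(counts, taxonomy,
                               threshold = default_depth_thresholds()[[counts$library]],
                               seed = 1L, policy = "keep") {
  rem <- remove_host_taxa(counts, taxonomy)
  std <- standardize_depth(rem$counts, threshold, seed = seed, policy = policy)
  rel <- to_relative(std)
  list(host_report = rem$report, filtered = rem$counts, standardized = std,
       rel = rel, transformed = sqrt_transform(rel))
}
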