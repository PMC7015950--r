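# Domain types: OTU count matrices, taxonomy, sample metadata, qPCR Ct tables.
# All on-disk formats are UTF-8 tab-separated text; lines starting with "#"
# are comments. OTUs are rows, samples are columns (OTU count >> sample count).

FRACTION_LEVELS <- c("bulk", "rhizosphere", "root")
ANCESTRY_LEVELS <- c("modern", "wild", "synthetic", "none")
DGENOME_LEVELS <- c("none", "wild", "artificial", "mixed")
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct an OTU count matrix
#'
#' @param counts Integer matrix, OTUs as rows, samples as columns, with
#'   unique row and column names.
#' @param library One of `"prokaryote16S"`, `"eukaryote18S"`, `"fungalITS1"`,
#'   `"oomyceteITS1"`.
#' @param allow_empty_samples Keep all-zero sample columns? They are rejected
#'   unless explicitly flagged, so a silently empty sample cannot slip through.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, library, allow_empty_samples = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) || is.null(colnames(counts)))
    .stopf("counts must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicated OTU ids: %s",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    .stopf("duplicated sample ids: %s",
           paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    .stopf("counts must be finite non-negative integers")
  if (!library %in% LIBRARIES)
    .stopf("unknown library '%s'; must be one of: %s", library,
           paste(LIBRARIES, collapse = ", "))
  empty <- colSums(counts) == 0
  if (any(empty) && !allow_empty_samples)
    .stopf("all-zero sample column(s): %s (set allow_empty_samples = TRUE to keep)",
           paste(colnames(counts)[empty], collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, library = library,
                 empty_samples = colnames(counts)[empty]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d OTUs x %d samples, %s reads total\n",
              x$library, nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

otu_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

#' Construct/validate a sample metadata frame
#'
#' Validates per-sample design factors: fraction (bulk/rhizosphere/root),
#' genotype line, species, ancestry class, ploidy, D-genome class and
#' replicate number. Bulk soil samples must carry genotype `"unplanted"`, and
#' the factors must nest: each genotype maps to exactly one species and each
#' species to exactly one ancestry class.
#'
#' @param df Data frame with columns `sample_id`, `fraction`, `genotype`,
#'   `species`, `ancestry`, `ploidy`, `d_genome`, `replicate`.
#' @return A validated `sample_frame` (a data.frame).
#' @export
sample_frame <- function(df) {
  req <- c("sample_id", "fraction", "genotype", "species", "ancestry",
           "ploidy", "d_genome", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("sample_id", "fraction", "genotype", "species", "ancestry", "d_genome"))
    df[[col]] <- as.character(df[[col]])
  df$ploidy <- as.integer(df$ploidy)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    .stopf("duplicated sample ids in metadata: %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  .check_levels(df$fraction, FRACTION_LEVELS, "fraction")
  .check_levels(df$ancestry, ANCESTRY_LEVELS, "ancestry")
  .check_levels(df$d_genome, DGENOME_LEVELS, "d_genome")
  bad_ploidy <- !(df$ploidy %in% c(0L, 2L, 4L, 6L))
  if (any(bad_ploidy))
    .stopf("ploidy must be one of 0 (unplanted), 2, 4, 6; offending samples: %s",
           paste(df$sample_id[bad_ploidy], collapse = ", "))
  if (any(df$replicate < 1L))
    .stopf("replicate must be a positive integer")
  bulk <- df$fraction == "bulk"
  if (any(bulk & df$genotype != "unplanted"))
    .stopf("bulk samples must have genotype 'unplanted': %s",
           paste(df$sample_id[bulk & df$genotype != "unplanted"], collapse = ", "))
  # Nesting: genotype determines species, species determines ancestry.
  g2s <- tapply(df$species, df$genotype, function(v) length(unique(v)))
  if (any(g2s > 1))
    .stopf("genotype(s) mapped to more than one species: %s",
           paste(names(g2s)[g2s > 1], collapse = ", "))
  s2a <- tapply(df$ancestry, df$species, function(v) length(unique(v)))
  if (any(s2a > 1))
    .stopf("species mapped to more than one ancestry class: %s",
           paste(names(s2a)[s2a > 1], collapse = ", "))
  class(df) <- c("sample_frame", "data.frame")
  df
}

.check_levels <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad))
    .stopf("unknown %s level(s) %s; allowed: %s", what,
           paste(sQuote(bad), collapse = ", "), paste(allowed, collapse = ", "))
  invisible(TRUE)
}

#' Construct/validate a taxonomy table
#'
#' One row per OTU with a ranked lineage (domain..genus; empty string for an
#' unknown rank, never "NA") and logical host-plant / organelle flags.
#'
#' @param df Data frame with columns `otu_id`, the six rank columns,
#'   `is_host_plant`, `is_organelle`.
#' @return A validated `taxonomy_table` (a data.frame).
#' @export
taxonomy_table <- function(df) {
  req <- c("otu_id", TAXONOMY_RANKS, "is_host_plant", "is_organelle")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("taxonomy is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$otu_id))
    .stopf("duplicated OTU ids in taxonomy: %s",
           paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  for (col in c("otu_id", TAXONOMY_RANKS)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]]) | df[[col]] == "NA"] <- ""
  }
  df$is_host_plant <- as.logical(df$is_host_plant)
  df$is_organelle <- as.logical(df$is_organelle)
  if (any(is.na(df$is_host_plant)) || any(is.na(df$is_organelle)))
    .stopf("is_host_plant / is_organelle must be TRUE or FALSE")
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Construct/validate a qPCR Ct table
#'
#' @param df Data frame with columns `sample_id`, `ct16`, `ct18`,
#'   `plant_frac18` (fraction in \[0, 1\] of 18S amplicons of host-plant
#'   origin).
#' @return A validated `qpcr_table` (a data.frame).
#' @export
qpcr_table <- function(df) {
  req <- c("sample_id", "ct16", "ct18", "plant_frac18")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stopf("qPCR table is missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  for (col in c("ct16", "ct18", "plant_frac18")) df[[col]] <- as.numeric(df[[col]])
  if (anyDuplicated(df$sample_id))
    .stopf("duplicated sample ids in qPCR table")
  if (any(!is.finite(df$ct16)) || any(!is.finite(df$ct18)) ||
      any(df$ct16 <= 0) || any(df$ct18 <= 0))
    .stopf("Ct values must be finite and > 0")
  if (any(!is.finite(df$plant_frac18)) || any(df$plant_frac18 < 0) || any(df$plant_frac18 > 1))
    .stopf("plant_frac18 must lie in [0, 1]; offending samples: %s",
           paste(df$sample_id[!is.finite(df$plant_frac18) |
                                df$plant_frac18 < 0 | df$plant_frac18 > 1],
                 collapse = ", "))
  class(df) <- c("qpcr_table", "data.frame")
  df
}

# ---- readers -----------------------------------------------------------

.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) .stopf("cannot parse '%s' as a tab-separated table: %s",
                               path, conditionMessage(e)))
  if (nrow(df) == 0L && ncol(df) <= 1L)
    .stopf("'%s' is empty or has no data rows", path)
  df
}

#' Read an OTU count table
#'
#' Tab-separated, first column the OTU id, header row of sample ids, integer
#' cells. Comment lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param library Amplicon library label (see [count_matrix()]).
#' @param allow_empty_samples Passed to [count_matrix()].
#' @return A `count_matrix`.
#' @export
read_count_table <- function(path, library, allow_empty_samples = FALSE) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) .stopf("count table '%s' has no sample columns", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  bad <- which(is.na(num) | num != floor(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    .stopf("non-integer count cell(s) in '%s': first offender at OTU '%s', sample '%s' (value '%s')",
           path, ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], m[bad[1L, 1L], bad[1L, 2L]])
  }
  rownames(num) <- ids
  colnames(num) <- colnames(m)
  count_matrix(num, library, allow_empty_samples = allow_empty_samples)
}

#' Read a sample metadata table
#' @param path File path to a tab-separated table with the columns required
#'   by [sample_frame()].
#' @return A `sample_frame`.
#' @export
read_metadata <- function(path) sample_frame(.read_tsv(path))

#' Read a taxonomy table
#' @param path File path to a tab-separated table with the columns required
#'   by [taxonomy_table()].
#' @return A `taxonomy_table`.
#' @export
read_taxonomy <- function(path) taxonomy_table(.read_tsv(path))

#' Read a qPCR Ct table
#' @param path File path to a tab-separated table with the columns required
#'   by [qpcr_table()].
#' @return A `qpcr_table`.
#' @export
read_qpcr <- function(path) qpcr_table(.read_tsv(path))

# ---- writers -----------------------------------------------------------

#' Write a tab-separated results table
#'
#' Deterministic, round-trippable TSV output: integers are written exactly,
#' doubles at 17 significant digits so that re-reading reproduces them to
#' better than 1e-12 relative error.
#'
#' @param df Data frame to write.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(df)
  num <- vapply(df, function(col) is.double(col), logical(1L))
  df[num] <- lapply(df[num], function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- "NA"
    out
  })
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) .stopf("cannot write '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' Write an OTU count table
#' @param x A `count_matrix`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write sample metadata / taxonomy / qPCR tables
#' @param x The table object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(x, path) write_tsv(x, path)

#' @rdname write_metadata
#' @export
write_taxonomy_table <- function(x, path) write_tsv(x, path)

#' @rdname write_metadata
#' @export
write_qpcr_table <- function(x, path) write_tsv(x, path)

#' Check that a count matrix and metadata describe the same samples
#'
#' Samples present in the metadata but absent from the counts are tolerated
#' with a warning (failed sequencing is encoded as an absent column, never as
#' zeros); samples present in the counts but missing from the metadata are an
#' error.
#'
#' @param counts A `count_matrix`.
#' @param meta A `sample_frame`.
#' @return Invisibly, the metadata restricted to samples present in counts,
#'   in count-column order.
#' @export
align_samples <- function(counts, meta) {
  cs <- sample_ids(counts)
  missing_meta <- setdiff(cs, meta$sample_id)
  if (length(missing_meta))
    .stopf("sample(s) in counts but absent from metadata: %s",
           paste(missing_meta, collapse = ", "))
  extra <- setdiff(meta$sample_id, cs)
  if (length(extra))
    warning(sprintf("metadata sample(s) absent from counts (ignored): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  out <- meta[match(cs, meta$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  invisible(out)
}
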