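#' @keywords internal
"_PACKAGE"

# Known amplicon libraries and their default depth-standardization thresholds.
LIBRARIES <- c("prokaryote16S", "eukaryote18S", "fungalITS1", "oomyceteITS1")

#' Default per-library sequencing depth thresholds
#'
#' Upper thresholds used to standardize the number of sequences per sample:
#' 10,000 for the prokaryote 16S library, 5,000 for the eukaryote 18S library,
#' 3,000 for the fungal ITS1 library and 2,000 for the oomycete ITS1 library.
#'
#' @return Named integer vector of thresholds, one per library.
#' @export
default_depth_thresholds <- function() {
  c(prokaryote16S = 10000L, eukaryote18S = 5000L,
    fungalITS1 = 3000L, oomyceteITS1 = 2000L)
}

# Deterministic 31-bit hash of a string, for per-unit RNG substreams.
.str_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(as.character(s))) h <- (h * 31 + c) %% 2147483647
  h
}

#' Derive a reproducible RNG substream seed
#'
#' Fans a single global seed out to independent, order-insensitive substreams
#' keyed by a label (a stage name, a sample id). The same (seed, label) pair
#' always yields the same substream seed, so reordering units of work cannot
#' change results.
#'
#' @param seed Integer global seed.
#' @param label Character scalar naming the substream.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + .str_hash(label)) %% 2147483647)
}

# Evaluate an expression under a local RNG state seeded from (seed, label).
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}

# Minimal timestamped logger; level in c("INFO", "WARN").
wr_log <- function(..., level = "INFO", verbose = getOption("wheatrhizo.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
  }
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
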