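# Shared settings for the analysis drivers. Everything downstream of
# 01_simulate.R reads its inputs from results/tables, so any stage can be
# re-run in isolation.

library(wheatrhizo)

SEED <- 20200206L
TABLES_DIR <- "results/tables"
OUT_DIR <- "results"
LIBRARIES <- c("prokaryote16S", "eukaryote18S")

# Default study conditions at a desk-friendly replicate count.
analysis_config <- function() {
  sim_config(reps_per_line = 4L, seed = SEED)
}

read_stage_counts <- function(lb) {
  read_count_table(file.path(TABLES_DIR, paste0("counts_", lb, ".tsv")), lb,
                   allow_empty_samples = TRUE)
}
read_stage_taxonomy <- function(lb) {
  read_taxonomy(file.path(TABLES_DIR, paste0("taxonomy_", lb, ".tsv")))
}
read_stage_meta <- function() read_metadata(file.path(TABLES_DIR, "metadata.tsv"))

preprocess_stage <- function(lb) {
  preprocess_library(read_stage_counts(lb), read_stage_taxonomy(lb),
                     seed = substream_seed(SEED, paste0("prep:", lb)))
}
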