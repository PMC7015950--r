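#!/usr/bin/env Rscript
# Stage 4: core microbiota membership. An OTU belongs to a species' core if
# present in every line of that species in >= 25% of each line's replicates;
# the Venn partition gives the shared core and the species-specific sets,
# each with its mean relative-abundance share.

source("analysis/00_config.R")

meta <- read_stage_meta()
for (lb in LIBRARIES) {
  std <- read_stage_counts_std <- read_count_table(
    file.path(TABLES_DIR, paste0("standardized_", lb, ".tsv")), lb,
    allow_empty_samples = TRUE)
  core <- core_summary(std$counts, meta, min_rep_frac = 0.25,
                       fraction = "rhizosphere")
  write_tsv(core$summary, file.path(OUT_DIR, paste0("core_summary_", lb, ".tsv")))
  write_tsv(core$venn$region_sizes,
            file.path(OUT_DIR, paste0("venn_regions_", lb, ".tsv")))
  shared <- core$summary[core$summary$set == "shared_core", ]
  spec <- core$summary[core$summary$set == "species_specific", ]
  cat(sprintf("[%s] shared core: %d OTUs, %.1f%% of community abundance;\n",
              lb, shared$n_otus, shared$share_pct))
  cat(sprintf("[%s] species-specific sets: %d-%d OTUs, mean share %.2f%%\n",
              lb, min(spec$n_otus), max(spec$n_otus), mean(spec$share_pct)))
}
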