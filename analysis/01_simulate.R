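#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — 22 wheat lines in six species
# groups plus bulk soil controls, rhizosphere and root fractions, prokaryote
# 16S and eukaryote 18S amplicon libraries, and matching qPCR Ct values —
# and write every input table under results/tables.

source("analysis/00_config.R")

cfg <- analysis_config()
ds <- simulate_dataset(cfg, libraries = LIBRARIES)

dir.create(TABLES_DIR, recursive = TRUE, showWarnings = FALSE)
write_metadata(ds$design, file.path(TABLES_DIR, "metadata.tsv"))
write_qpcr_table(ds$qpcr, file.path(TABLES_DIR, "qpcr.tsv"))
for (lb in LIBRARIES) {
  write_count_table(ds$libraries[[lb]]$counts,
                    file.path(TABLES_DIR, paste0("counts_", lb, ".tsv")))
  write_taxonomy_table(ds$libraries[[lb]]$taxonomy,
                       file.path(TABLES_DIR, paste0("taxonomy_", lb, ".tsv")))
  tr <- ds$libraries[[lb]]$truth
  write_tsv(data.frame(sample_id = names(tr$euk_frac),
                       euk_frac = unname(tr$euk_frac),
                       plant_frac = unname(tr$plant_frac[names(tr$euk_frac)])),
            file.path(TABLES_DIR, paste0("truth_", lb, ".tsv")))
}

cat(sprintf("Simulated %d samples x %d libraries (seed %d).\n",
            nrow(ds$design), length(LIBRARIES), SEED))
cat(sprintf("Design: %d genotypes, fractions: %s; bulk controls: %d.\n",
            length(setdiff(unique(ds$design$genotype), "unplanted")),
            paste(setdiff(unique(ds$design$fraction), "bulk"), collapse = "/"),
            sum(ds$design$fraction == "bulk")))
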