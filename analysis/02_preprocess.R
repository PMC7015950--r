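#!/usr/bin/env Rscript
# Stage 2: host/organelle OTU removal, depth standardization (10,000 reads
# for the 16S library, 5,000 for the 18S library), per-sample percent
# standardization and square-root transform. Writes the host-removal report
# and the standardized count tables.

source("analysis/00_config.R")

for (lb in LIBRARIES) {
  pp <- preprocess_stage(lb)
  write_tsv(pp$host_report,
            file.path(OUT_DIR, paste0("host_report_", lb, ".tsv")))
  write_count_table(pp$standardized,
                    file.path(TABLES_DIR, paste0("standardized_", lb, ".tsv")))
  planted <- pp$host_report$plant_frac[pp$host_report$plant_frac > 0]
  cat(sprintf("[%s] removed host/organelle OTUs; plant-read fraction in planted samples: %s\n",
              lb,
              if (length(planted)) sprintf("%.2f-%.2f (median %.2f)",
                                           min(planted), max(planted),
                                           median(planted)) else "none"))
  cat(sprintf("[%s] depths standardized to <= %d reads/sample (%d samples)\n",
              lb, default_depth_thresholds()[[lb]], ncol(pp$standardized$counts)))
}
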