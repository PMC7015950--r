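#!/usr/bin/env Rscript
# Stage 5: Bray-Curtis distances on the sqrt-transformed standardized
# tables, PCoA with group centroids +/- SE, multifactorial PERMANOVA
# (Type I sequential, residual permutation under the reduced model), the
# nested Type I and Type III variants, and CAP by ancestry class.

source("analysis/00_config.R")

meta <- read_stage_meta()
for (lb in LIBRARIES) {
  pp <- preprocess_stage(lb)
  tr <- pp$transformed
  keep <- setdiff(colnames(tr), attr(tr, "empty_samples"))
  d <- bray_curtis(tr[, keep])
  m <- meta[match(keep, meta$sample_id), ]

  ord <- pcoa(d)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates[, 1:3])
  write_tsv(coords, file.path(OUT_DIR, paste0("pcoa_", lb, ".tsv")))
  write_tsv(group_centroids(ord, setNames(m$fraction, m$sample_id)),
            file.path(OUT_DIR, paste0("pcoa_centroids_fraction_", lb, ".tsv")))
  cat(sprintf("[%s] PCoA axes 1-2 explain %.1f%% + %.1f%%\n", lb,
              100 * ord$prop_explained[1], 100 * ord$prop_explained[2]))

  planted <- intersect(keep, meta$sample_id[meta$fraction != "bulk"])
  dp <- dist_matrix(d$d[planted, planted])
  mp <- meta[match(planted, meta$sample_id), ]

  flat <- permanova(dp, mp, c("fraction", "ploidy", "ancestry", "species",
                              "genotype"),
                    n_perm = 999L, seed = substream_seed(SEED, paste0("pm:", lb)))
  write_tsv(flat$table, file.path(OUT_DIR, paste0("permanova_flat_", lb, ".tsv")))
  top <- flat$table[which.max(flat$table$pseudoF), ]
  cat(sprintf("[%s] strongest factor: %s (pseudo-F = %.1f, p = %.4g)\n",
              lb, top$term, top$pseudoF, top$p))

  nested <- permanova(dp, mp, c("fraction", "ancestry", "species(ancestry)",
                                "genotype(species)"),
                      n_perm = 999L,
                      seed = substream_seed(SEED, paste0("pmnest:", lb)))
  write_tsv(nested$table, file.path(OUT_DIR, paste0("permanova_nested_", lb, ".tsv")))
  # Type III marginal tests are identifiable only for terms not contained
  # in another term's span (genotype spans species/ancestry/ploidy here)
  nested3 <- permanova(dp, mp, c("fraction", "genotype(species)"),
                       n_perm = 999L, ss_type = "III",
                       seed = substream_seed(SEED, paste0("pmnest3:", lb)))
  write_tsv(nested3$table,
            file.path(OUT_DIR, paste0("permanova_nested_typeIII_", lb, ".tsv")))

  cp <- cap(dp, setNames(mp$ancestry, mp$sample_id), n_perm = 499L,
            seed = substream_seed(SEED, paste0("cap:", lb)))
  write_tsv(data.frame(m = cp$m, allocation_success = cp$allocation_success,
                       trace = cp$trace, p = cp$p),
            file.path(OUT_DIR, paste0("cap_ancestry_", lb, ".tsv")))
  cat(sprintf("[%s] CAP by ancestry: m = %d, allocation %.0f%%, p = %.4g\n",
              lb, cp$m, 100 * cp$allocation_success, cp$p))
}
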