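#!/usr/bin/env Rscript
# Stage 6: taxon-level screens. Phylum aggregation, per-taxon ANOVA with
# pairwise-Bonferroni compact letters (fraction shifts in the 16S library,
# D-genome shifts in the 18S library), the doubled-abundance fold screen
# across species, and the Nematoda-Glomeromycetes correlation across
# genotype means.

source("analysis/00_config.R")

meta <- read_stage_meta()

for (lb in LIBRARIES) {
  pp <- preprocess_stage(lb)
  tax <- read_stage_taxonomy(lb)
  tm <- aggregate_taxa(pp$rel, tax, "phylum")
  write_tsv(data.frame(taxon = rownames(tm), tm, check.names = FALSE),
            file.path(OUT_DIR, paste0("taxa_phylum_", lb, ".tsv")))

  scope <- if (lb == "eukaryote18S") {
    meta$sample_id[meta$fraction == "rhizosphere"]
  } else meta$sample_id
  scope <- setdiff(intersect(colnames(tm), scope), attr(pp$rel, "empty_samples"))
  fac <- if (lb == "eukaryote18S") "d_genome" else "fraction"
  gt <- group_tests(tm[, scope, drop = FALSE], meta, factor = fac)
  write_tsv(gt$tests, file.path(OUT_DIR, paste0("taxa_tests_", lb, ".tsv")))
  write_tsv(gt$letters, file.path(OUT_DIR, paste0("taxa_letters_", lb, ".tsv")))
  sig <- gt$tests$taxon[gt$tests$p < 0.05]
  cat(sprintf("[%s] phyla shifting with %s (ANOVA p < 0.05): %s\n", lb, fac,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))

  fold <- fold_change_screen(tm[, scope, drop = FALSE],
                             meta, factor = "species", threshold = 2)
  write_tsv(fold, file.path(OUT_DIR, paste0("fold_screen_", lb, ".tsv")))
  flagged <- fold[fold$flagged & fold$taxon != "unassigned", ]
  cat(sprintf("[%s] doubled-abundance flags: %s\n", lb,
              if (nrow(flagged)) paste(sprintf("%s in %s (%.1fx)", flagged$taxon,
                                               flagged$level, flagged$fold),
                                       collapse = "; ") else "none"))
}

# D-genome screen: Nematoda (phylum) and Glomeromycetes (class via order
# list) in the rhizosphere 18S community, correlated across genotype means.
pp18 <- preprocess_stage("eukaryote18S")
tax18 <- read_stage_taxonomy("eukaryote18S")
rhizo <- setdiff(intersect(colnames(pp18$rel),
                           meta$sample_id[meta$fraction == "rhizosphere"]),
                 attr(pp18$rel, "empty_samples"))
rel <- pp18$rel[, rhizo]
taxa2 <- rbind(
  Nematoda = colSums(rel[intersect(tax18$otu_id[tax18$phylum == "Nematoda"],
                                   rownames(rel)), , drop = FALSE]),
  Glomeromycetes = colSums(rel[intersect(glomeromycetes_mask(tax18),
                                         rownames(rel)), , drop = FALSE]))
m2 <- meta[match(rhizo, meta$sample_id), ]
gt2 <- group_tests(taxa2, m2, factor = "d_genome")
write_tsv(gt2$letters, file.path(OUT_DIR, "dgenome_letters.tsv"))
means <- gt2$letters[gt2$letters$taxon == "Nematoda", c("level", "mean", "letters")]
cat("Nematoda relative abundance by D-genome class:\n")
print(means, row.names = FALSE)
r <- taxon_correlation(taxa2, "Nematoda", "Glomeromycetes", m2,
                       unit = "genotype-mean")
write_tsv(data.frame(taxon_a = "Nematoda", taxon_b = "Glomeromycetes",
                     unit = r$unit, n = r$n, r = r$r),
          file.path(OUT_DIR, "nematoda_glomeromycetes_r.tsv"))
cat(sprintf("Nematoda-Glomeromycetes Pearson r across %d genotype means: %.2f\n",
            r$n, r$r))
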