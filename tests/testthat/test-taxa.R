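demo_taxonomy <- function() {
  taxonomy_table(data.frame(
    otu_id = paste0("otu", 1:6),
    domain = "Eukaryota",
    phylum = c("Nematoda", "Nematoda", "Mucoromycota", "Ascomycota",
               "Ascomycota", ""),
    class = c("", "", "Glomeromycetes", "", "", ""),
    order = c("", "", "Glomerales", "Hypocreales", "", ""),
    family = "", genus = "",
    is_host_plant = FALSE, is_organelle = FALSE))
}

test_that("rank aggregation pools by rank value and conserves totals", {
  tax <- demo_taxonomy()
  rel <- matrix(c(30, 20, 10, 15, 20, 5,
                  10, 10, 40, 20, 10, 10), ncol = 2,
                dimnames = list(tax$otu_id, c("S1", "S2")))
  tm <- aggregate_taxa(rel, tax, "phylum")
  expect_equal(tm["Nematoda", "S1"], 50)
  expect_equal(tm["unassigned", "S1"], 5)
  expect_equal(unname(colSums(tm)), c(100, 100), tolerance = 1e-9)
  expect_error(aggregate_taxa(rel, tax, "kingdom"), "unknown rank")
  # conservation holds on random matrices
  set.seed(14)
  r2 <- matrix(runif(6 * 5), 6, 5, dimnames = list(tax$otu_id, paste0("x", 1:5)))
  r2 <- sweep(r2, 2, colSums(r2), "/") * 100
  expect_equal(unname(colSums(aggregate_taxa(r2, tax, "order"))),
               rep(100, 5), tolerance = 1e-9)
})

test_that("Glomeromycetes mask matches the four orders case-insensitively", {
  tax <- demo_taxonomy()
  expect_equal(glomeromycetes_mask(tax), "otu3")
  tax2 <- tax
  tax2$order <- c("GLOMERALES", "diversisporales", "Archaeosporales",
                  "Paraglomerales", "Hypocreales", "")
  expect_setequal(glomeromycetes_mask(tax2), paste0("otu", 1:4))
})

test_that("group tests: identical groups, single-shift letters, conventions", {
  meta <- manual_meta(species = rep(c("A.tauschii", "T.durum"), each = 3),
                      genotype = rep(c("L1", "L2"), each = 3),
                      replicate = rep(1:3, 2))
  taxa <- matrix(c(rep(5, 6), 1, 2, 3, 1, 2, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("flat", "same"), meta$sample_id))
  out <- group_tests(taxa, meta, factor = "species")
  expect_equal(out$tests$F, c(0, 0))
  # all levels share one letter when nothing differs
  expect_true(all(out$letters$letters == "a"))

  # noise-free three-group case: only the shifted group gets its own letter
  meta3 <- manual_meta(species = rep(c("A.tauschii", "T.durum", "SHW"), each = 3),
                       genotype = rep(c("L1", "L2", "L3"), each = 3),
                       replicate = rep(1:3, 3))
  x <- c(1.0, 1.1, 0.9,  1.0, 1.1, 0.9,  9.0, 9.1, 8.9)
  taxa3 <- matrix(x, nrow = 1, dimnames = list("t", meta3$sample_id))
  out3 <- group_tests(taxa3, meta3, factor = "species")
  lt <- setNames(out3$letters$letters, out3$letters$level)
  expect_equal(lt[["SHW"]], "a")        # highest mean seeded first
  expect_equal(lt[["A.tauschii"]], lt[["T.durum"]])
  expect_false(lt[["SHW"]] == lt[["A.tauschii"]])

  expect_error(group_tests(taxa3[, 1:4, drop = FALSE], meta3, "species"),
               "n < 2")
})

test_that("letter display shares a letter exactly when Bonferroni p >= alpha", {
  set.seed(99)
  for (k in 1:30) {
    n_lev <- sample(3:5, 1)
    levels <- paste0("g", seq_len(n_lev))
    means <- rnorm(n_lev, sd = 2)
    names(means) <- levels
    p_adj <- matrix(1, n_lev, n_lev, dimnames = list(levels, levels))
    for (i in seq_len(n_lev - 1)) {
      for (j in (i + 1):n_lev) {
        p_adj[i, j] <- p_adj[j, i] <- sample(c(runif(1, 0, 0.04),
                                               runif(1, 0.06, 1)), 1)
      }
    }
    lt <- compact_letters(p_adj, means, alpha = 0.05)
    for (i in seq_len(n_lev - 1)) {
      for (j in (i + 1):n_lev) {
        share <- any(strsplit(lt[levels[i]], "")[[1]] %in%
                       strsplit(lt[levels[j]], "")[[1]])
        expect_equal(share, p_adj[i, j] >= 0.05,
                     info = sprintf("case %d pair %s-%s", k, levels[i], levels[j]))
      }
    }
  }
})

test_that("taxon correlation: exact lines and unit choice", {
  meta <- manual_meta(species = rep("A.tauschii", 6),
                      genotype = rep(c("L1", "L2", "L3"), each = 2),
                      replicate = rep(1:2, 3))
  a <- c(1, 2, 3, 4, 5, 6)
  taxa <- rbind(a = a, b = 2 * a + 1, c = -a)
  colnames(taxa) <- meta$sample_id
  expect_equal(taxon_correlation(taxa, "a", "b", unit = "sample")$r, 1)
  expect_equal(taxon_correlation(taxa, "a", "c", unit = "sample")$r, -1)
  gm <- taxon_correlation(taxa, "a", "b", meta, unit = "genotype-mean")
  expect_equal(gm$n, 3)
  expect_equal(gm$r, 1)
  flat <- rbind(taxa, d = rep(1, 6))
  expect_warning(r0 <- taxon_correlation(flat, "a", "d", unit = "sample"),
                 "zero variance")
  expect_true(is.na(r0$r))
})

test_that("fold screen: forced arithmetic, scale invariance, zero denominator", {
  meta <- manual_meta(species = rep(c("A.tauschii", "T.durum", "SHW"), each = 2),
                      genotype = rep(c("L1", "L2", "L3"), each = 2),
                      replicate = rep(1:2, 3))
  taxa <- matrix(c(8, 8, 1, 1, 1, 1), nrow = 1,
                 dimnames = list("cyano", meta$sample_id))
  out <- fold_change_screen(taxa, meta, factor = "species")
  row_a <- out[out$level == "A.tauschii", ]
  expect_equal(row_a$fold, 8)
  expect_true(row_a$flagged)
  expect_false(any(out$flagged[out$level != "A.tauschii"]))

  # equal levels: fold 1, nothing flagged
  flat <- matrix(rep(4, 6), nrow = 1, dimnames = list("t", meta$sample_id))
  expect_false(any(fold_change_screen(flat, meta)$flagged))
  expect_equal(unique(fold_change_screen(flat, meta)$fold), 1)

  # scale invariance
  out10 <- fold_change_screen(taxa * 10, meta, factor = "species")
  expect_equal(out10$fold, out$fold)

  # zero denominator with positive numerator: infinite fold sentinel, flagged
  zt <- matrix(c(3, 3, 0, 0, 0, 0), nrow = 1,
               dimnames = list("z", meta$sample_id))
  oz <- fold_change_screen(zt, meta, factor = "species")
  expect_equal(oz$fold[oz$level == "A.tauschii"], Inf)
  expect_true(oz$flagged[oz$level == "A.tauschii"])
})
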