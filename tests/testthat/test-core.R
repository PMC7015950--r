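test_that("prevalence rule: present in all lines, >= 25% of replicates each", {
  # species with 2 lines x 4 reps
  meta <- manual_meta(species = rep("A.tauschii", 8),
                      genotype = rep(c("L1", "L2"), each = 4),
                      replicate = rep(1:4, 2))
  mat <- matrix(0, 3, 8, dimnames = list(paste0("otu", 1:3), meta$sample_id))
  mat["otu1", 1:4] <- 5; mat["otu1", 5] <- 1   # 4/4 and 1/4 -> core
  mat["otu2", 1:4] <- 5                        # 4/4 and 0/4 -> not core
  mat["otu3", c(1, 5)] <- 2                    # 1/4 and 1/4 -> core
  core <- species_core(mat, meta, 0.25)
  expect_setequal(core$A.tauschii, c("otu1", "otu3"))

  # 7 reps: ceiling(0.25 * 7) = 2, so 1/7 is not enough
  meta7 <- manual_meta(species = rep("A.tauschii", 7), genotype = rep("L1", 7),
                       replicate = 1:7)
  m7 <- matrix(0, 2, 7, dimnames = list(c("a", "b"), meta7$sample_id))
  m7["a", 1] <- 1        # 1/7 < 2
  m7["b", 1:2] <- 1      # 2/7 >= 2
  expect_equal(species_core(m7, meta7, 0.25)$A.tauschii, "b")

  expect_error(species_core(m7, meta7, 0), "\\(0, 1\\]")
  expect_error(species_core(m7, meta7, 1.2), "\\(0, 1\\]")
})

test_that("species_core equals the brute-force rule on random matrices", {
  set.seed(77)
  for (rep_i in 1:60) {
    n_species <- sample(2:3, 1)
    lines_per <- sample(1:3, n_species, replace = TRUE)
    reps_per_line <- sample(3:8, sum(lines_per), replace = TRUE)
    species <- rep(paste0("sp", seq_len(n_species)), times = lines_per)
    genotype <- paste0("g", seq_along(species))
    meta_rows <- do.call(rbind, lapply(seq_along(genotype), function(i) {
      data.frame(genotype = genotype[i], species = species[i],
                 replicate = seq_len(reps_per_line[i]))
    }))
    meta <- sample_frame(data.frame(
      sample_id = sprintf("s%03d", seq_len(nrow(meta_rows))),
      fraction = "rhizosphere", genotype = meta_rows$genotype,
      species = meta_rows$species, ancestry = "wild", ploidy = 2L,
      d_genome = "none", replicate = meta_rows$replicate))
    n_otu <- sample(5:50, 1)
    mat <- matrix(rbinom(n_otu * nrow(meta), 1, runif(1, 0.1, 0.7)) *
                    rpois(n_otu * nrow(meta), 3),
                  n_otu, nrow(meta),
                  dimnames = list(paste0("otu", seq_len(n_otu)), meta$sample_id))
    frac <- sample(c(0.25, 0.4, 0.5, 0.75, 1), 1)
    expect_identical(species_core(mat, meta, frac),
                     brute_force_core(mat, meta, frac))
  }
})

test_that("raising the prevalence threshold never grows a core", {
  set.seed(13)
  meta <- manual_meta(species = rep(c("A.tauschii", "T.durum"), each = 8),
                      genotype = rep(c("L1", "L2", "L3", "L4"), each = 4),
                      replicate = rep(1:4, 4))
  mat <- matrix(rbinom(30 * 16, 1, 0.4), 30, 16,
                dimnames = list(paste0("otu", 1:30), meta$sample_id))
  fracs <- c(0.1, 0.25, 0.5, 0.75, 1)
  cores <- lapply(fracs, function(f) species_core(mat, meta, f))
  for (i in seq_along(fracs)[-1]) {
    for (s in names(cores[[i]])) {
      expect_true(all(cores[[i]][[s]] %in% cores[[i - 1]][[s]]))
    }
  }
})

test_that("Venn partition: shared, specific and exhaustive region coverage", {
  vp <- venn_partition(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(vp$shared_core, "2")
  expect_equal(vp$specific$A, "1")
  expect_equal(vp$specific$B, "3")

  same <- venn_partition(list(A = c("1", "2"), B = c("1", "2")))
  expect_length(same$specific$A, 0)
  expect_length(same$specific$B, 0)

  # brute-force oracle: every OTU falls in exactly one region
  set.seed(5)
  for (k in 1:25) {
    n_sp <- sample(2:4, 1)
    universe <- paste0("o", 1:15)
    cores <- lapply(seq_len(n_sp), function(i)
      sample(universe, sample(0:12, 1)))
    names(cores) <- paste0("sp", seq_len(n_sp))
    vp <- venn_partition(cores)
    all_otus <- unique(unlist(cores))
    expect_setequal(vp$regions$otu_id, all_otus)
    expect_equal(anyDuplicated(vp$regions$otu_id), 0L)
    for (otu in all_otus) {
      members <- names(cores)[vapply(cores, function(s) otu %in% s, logical(1))]
      expect_equal(vp$regions$region[vp$regions$otu_id == otu],
                   paste(members, collapse = "&"))
    }
    # shared core contained in every species core
    for (s in names(cores)) expect_true(all(vp$shared_core %in% cores[[s]]))
  }
})

test_that("abundance shares average per-sample sums, with partition additivity", {
  rel <- matrix(c(60, 30, 10,   80, 10, 10), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("S1", "S2")))
  expect_equal(abundance_share(rel, c("a", "b", "c"))$mean, 100)
  expect_equal(abundance_share(rel, character(0))$mean, 0)
  sh <- abundance_share(rel, "a")
  expect_equal(sh$mean, 70)
  expect_equal(sh$se, stats::sd(c(60, 80)) / sqrt(2))
  expect_error(abundance_share(rel, "zz"), "not in matrix")
  expect_error(abundance_share(rel, "a", character(0)), "empty")

  # partition additivity: Venn-region shares sum to the species-core share
  meta <- manual_meta(species = rep(c("A.tauschii", "T.durum"), each = 4),
                      genotype = rep(c("L1", "L2"), each = 4),
                      replicate = rep(1:4, 2))
  set.seed(8)
  counts <- matrix(rbinom(20 * 8, 1, 0.5) * rpois(20 * 8, 4), 20, 8,
                   dimnames = list(paste0("otu", 1:20), meta$sample_id))
  rel2 <- to_relative(counts)
  cores <- species_core(counts, meta)
  vp <- venn_partition(cores)
  sA <- meta$sample_id[meta$species == "A.tauschii"]
  region_ids <- split(vp$regions$otu_id, vp$regions$region)
  in_A <- vapply(strsplit(names(region_ids), "&", fixed = TRUE),
                 function(r) "A.tauschii" %in% r, logical(1))
  total_regions <- sum(vapply(region_ids[in_A], function(ids)
    abundance_share(rel2, ids, sA)$mean, numeric(1)))
  expect_equal(total_regions,
               abundance_share(rel2, cores$A.tauschii, sA)$mean,
               tolerance = 1e-9)
})
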