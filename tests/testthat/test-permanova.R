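euclid_d <- function(y) dist_matrix(as.matrix(stats::dist(y)))

test_that("univariate pseudo-F equals classical one-way ANOVA F", {
  # hand-checked instance: {0,1} vs {4,5}: SSB = 16, SSW = 1, F = 32
  y <- c(0, 1, 4, 5)
  names(y) <- paste0("S", 1:4)
  meta <- data.frame(sample_id = names(y), g = c("a", "a", "b", "b"))
  res <- permanova(euclid_d(y), meta, "g", n_perm = 0)
  expect_equal(res$table$pseudoF[1], 32, tolerance = 1e-10)
  expect_equal(res$table$SS, c(16, 1, 17), tolerance = 1e-10)
  expect_equal(res$table$df, c(1, 2, 3))
})

test_that("pseudo-F equals ANOVA F over random univariate instances", {
  set.seed(41)
  for (k in 1:100) {
    n <- sample(6:30, 1)
    n_lev <- sample(2:4, 1)
    g <- sample(rep(letters[1:n_lev], length.out = n))
    y <- rnorm(n, mean = as.integer(factor(g)) * runif(1, 0, 2))
    names(y) <- paste0("S", 1:n)
    meta <- data.frame(sample_id = names(y), g = g)
    res <- permanova(euclid_d(y), meta, "g", n_perm = 0)
    expect_equal(res$table$pseudoF[1], anova_f(y, g), tolerance = 1e-10)
  }
})

test_that("Monte-Carlo p matches the exhaustive permutation p for small n", {
  set.seed(17)
  for (n in 5:7) {
    g <- rep(c("a", "b"), length.out = n)
    y <- rnorm(n) + (g == "b") * 1.5
    names(y) <- paste0("S", 1:n)
    meta <- data.frame(sample_id = names(y), g = g)
    f_obs <- anova_f(y, g)
    perms <- all_perms(n)
    f_all <- vapply(perms, function(p) anova_f(y[p], g), numeric(1))
    p_ex <- mean(f_all >= f_obs - 1e-12)
    res <- permanova(euclid_d(y), meta, "g", n_perm = 9999, seed = 3)
    se <- sqrt(p_ex * (1 - p_ex) / 9999)
    expect_lt(abs(res$table$p[1] - p_ex), 3 * se + 2 / 10000)
  }
})

test_that("Type-I SS are additive and invariant to sample order", {
  cfg <- tiny_config(reps = 4L, seed = 19L)
  des <- simulate_design(cfg)
  sim <- simulate_counts(des, cfg, "prokaryote16S")
  pp <- preprocess_library(sim$counts, sim$taxonomy, seed = 2L)
  keep <- setdiff(colnames(pp$transformed), attr(pp$transformed, "empty_samples"))
  d <- bray_curtis(pp$transformed[, keep])
  meta <- des[match(keep, des$sample_id), ]
  terms <- c("fraction", "species", "genotype(species)")
  res <- permanova(d, meta, terms, n_perm = 99, seed = 5)
  tab <- res$table
  expect_equal(sum(tab$SS[tab$term != "Total"]), tab$SS[tab$term == "Total"],
               tolerance = 1e-8)
  expect_equal(sum(tab$df[tab$term != "Total"]), tab$df[tab$term == "Total"])

  # permuting the sample order leaves SS, F and p unchanged (same seed)
  perm <- sample(length(keep))
  d2 <- dist_matrix(d$d[perm, perm])
  res2 <- permanova(d2, meta, terms, n_perm = 99, seed = 5)
  expect_equal(res2$table$SS, tab$SS, tolerance = 1e-10)
  expect_equal(res2$table$pseudoF, tab$pseudoF, tolerance = 1e-10)
  expect_equal(res2$table$p, tab$p)
})

test_that("multivariate sequential SS and F agree with the adonis2 oracle", {
  skip_if_not_installed("vegan")
  cfg <- tiny_config(reps = 4L, seed = 23L)
  des <- simulate_design(cfg)
  sim <- simulate_counts(des, cfg, "prokaryote16S")
  pp <- preprocess_library(sim$counts, sim$taxonomy, seed = 2L)
  keep <- setdiff(colnames(pp$transformed), attr(pp$transformed, "empty_samples"))
  x <- t(pp$transformed[, keep])
  meta <- des[match(keep, des$sample_id), ]
  d <- bray_curtis(pp$transformed[, keep])
  res <- permanova(d, meta, c("fraction", "species"), n_perm = 0)
  ref <- vegan::adonis2(x ~ fraction + species,
                        data = as.data.frame(meta), method = "bray",
                        permutations = 2, by = "terms")
  expect_equal(res$table$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$table$pseudoF[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(res$table$df[1:2], ref$Df[1:2])
})

test_that("Type III marginal SS match the full-vs-drop-one decomposition", {
  set.seed(55)
  n <- 24
  g1 <- sample(rep(c("a", "b"), 12))
  g2 <- sample(rep(c("x", "y", "z"), 8))
  y <- rnorm(n) + (g1 == "b") + 2 * (g2 == "z")
  names(y) <- paste0("S", 1:n)
  meta <- data.frame(sample_id = names(y), g1 = g1, g2 = g2)
  res3 <- permanova(euclid_d(y), meta, c("g1", "g2"), n_perm = 0, ss_type = "III")
  # oracle: marginal SS from linear-model residual sums of squares
  rss <- function(form) sum(stats::resid(stats::lm(form))^2)
  ss_g1 <- rss(y ~ factor(g2)) - rss(y ~ factor(g1) + factor(g2))
  ss_g2 <- rss(y ~ factor(g1)) - rss(y ~ factor(g1) + factor(g2))
  expect_equal(res3$table$SS[1:2], c(ss_g1, ss_g2), tolerance = 1e-10)
})

test_that("null labels give approximately uniform permutation p-values", {
  set.seed(71)
  n_rep <- 200L
  pvals <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    n <- 16
    y <- rnorm(n)
    names(y) <- paste0("S", 1:n)
    meta <- data.frame(sample_id = names(y), g = sample(rep(c("a", "b"), 8)))
    pvals[k] <- permanova(euclid_d(y), meta, "g", n_perm = 199,
                          seed = k)$table$p[1]
  }
  # rejection rate at alpha = 0.10 within exact binomial 99% bounds
  rej <- sum(pvals <= 0.10)
  ci <- qbinom(c(0.005, 0.995), n_rep, 0.10)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("nested terms restrict permutations to the parent stratum", {
  cfg <- tiny_config(reps = 4L, seed = 29L)
  des <- simulate_design(cfg)
  sim <- simulate_counts(des, cfg, "eukaryote18S")
  pp <- preprocess_library(sim$counts, sim$taxonomy, seed = 1L)
  keep <- setdiff(colnames(pp$transformed), attr(pp$transformed, "empty_samples"))
  d <- bray_curtis(pp$transformed[, keep])
  meta <- des[match(keep, des$sample_id), ]
  res <- permanova(d, meta, c("species", "genotype(species)"),
                   n_perm = 199, seed = 11)
  expect_equal(res$table$term[2], "genotype(species)")
  # df of the nested term: n_genotypes - n_species (4 lines, 2 species)
  expect_equal(res$table$df[2], 2)
  expect_true(res$table$p[2] > 0 && res$table$p[2] <= 1)
})

test_that("aliased and saturated designs are rejected with clear errors", {
  y <- rnorm(6); names(y) <- paste0("S", 1:6)
  g <- rep(c("a", "b"), 3)
  meta <- data.frame(sample_id = names(y), g = g, h = g)  # h aliases g
  expect_error(permanova(euclid_d(y), meta, c("g", "h"), n_perm = 0), "aliased")
  meta2 <- data.frame(sample_id = names(y), g = paste0("lvl", 1:6))
  expect_error(permanova(euclid_d(y), meta2, "g", n_perm = 0), "saturated")
})
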