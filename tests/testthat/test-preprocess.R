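make_counts <- function(m, library = "eukaryote18S") {
  rownames(m) <- paste0("otu", seq_len(nrow(m)))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  count_matrix(m, library, allow_empty_samples = TRUE)
}

flat_taxonomy <- function(otus, host = character(0), organelle = character(0)) {
  taxonomy_table(data.frame(
    otu_id = otus, domain = "Eukaryota", phylum = "Ascomycota", class = "",
    order = "", family = "", genus = "",
    is_host_plant = otus %in% host, is_organelle = otus %in% organelle))
}

test_that("host removal reports removed fractions on pre-removal totals", {
  m <- matrix(c(50, 30, 20,   10, 80, 10), nrow = 3)
  cm <- make_counts(m)
  tax <- flat_taxonomy(rownames(cm$counts), host = "otu1", organelle = "otu3")
  out <- remove_host_taxa(cm, tax)
  expect_equal(out$report$plant_frac, c(0.5, 0.1))
  expect_equal(out$report$organelle_frac, c(0.2, 0.1))
  expect_equal(rownames(out$counts$counts), "otu2")
  expect_equal(unname(out$counts$counts["otu2", ]), c(30L, 80L))

  # no flagged OTUs: identity
  tax0 <- flat_taxonomy(rownames(cm$counts))
  expect_identical(remove_host_taxa(cm, tax0)$counts$counts, cm$counts)

  # all flagged: samples flagged empty, not silently zeroed
  tax_all <- flat_taxonomy(rownames(cm$counts), host = rownames(cm$counts))
  all_out <- remove_host_taxa(cm, tax_all)
  expect_true(all(all_out$report$emptied))
  expect_equal(all_out$counts$empty_samples, c("S1", "S2"))

  # missing taxonomy entry errors with the offender named
  expect_error(remove_host_taxa(cm, tax[-2, ]), "otu2")
})

test_that("depth standardization subsamples to the threshold exactly", {
  set.seed(1)
  m <- matrix(rpois(40, 50), nrow = 4)
  m[1, 1] <- 12000L
  cm <- make_counts(m)
  out <- standardize_depth(cm, threshold = 10000L, seed = 7L)
  expect_equal(unname(colSums(out$counts)[1]), 10000)
  # below-threshold samples untouched under the default policy
  expect_identical(out$counts[, -1], cm$counts[, -1])
  # boundary: total exactly at threshold is unchanged
  at <- make_counts(matrix(c(600L, 400L), nrow = 2))
  expect_identical(standardize_depth(at, 1000L, seed = 1)$counts, at$counts)
  # drop policy removes and only removes sub-threshold samples
  dropped <- standardize_depth(cm, threshold = 10000L, seed = 7L, policy = "drop")
  expect_equal(colnames(dropped$counts), "S1")
  expect_error(standardize_depth(cm, threshold = 0L), "positive")
})

test_that("subsampling is deterministic per (seed, sample) and order-invariant", {
  set.seed(2)
  m <- matrix(rpois(60, 400), nrow = 6)
  cm <- make_counts(m)
  a <- standardize_depth(cm, 1000L, seed = 3L)$counts
  b <- standardize_depth(cm, 1000L, seed = 3L)$counts
  expect_identical(a, b)
  # permuting columns leaves each sample's subsample unchanged
  perm <- c(3, 1, 2, 5, 4, 6, 8, 7, 9, 10)
  cmp <- make_counts(m)
  cmp$counts <- cmp$counts[, perm]
  shuffled <- standardize_depth(cmp, 1000L, seed = 3L)$counts
  expect_identical(shuffled[, colnames(a)], a)
  # different seed, different subsample
  expect_false(identical(standardize_depth(cm, 1000L, seed = 4L)$counts, a))
})

test_that("subsampling preserves expected composition", {
  x <- c(500L, 300L, 150L, 50L)
  m <- matrix(x, ncol = 1)
  props <- x / sum(x)
  n_rep <- 400L
  size <- 200L
  acc <- matrix(0, length(x), n_rep)
  for (k in seq_len(n_rep)) {
    cm <- make_counts(m)
    colnames(cm$counts) <- paste0("rep", k)  # fresh substream per replicate
    acc[, k] <- standardize_depth(cm, size, seed = 100L)$counts[, 1] / size
  }
  mc_se <- sqrt(props * (1 - props) / size) / sqrt(n_rep)
  expect_true(all(abs(rowMeans(acc) - props) <= 3 * mc_se + 1e-12))
})

test_that("relative abundance and sqrt transform behave as specified", {
  m <- make_counts(matrix(c(1, 1, 2,  0, 0, 7,  0, 0, 0), nrow = 3))
  rel <- to_relative(m)
  expect_equal(unname(rel[, 1]), c(25, 25, 50))
  expect_equal(unname(rel[, 2]), c(0, 0, 100))
  expect_equal(unname(rel[, 3]), c(0, 0, 0))
  expect_equal(attr(rel, "empty_samples"), "S3")
  expect_equal(colSums(rel[, 1:2]), c(S1 = 100, S2 = 100), tolerance = 1e-9)

  tr <- sqrt_transform(rel)
  expect_equal(unname(tr[3, 2]), 10)   # 100 -> 10
  expect_equal(unname(tr[1, 2]), 0)    # 0 -> 0
  # monotonicity on random matrices
  set.seed(4)
  a <- matrix(runif(50, 0, 100), 10)
  b <- a + matrix(runif(50, 0, 10), 10)
  expect_true(all(sqrt_transform(a) <= sqrt_transform(b)))
  expect_error(sqrt_transform(a - 50), "negative")
})

test_that("full preprocessing chain runs in the documented order", {
  cfg <- tiny_config(reps = 3L)
  des <- simulate_design(cfg)
  sim <- simulate_counts(des, cfg, "eukaryote18S")
  pp <- preprocess_library(sim$counts, sim$taxonomy, threshold = 800L, seed = 5L)
  # host OTUs are gone before standardization
  expect_false(any(sim$taxonomy$otu_id[sim$taxonomy$is_host_plant] %in%
                     rownames(pp$standardized$counts)))
  expect_true(all(colSums(pp$standardized$counts) <= 800L))
  nonempty <- setdiff(colnames(pp$rel), attr(pp$rel, "empty_samples"))
  expect_equal(unname(colSums(pp$rel[, nonempty])), rep(100, length(nonempty)),
               tolerance = 1e-9)
})
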