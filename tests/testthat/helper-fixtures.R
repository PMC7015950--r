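# Shared in-code fixtures for the test suite.

# Tiny deterministic count matrix with sample metadata: 2 species x 2 lines
# x n reps, rhizosphere only, plus 2 bulk controls.
tiny_design <- function(reps = 4L, fractions = "rhizosphere") {
  cfg <- tiny_config(reps = reps, fractions = fractions)
  simulate_design(cfg)
}

tiny_config <- function(reps = 4L, fractions = "rhizosphere", seed = 11L, ...) {
  st <- data.frame(
    species  = c("A.tauschii", "T.durum"),
    ancestry = c("wild", "modern"),
    ploidy   = c(2L, 4L),
    d_genome = c("wild", "none"),
    n_lines  = c(2L, 2L),
    stringsAsFactors = FALSE)
  sim_config(species_table = st, reps_per_line = reps, fractions = fractions,
             n_otus = 60L, seed = seed,
             depth_thresholds = c(prokaryote16S = 1000L, eukaryote18S = 1000L,
                                  fungalITS1 = 1000L, oomyceteITS1 = 1000L),
             ...)
}

# hand-built metadata frame for rule-level tests
manual_meta <- function(species, genotype, replicate,
                        fraction = "rhizosphere") {
  n <- length(genotype)
  anc <- ifelse(species == "unplanted", "none", "wild")
  sample_frame(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    fraction = rep(fraction, length.out = n),
    genotype = genotype, species = species, ancestry = anc,
    ploidy = ifelse(species == "unplanted", 0L, 2L),
    d_genome = "none", replicate = replicate,
    stringsAsFactors = FALSE))
}

# literal brute-force evaluation of the core-membership rule, used as the
# independent oracle against species_core()
brute_force_core <- function(mat, meta, min_rep_frac = 0.25) {
  species <- setdiff(unique(meta$species), "unplanted")
  out <- list()
  for (s in species) {
    core <- character(0)
    for (otu in rownames(mat)) {
      ok <- TRUE
      for (ln in unique(meta$genotype[meta$species == s])) {
        ids <- meta$sample_id[meta$genotype == ln]
        n_rep <- length(ids)
        n_present <- sum(mat[otu, ids] > 0)
        if (n_present < ceiling(min_rep_frac * n_rep)) ok <- FALSE
      }
      if (ok) core <- c(core, otu)
    }
    out[[s]] <- core
  }
  out
}

# all permutations of 1..n (n <= 7), for exhaustive permutation oracles
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# classical one-way ANOVA F, the univariate PERMANOVA oracle
anova_f <- function(y, g) {
  fit <- stats::lm(y ~ factor(g))
  stats::anova(fit)$`F value`[1L]
}
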