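# Synthetic community generator. Emulates the glasshouse design of the study
# system: 22 wheat lines from six groups (bread wheat, pasta wheat, goat
# grass, wild emmer, synthetic hexaploids and F1 crosses) plus unplanted bulk
# soil, sampled in rhizosphere/root fractions and profiled with four amplicon
# libraries. Counts are Dirichlet-multinomial around a log-normal baseline
# community with multiplicative group effects; ground truth is retained for
# parameter-recovery tests.

#' Species table mirroring the study design
#'
#' Six plant groups with their ancestry class, ploidy, D-genome class and the
#' number of lines per group (4 bread wheat, 3 pasta wheat, 4 goat grass,
#' 3 wild emmer, 4 synthetic hexaploids, 4 F1 crosses = 22 lines).
#'
#' @return A data.frame with columns `species`, `ancestry`, `ploidy`,
#'   `d_genome`, `n_lines`.
#' @export
default_species_table <- function() {
  data.frame(
    species  = c("T.aestivum", "T.durum", "A.tauschii", "T.dicoccoides", "SHW", "F1"),
    ancestry = c("modern", "modern", "wild", "wild", "synthetic", "synthetic"),
    ploidy   = c(6L, 4L, 2L, 4L, 6L, 6L),
    d_genome = c("artificial", "none", "wild", "none", "wild", "mixed"),
    n_lines  = c(4L, 3L, 4L, 3L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Default multiplicative effect map
#'
#' Per-library list of taxon-group effects applied multiplicatively to
#' relative abundances before renormalization. Defaults encode the study
#' system's structure: a strong niche (fraction) effect on dominant
#' bacterial phyla, a bread-wheat-specific Cyanobacteria enrichment, and
#' wild-D-genome enrichment of Nematoda (4x) and Glomeromycetes (3x) in the
#' eukaryote 18S library.
#'
#' @return Nested list: `effects[[library]]` is a list of entries with
#'   fields `group` (a taxonomy group label), `factor` (a `sample_frame`
#'   column) and `fold` (named numeric vector: factor level -> multiplier).
#' @export
default_effects <- function() {
  list(
    prokaryote16S = list(
      list(group = "Proteobacteria", factor = "fraction",
           fold = c(rhizosphere = 2.5, root = 6)),
      list(group = "Actinobacteria", factor = "fraction",
           fold = c(root = 0.4)),
      list(group = "Acidobacteria", factor = "fraction",
           fold = c(root = 0.3)),
      list(group = "Cyanobacteria", factor = "species",
           fold = c(T.aestivum = 8))
    ),
    eukaryote18S = list(
      list(group = "Nematoda", factor = "d_genome",
           fold = c(wild = 4, mixed = 2)),
      list(group = "Glomeromycetes", factor = "d_genome",
           fold = c(wild = 3, mixed = 2))
    ),
    fungalITS1 = list(
      list(group = "Glomeromycetes", factor = "d_genome",
           fold = c(wild = 2))
    ),
    oomyceteITS1 = list()
  )
}

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions: the 22-line/6-group design with
#' 8 biological replicates per line (the study used 6-10) plus 8 bulk soil
#' controls, rhizosphere and root fractions, host-plant 18S contamination
#' drawn uniformly from 14-75% of the eukaryotic community in planted
#' samples, sequencing depths log-normal around twice the per-library
#' standardization threshold, a target eukaryote qPCR contribution of 5.4%
#' in bulk soil and 6.8% in planted fractions, and Dirichlet concentration
#' 200 for biological overdispersion.
#'
#' @param species_table Data frame as [default_species_table()].
#' @param reps_per_line Biological replicates per line (and bulk controls).
#' @param fractions Character subset of `c("rhizosphere", "root")` to
#'   simulate for planted lines; bulk soil controls are always added.
#' @param n_otus OTUs per amplicon library.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline OTU abundance
#'   profile parameters.
#' @param concentration Dirichlet concentration (overdispersion; larger =
#'   closer to multinomial). `Inf` gives plain multinomial sampling.
#' @param effects Effect map, see [default_effects()].
#' @param host_contamination_range Interval in \[0,1\]: per-sample share of
#'   the 18S community of host-plant origin (planted samples only).
#' @param depth_thresholds Named per-library depth thresholds; depths are
#'   drawn log-normal around twice these values.
#' @param depth_sdlog Log-sd of the depth distribution.
#' @param euk_fraction Named vector: target true eukaryote contribution by
#'   fraction (bulk/rhizosphere/root), on (0,1).
#' @param euk_sdlog Per-sample log-scale jitter of the eukaryote fraction.
#' @param ct_noise_sd Gaussian noise sd (cycles) added to simulated Ct.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species_table = default_species_table(),
                       reps_per_line = 8L,
                       fractions = c("rhizosphere", "root"),
                       n_otus = 300L,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.5,
                       concentration = 200,
                       effects = default_effects(),
                       host_contamination_range = c(0.14, 0.75),
                       depth_thresholds = default_depth_thresholds(),
                       depth_sdlog = 0.3,
                       euk_fraction = c(bulk = 0.054, rhizosphere = 0.068, root = 0.068),
                       euk_sdlog = 0.08,
                       ct_noise_sd = 0.15,
                       seed = 1L) {
  reps_per_line <- as.integer(reps_per_line)
  if (is.na(reps_per_line) || reps_per_line < 1L)
    .stopf("reps_per_line must be a positive integer")
  fractions <- match.arg(fractions, c("rhizosphere", "root"), several.ok = TRUE)
  if (any(host_contamination_range < 0) || any(host_contamination_range > 1) ||
      host_contamination_range[1] > host_contamination_range[2])
    .stopf("host_contamination_range must be an interval within [0, 1]")
  for (lib in names(effects)) {
    for (ef in effects[[lib]]) {
      if (any(ef$fold <= 0)) .stopf("all multiplicative effects must be > 0")
    }
  }
  if (any(euk_fraction <= 0) || any(euk_fraction >= 1))
    .stopf("euk_fraction targets must lie in (0, 1)")
  structure(list(
    species_table = species_table, reps_per_line = reps_per_line,
    fractions = fractions, n_otus = as.integer(n_otus),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    concentration = concentration, effects = effects,
    host_contamination_range = host_contamination_range,
    depth_thresholds = depth_thresholds, depth_sdlog = depth_sdlog,
    euk_fraction = euk_fraction, euk_sdlog = euk_sdlog,
    ct_noise_sd = ct_noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate the experimental design
#'
#' One sample per (line, replicate, fraction) for every planted line, plus
#' `reps_per_line` unplanted bulk soil controls. With the default
#' configuration (22 lines, 8 replicates, rhizosphere only) this yields
#' 22*8 + 8 = 184 samples.
#'
#' @param config A `sim_config`.
#' @param fractions Optional override of `config$fractions`.
#' @return A `sample_frame`.
#' @export
simulate_design <- function(config = sim_config(), fractions = config$fractions) {
  st <- config$species_table
  rows <- list()
  for (i in seq_len(nrow(st))) {
    for (l in seq_len(st$n_lines[i])) {
      genotype <- sprintf("%s-L%02d", st$species[i], l)
      for (fr in fractions) {
        for (r in seq_len(config$reps_per_line)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s.%s.r%02d", genotype, fr, r),
            fraction = fr, genotype = genotype, species = st$species[i],
            ancestry = st$ancestry[i], ploidy = st$ploidy[i],
            d_genome = st$d_genome[i], replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (r in seq_len(config$reps_per_line)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("bulk.r%02d", r), fraction = "bulk",
      genotype = "unplanted", species = "unplanted", ancestry = "none",
      ploidy = 0L, d_genome = "none", replicate = r, stringsAsFactors = FALSE)
  }
  sample_frame(do.call(rbind, rows))
}

# Taxonomy group composition per library: label -> (lineage columns, share of
# OTUs). Shares are approximate fractions of the OTU pool.
.library_groups <- function(library) {
  switch(library,
    prokaryote16S = list(
      list(group = "Proteobacteria", share = 0.25,
           lineage = c(domain = "Bacteria", phylum = "Proteobacteria")),
      list(group = "Actinobacteria", share = 0.15,
           lineage = c(domain = "Bacteria", phylum = "Actinobacteria")),
      list(group = "Acidobacteria", share = 0.15,
           lineage = c(domain = "Bacteria", phylum = "Acidobacteria")),
      list(group = "Cyanobacteria", share = 0.04,
           lineage = c(domain = "Bacteria", phylum = "Cyanobacteria", genus = "Nostoc")),
      list(group = "Thaumarchaeota", share = 0.05,
           lineage = c(domain = "Archaea", phylum = "Thaumarchaeota")),
      list(group = "Bacteroidetes", share = 0.1,
           lineage = c(domain = "Bacteria", phylum = "Bacteroidetes")),
      list(group = "OtherBacteria", share = 0.26,
           lineage = c(domain = "Bacteria", phylum = "Firmicutes"))),
    eukaryote18S = list(
      list(group = "Nematoda", share = 0.05,
           lineage = c(domain = "Eukaryota", phylum = "Nematoda")),
      list(group = "Glomeromycetes", share = 0.04,
           lineage = c(domain = "Eukaryota", phylum = "Mucoromycota",
                       class = "Glomeromycetes", order = "Glomerales",
                       genus = "Glomus")),
      list(group = "Ascomycota", share = 0.40,
           lineage = c(domain = "Eukaryota", phylum = "Ascomycota")),
      list(group = "Cercozoa", share = 0.15,
           lineage = c(domain = "Eukaryota", phylum = "Cercozoa")),
      list(group = "OtherEukaryota", share = 0.33,
           lineage = c(domain = "Eukaryota", phylum = "Chlorophyta")),
      list(group = "HostPlant", share = 0.03, host = TRUE,
           lineage = c(domain = "Eukaryota", phylum = "Streptophyta",
                       genus = "Triticum"))),
    fungalITS1 = list(
      list(group = "Ascomycota", share = 0.55,
           lineage = c(domain = "Eukaryota", phylum = "Ascomycota")),
      list(group = "Basidiomycota", share = 0.3,
           lineage = c(domain = "Eukaryota", phylum = "Basidiomycota")),
      list(group = "Glomeromycetes", share = 0.05,
           lineage = c(domain = "Eukaryota", phylum = "Mucoromycota",
                       class = "Glomeromycetes", order = "Glomerales",
                       genus = "Glomus")),
      list(group = "OtherFungi", share = 0.1,
           lineage = c(domain = "Eukaryota", phylum = "Mortierellomycota"))),
    oomyceteITS1 = list(
      list(group = "Pythium", share = 0.6,
           lineage = c(domain = "Eukaryota", phylum = "Oomycota",
                       genus = "Pythium")),
      list(group = "OtherOomycota", share = 0.4,
           lineage = c(domain = "Eukaryota", phylum = "Oomycota"))),
    .stopf("unknown library '%s'", library))
}

# Build a taxonomy_table for one library; returns the table plus a
# group -> otu_id map.
.simulate_taxonomy <- function(library, n_otus, with_organelles = identical(library, "prokaryote16S")) {
  groups <- .library_groups(library)
  shares <- vapply(groups, `[[`, numeric(1), "share")
  n_per <- pmax(1L, round(shares / sum(shares) * n_otus))
  # adjust the largest group so totals match n_otus
  n_per[which.max(n_per)] <- n_per[which.max(n_per)] + (n_otus - sum(n_per))
  otu <- 0L
  rows <- list(); group_map <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    ids <- sprintf("%s_OTU%04d", library, otu + seq_len(n_per[i]))
    otu <- otu + n_per[i]
    lin <- setNames(rep("", length(TAXONOMY_RANKS)), TAXONOMY_RANKS)
    lin[names(g$lineage)] <- g$lineage
    rows[[i]] <- data.frame(otu_id = ids,
                            domain = lin[["domain"]], phylum = lin[["phylum"]],
                            class = lin[["class"]], order = lin[["order"]],
                            family = lin[["family"]], genus = lin[["genus"]],
                            is_host_plant = isTRUE(g$host),
                            is_organelle = FALSE,
                            stringsAsFactors = FALSE)
    group_map[[g$group]] <- c(group_map[[g$group]], ids)
  }
  tax <- do.call(rbind, rows)
  if (with_organelles) {
    # a couple of chloroplast/mitochondrial OTUs slipping past PNA blockers
    org <- data.frame(otu_id = sprintf("%s_ORG%02d", library, 1:2),
                      domain = "Bacteria", phylum = "Cyanobacteria",
                      class = "", order = "Chloroplast", family = "",
                      genus = "", is_host_plant = FALSE, is_organelle = TRUE,
                      stringsAsFactors = FALSE)
    tax <- rbind(tax, org)
    group_map[["Organelle"]] <- org$otu_id
  }
  rownames(tax) <- NULL
  list(taxonomy = taxonomy_table(tax), groups = group_map)
}

#' Simulate OTU counts for one amplicon library
#'
#' Per sample, the expected composition is a log-normal baseline OTU profile
#' multiplied by `exp`-style factor effects for the sample's design levels and
#' renormalized; counts are drawn Dirichlet-multinomial at a log-normal depth.
#' In the eukaryote 18S library, planted samples receive a host-plant OTU
#' share drawn uniformly from the configured contamination range; in the
#' prokaryote 16S library a small organelle share is injected into planted
#' root/rhizosphere samples.
#'
#' @param design A `sample_frame` from [simulate_design()].
#' @param config A `sim_config`.
#' @param library Amplicon library to simulate.
#' @return List with elements `counts` (a `count_matrix`), `taxonomy`
#'   (a `taxonomy_table`) and `truth` (a `ground_truth` list: per-sample true
#'   compositions including host share, the group map, per-sample plant
#'   fraction and true eukaryote fraction).
#' @export
simulate_counts <- function(design, config = sim_config(), library = "prokaryote16S") {
  stopifnot(inherits(design, "sample_frame"))
  if (!library %in% LIBRARIES) .stopf("unknown library '%s'", library)
  n <- nrow(design)
  tx <- with_substream(config$seed, paste0("taxonomy:", library),
                       .simulate_taxonomy(library, config$n_otus))
  tax <- tx$taxonomy; groups <- tx$groups
  otus <- tax$otu_id
  n_otu <- length(otus)

  # validate the effect map against the taxonomy groups
  effs <- config$effects[[library]]
  if (is.null(effs)) effs <- list()
  for (ef in effs) {
    if (!ef$group %in% names(groups))
      .stopf("effect map names taxon group '%s' absent from the %s taxonomy",
             ef$group, library)
    if (!ef$factor %in% names(design))
      .stopf("effect map names unknown design factor '%s'", ef$factor)
  }

  baseline <- with_substream(config$seed, paste0("baseline:", library),
                             stats::rlnorm(n_otu, config$baseline_meanlog,
                                           config$baseline_sdlog))
  names(baseline) <- otus
  host_otus <- tax$otu_id[tax$is_host_plant]
  org_otus <- tax$otu_id[tax$is_organelle]
  microbial <- setdiff(otus, c(host_otus, org_otus))
  baseline[c(host_otus, org_otus)] <- 0  # host/organelle share set per sample

  comp <- matrix(0, n_otu, n, dimnames = list(otus, design$sample_id))
  plant_frac <- setNames(numeric(n), design$sample_id)
  threshold <- config$depth_thresholds[[library]]

  counts <- with_substream(config$seed, paste0("counts:", library), {
    out <- matrix(0L, n_otu, n, dimnames = list(otus, design$sample_id))
    for (j in seq_len(n)) {
      p <- baseline
      for (ef in effs) {
        lev <- as.character(design[[ef$factor]][j])
        if (lev %in% names(ef$fold))
          p[groups[[ef$group]]] <- p[groups[[ef$group]]] * ef$fold[[lev]]
      }
      p <- p / sum(p)
      planted <- design$fraction[j] != "bulk"
      if (length(host_otus) && planted) {
        s <- stats::runif(1, config$host_contamination_range[1],
                          config$host_contamination_range[2])
        plant_frac[j] <- s
        p[microbial] <- p[microbial] * (1 - s)
        p[host_otus] <- s / length(host_otus)
      }
      if (length(org_otus) && planted) {
        s_org <- stats::runif(1, 0.005, 0.02)
        p <- p * (1 - s_org)
        p[org_otus] <- s_org / length(org_otus)
      }
      comp[, j] <- p
      depth <- max(100L, round(stats::rlnorm(1, log(2 * threshold),
                                             config$depth_sdlog)))
      if (is.finite(config$concentration)) {
        # Dirichlet draw via gammas, then multinomial
        alpha <- p * config$concentration
        gam <- stats::rgamma(n_otu, shape = alpha, rate = 1)
        gam[alpha == 0] <- 0
        if (sum(gam) == 0) gam <- p
        p_j <- gam / sum(gam)
      } else p_j <- p
      out[, j] <- stats::rmultinom(1, depth, p_j)[, 1L]
    }
    out
  })

  euk_target <- config$euk_fraction[design$fraction]
  euk_frac <- with_substream(config$seed, paste0("eukfrac:", library),
                             pmin(0.9, euk_target * stats::rlnorm(n, 0, config$euk_sdlog)))
  names(euk_frac) <- design$sample_id

  truth <- structure(list(
    composition = comp, groups = groups,
    plant_frac = plant_frac, euk_frac = euk_frac,
    effects = effs, library = library
  ), class = "ground_truth")

  list(counts = count_matrix(counts, library, allow_empty_samples = TRUE),
       taxonomy = tax, truth = truth)
}

#' Simulate qPCR Ct values from ground truth
#'
#' Inverts the 2^(-Ct) contribution estimator: a per-sample template "value"
#' sum is split into 16S and 18S parts according to the true eukaryote
#' fraction, the 18S part is inflated by host-plant contamination
#' (1/(1 - plant_frac18)), and Ct = -log2(value) plus Gaussian noise.
#'
#' @param truth A `ground_truth` from [simulate_counts()] (18S library), or
#'   any list with `euk_frac` and `plant_frac` named vectors.
#' @param config A `sim_config`.
#' @param value_sum Total template "value" (2^-Ct scale) per sample.
#' @return A `qpcr_table` with columns `sample_id`, `ct16`, `ct18`,
#'   `plant_frac18`.
#' @export
simulate_qpcr <- function(truth, config = sim_config(), value_sum = 2^-15) {
  e <- truth$euk_frac
  pf <- truth$plant_frac[names(e)]
  pf[is.na(pf)] <- 0
  if (any(e <= 0 | e >= 1))
    .stopf("true eukaryote fractions must lie in (0, 1)")
  v18 <- e * value_sum
  v16 <- (1 - e) * value_sum
  v18_obs <- v18 / (1 - pf)  # contamination inflates the observed 18S signal
  noise <- with_substream(config$seed, "qpcr",
                          matrix(stats::rnorm(2 * length(e), 0, config$ct_noise_sd),
                                 ncol = 2))
  qpcr_table(data.frame(
    sample_id = names(e),
    ct16 = -log2(v16) + noise[, 1L],
    ct18 = -log2(v18_obs) + noise[, 2L],
    plant_frac18 = pf,
    stringsAsFactors = FALSE))
}

#' Simulate a full multi-library dataset
#'
#' Convenience wrapper: design, the four amplicon libraries' counts and
#' taxonomies, ground truths, and the qPCR Ct table (driven by the 18S
#' ground truth).
#'
#' @param config A `sim_config`.
#' @param libraries Libraries to simulate.
#' @return List with `design`, `libraries` (per-library list of
#'   counts/taxonomy/truth) and `qpcr`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             libraries = LIBRARIES) {
  design <- simulate_design(config)
  libs <- lapply(libraries, function(lb) simulate_counts(design, config, lb))
  names(libs) <- libraries
  qp <- if ("eukaryote18S" %in% libraries) {
    simulate_qpcr(libs[["eukaryote18S"]]$truth, config)
  } else NULL
  list(design = design, libraries = libs, qpcr = qp)
}
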