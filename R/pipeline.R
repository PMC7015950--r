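# One-command orchestration: simulate (or ingest) -> preprocess -> qPCR
# ratios -> core membership -> ordination / PERMANOVA / CAP -> taxa screens,
# with every stage output written as a tab-separated table and a run
# manifest recording seeds, thresholds and stage checksums.

#' Build a pipeline configuration
#'
#' @param sim A `sim_config` for synthetic input, or `NULL` to ingest
#'   tables from `input_dir`.
#' @param input_dir Directory with `counts_<library>.tsv`,
#'   `taxonomy_<library>.tsv`, `metadata.tsv`, `qpcr.tsv` (used when
#'   `sim` is `NULL`).
#' @param libraries Amplicon libraries to process.
#' @param thresholds Named per-library depth thresholds.
#' @param permanova_terms Ordered model terms for [permanova()].
#' @param n_perm Permutations for PERMANOVA/CAP.
#' @param alpha Significance level for letter displays.
#' @param seed Global seed; all stage streams derive from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            input_dir = NULL,
                            libraries = c("prokaryote16S", "eukaryote18S"),
                            thresholds = default_depth_thresholds(),
                            permanova_terms = c("fraction", "ploidy", "ancestry",
                                                "species(ancestry)", "genotype(species)"),
                            n_perm = 999L, alpha = 0.05, seed = 1L,
                            out_dir = tempfile("wheatrhizo_run_")) {
  structure(list(sim = sim, input_dir = input_dir, libraries = libraries,
                 thresholds = thresholds, permanova_terms = permanova_terms,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate or ingest the per-library count/taxonomy tables,
#' metadata and qPCR Ct table; (2) preprocess each library (host/organelle
#' removal, depth standardization, relative abundance, square root);
#' (3) qPCR eukaryote:prokaryote ratios and group comparison; (4) core
#' membership and Venn partition (16S, rhizosphere); (5) Bray-Curtis +
#' PCoA + PERMANOVA (+ CAP when a single grouping is requested); (6) taxa
#' aggregation, group tests, correlation and fold screens. All outputs are
#' written under `config$out_dir`; results are also returned.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(seed = seed, thresholds = as.list(config$thresholds),
                   n_perm = config$n_perm, alpha = config$alpha,
                   permanova_terms = config$permanova_terms)

  # stage 1: inputs
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim, libraries = config$libraries)
  } else {
    if (is.null(config$input_dir)) .stopf("either sim or input_dir must be set")
    ds <- .ingest_dataset(config$input_dir, config$libraries)
  }
  design <- ds$design
  for (lb in config$libraries) {
    .check_consistent(ds$libraries[[lb]]$counts, design, lb)
    write_count_table(ds$libraries[[lb]]$counts, file.path(out, paste0("counts_", lb, ".tsv")))
    write_taxonomy_table(ds$libraries[[lb]]$taxonomy, file.path(out, paste0("taxonomy_", lb, ".tsv")))
  }
  write_metadata(design, file.path(out, "metadata.tsv"))
  if (!is.null(ds$qpcr)) write_qpcr_table(ds$qpcr, file.path(out, "qpcr.tsv"))

  # stage 2: preprocess
  prep <- list()
  for (lb in config$libraries) {
    prep[[lb]] <- preprocess_library(ds$libraries[[lb]]$counts,
                                     ds$libraries[[lb]]$taxonomy,
                                     threshold = config$thresholds[[lb]],
                                     seed = substream_seed(seed, paste0("prep:", lb)))
    write_tsv(prep[[lb]]$host_report, file.path(out, paste0("host_report_", lb, ".tsv")))
  }

  # stage 3: qPCR ratios (18S host fractions come from the 18S host report)
  qres <- NULL
  if (!is.null(ds$qpcr)) {
    ratios <- qpcr_ratios(ds$qpcr)
    write_tsv(ratios, file.path(out, "qpcr_ratios.tsv"))
    grp <- tryCatch(compare_ratio_groups(ratios, design, group = "species"),
                    error = function(e) NULL)
    if (!is.null(grp)) {
      write_tsv(grp$pairwise, file.path(out, "qpcr_pairwise.tsv"))
      write_tsv(grp$groups, file.path(out, "qpcr_groups.tsv"))
    }
    qres <- list(ratios = ratios, groups = grp)
  }

  # stage 4: core membership (16S rhizosphere, the study's headline Venn)
  core <- NULL
  if ("prokaryote16S" %in% config$libraries &&
      any(design$fraction == "rhizosphere")) {
    core <- core_summary(prep[["prokaryote16S"]]$standardized$counts, design,
                         fraction = "rhizosphere")
    write_tsv(core$summary, file.path(out, "core_summary.tsv"))
    write_tsv(core$venn$region_sizes, file.path(out, "venn_regions.tsv"))
  }

  # stage 5: ordination + PERMANOVA per library
  ords <- list(); perms <- list()
  for (lb in config$libraries) {
    tr <- prep[[lb]]$transformed
    keep <- setdiff(colnames(tr), attr(tr, "empty_samples"))
    d <- bray_curtis(tr[, keep, drop = FALSE])
    ords[[lb]] <- pcoa(d)
    coords <- ords[[lb]]$coordinates
    write_tsv(data.frame(sample_id = rownames(coords), coords[, 1:min(4L, ncol(coords))]),
              file.path(out, paste0("pcoa_", lb, ".tsv")))
    meta_lb <- design[match(keep, design$sample_id), ]
    terms <- config$permanova_terms
    # drop terms constant in this data subset (e.g. single fraction)
    terms <- Filter(function(tm) {
      f <- .parse_term(tm)$factor
      length(unique(meta_lb[[f]])) > 1L
    }, terms)
    perms[[lb]] <- permanova(d, meta_lb, terms, n_perm = config$n_perm,
                             seed = substream_seed(seed, paste0("permanova:", lb)))
    write_tsv(perms[[lb]]$table, file.path(out, paste0("permanova_", lb, ".tsv")))
  }

  # stage 6: taxa screens (phylum level)
  taxa <- list()
  for (lb in config$libraries) {
    tm <- aggregate_taxa(prep[[lb]]$rel, ds$libraries[[lb]]$taxonomy, "phylum")
    planted <- intersect(colnames(tm),
                         design$sample_id[design$fraction != "bulk"])
    # preferred screen factor per library, falling back to the first factor
    # that actually varies with n >= 2 per level in this subset
    prefer <- if (lb == "eukaryote18S") "d_genome" else "fraction"
    meta_planted <- design[match(planted, design$sample_id), ]
    usable <- function(f) {
      sizes <- table(meta_planted[[f]])
      length(sizes) >= 2L && all(sizes >= 2L)
    }
    fac <- Find(usable, c(prefer, "fraction", "d_genome", "species"))
    taxa_tests <- if (length(planted) >= 4L && !is.null(fac)) {
      group_tests(tm[, planted, drop = FALSE], design, factor = fac,
                  alpha = config$alpha)
    } else NULL
    fold <- fold_change_screen(tm, design, factor = "species")
    write_tsv(as.data.frame(as.table(tm), stringsAsFactors = FALSE),
              file.path(out, paste0("taxa_phylum_", lb, ".tsv")))
    write_tsv(fold, file.path(out, paste0("fold_screen_", lb, ".tsv")))
    if (!is.null(taxa_tests)) {
      write_tsv(taxa_tests$tests, file.path(out, paste0("taxa_tests_", lb, ".tsv")))
      write_tsv(taxa_tests$letters, file.path(out, paste0("taxa_letters_", lb, ".tsv")))
    }
    taxa[[lb]] <- list(matrix = tm, tests = taxa_tests, fold = fold)
  }

  manifest$stages <- c("simulate/ingest", "preprocess", "qpcr", "core",
                       "ordination", "taxa")
  manifest$files <- sort(list.files(out))
  manifest$checksums <- vapply(manifest$files, function(f) {
    sum(utf8ToInt(paste(readLines(file.path(out, f), warn = FALSE), collapse = "\n")))
  }, numeric(1L))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out, "manifest.json"))
  invisible(list(design = design, dataset = ds, preprocessed = prep,
                 qpcr = qres, core = core, ordinations = ords,
                 permanova = perms, taxa = taxa, manifest = manifest,
                 out_dir = out))
}

.check_consistent <- function(counts, design, lb) {
  extra <- setdiff(sample_ids(counts), design$sample_id)
  missing <- setdiff(design$sample_id, sample_ids(counts))
  if (length(extra))
    .stopf("[%s] counts sample(s) missing from metadata: %s", lb,
           paste(extra, collapse = ", "))
  if (length(missing))
    wr_log("[", lb, "] metadata sample(s) without counts (treated as absent): ",
           paste(missing, collapse = ", "))
  invisible(TRUE)
}

.ingest_dataset <- function(dir, libraries) {
  design <- read_metadata(file.path(dir, "metadata.tsv"))
  libs <- lapply(libraries, function(lb) {
    list(counts = read_count_table(file.path(dir, paste0("counts_", lb, ".tsv")), lb,
                                   allow_empty_samples = TRUE),
         taxonomy = read_taxonomy(file.path(dir, paste0("taxonomy_", lb, ".tsv"))),
         truth = NULL)
  })
  names(libs) <- libraries
  qp_path <- file.path(dir, "qpcr.tsv")
  qp <- if (file.exists(qp_path)) read_qpcr(qp_path) else NULL
  list(design = design, libraries = libs, qpcr = qp)
}
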