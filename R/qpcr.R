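# Eukaryote:prokaryote contribution estimator from 16S/18S qPCR Ct values.
# Each Ct is transformed to a "value" 2^(-Ct); the 18S value is corrected
# for host-plant DNA (if half the 18S amplicons are of host-plant origin,
# the 18S value is halved); the eukaryote contribution is the corrected 18S
# share of the value sum. No absolute quantification is attempted.

#' Transform a Ct value to a template "value"
#'
#' @param ct Cycle-threshold value(s), finite.
#' @return `2^(-ct)`.
#' @export
ct_to_value <- function(ct) {
  if (any(!is.finite(ct))) .stopf("non-finite Ct value")
  2^(-ct)
}

#' Correct an 18S qPCR value for host-plant DNA
#'
#' Multiplies the 18S value by `(1 - plant_frac18)`: if 50% of the 18S
#' amplicons originate from the host plant, the 18S result is halved.
#'
#' @param value18 Non-negative 18S qPCR value(s).
#' @param plant_frac18 Fraction(s) in \[0, 1\] of 18S amplicons of
#'   host-plant origin.
#' @return Corrected value(s).
#' @export
correct_host <- function(value18, plant_frac18) {
  if (any(!is.finite(plant_frac18)) || any(plant_frac18 < 0) || any(plant_frac18 > 1))
    .stopf("plant_frac18 must lie in [0, 1]")
  value18 * (1 - plant_frac18)
}

#' Eukaryote contribution from 16S and corrected 18S values
#'
#' @param v16 16S value(s), non-negative.
#' @param v18c Host-corrected 18S value(s), non-negative.
#' @return Percent contribution of the 18S value to the value sum.
#' @export
eukaryote_fraction <- function(v16, v18c) {
  if (any(v16 + v18c <= 0)) .stopf("16S and 18S values are both zero")
  100 * v18c / (v16 + v18c)
}

#' Per-sample eukaryote:prokaryote ratio estimates
#'
#' @param qpcr A `qpcr_table` (columns `sample_id`, `ct16`, `ct18`,
#'   `plant_frac18`).
#' @return Data frame with `sample_id`, `v16`, `v18_corrected`, `euk_pct`,
#'   `prok_pct` (`euk_pct + prok_pct == 100` exactly).
#' @export
qpcr_ratios <- function(qpcr) {
  stopifnot(inherits(qpcr, "qpcr_table"))
  v16 <- ct_to_value(qpcr$ct16)
  v18c <- correct_host(ct_to_value(qpcr$ct18), qpcr$plant_frac18)
  euk <- eukaryote_fraction(v16, v18c)
  data.frame(sample_id = qpcr$sample_id, v16 = v16, v18_corrected = v18c,
             euk_pct = euk, prok_pct = 100 - euk, stringsAsFactors = FALSE)
}

# Welch two-sample t-test with a degenerate-variance convention: if both
# group variances are zero, p = 1 for equal means and p = 0 otherwise.
.welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Compare eukaryote percentages between sample groups
#'
#' One-way ANOVA across groups plus all pairwise two-sided Welch t-tests
#' with Bonferroni correction (raw p times the number of pairs, capped at
#' 1). The Bonferroni family is the full set of pairwise comparisons in this
#' call.
#'
#' @param ratios Output of [qpcr_ratios()] (or any data.frame with
#'   `sample_id` and a value column).
#' @param meta A `sample_frame`.
#' @param group Metadata column defining the groups (e.g. `"species"`).
#' @param value Column of `ratios` to compare.
#' @return List with `anova` (data.frame: F, df, p), `pairwise` (data.frame:
#'   group_a, group_b, t raw p, Bonferroni p) and `groups` (per-group n,
#'   mean, se).
#' @export
compare_ratio_groups <- function(ratios, meta, group = "species", value = "euk_pct") {
  stopifnot(inherits(meta, "sample_frame"))
  if (!group %in% names(meta)) .stopf("unknown grouping column '%s'", group)
  idx <- match(ratios$sample_id, meta$sample_id)
  if (anyNA(idx))
    .stopf("ratio sample(s) absent from metadata: %s",
           paste(ratios$sample_id[is.na(idx)], collapse = ", "))
  g <- as.character(meta[[group]][idx])
  x <- ratios[[value]]
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    .stopf("need >= 2 groups with >= 2 samples each; got: %s",
           paste(sprintf("%s(n=%d)", names(sizes), sizes), collapse = ", "))
  fit <- stats::aov(x ~ factor(g))
  an <- summary(fit)[[1L]]
  anova_tab <- data.frame(term = group, df = an$Df[1L], df_resid = an$Df[2L],
                          F = an$`F value`[1L], p = an$`Pr(>F)`[1L])
  levels <- sort(unique(g))
  pairs <- utils::combn(levels, 2L)
  n_pairs <- ncol(pairs)
  pw <- lapply(seq_len(n_pairs), function(k) {
    a <- x[g == pairs[1L, k]]; b <- x[g == pairs[2L, k]]
    p_raw <- .welch_p(a, b)
    data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
               mean_a = mean(a), mean_b = mean(b), p_raw = p_raw,
               p_bonferroni = min(1, p_raw * n_pairs),
               stringsAsFactors = FALSE)
  })
  groups <- data.frame(
    group = levels,
    n = as.integer(sizes[levels]),
    mean = vapply(levels, function(l) mean(x[g == l]), numeric(1L)),
    se = vapply(levels, function(l) stats::sd(x[g == l]) / sqrt(sum(g == l)), numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(anova = anova_tab, pairwise = do.call(rbind, pw), groups = groups)
}
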