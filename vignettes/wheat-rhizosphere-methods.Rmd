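---
title: "Methods: wheat rhizosphere and root microbiota analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wheat rhizosphere and root microbiota analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatrhizo)
```

## Scope and model of the data

`wheatrhizo` re-implements, as a tested pipeline, an amplicon-based analysis
of how wheat genomic content shapes the rhizosphere and root microbiota. The
experimental frame is a glasshouse design with 22 plant lines spanning six
groups — modern bread wheat (*T. aestivum*, AABBDD, artificially selected D
genome), pasta wheat (*T. durum*, AABB, no D), wild goat grass (*A.
tauschii*, DD, wild D), wild emmer (*T. dicoccoides*, AABB, no D), synthetic
hexaploid wheat (SHW, AABBDD, wild D) and F1 crosses of SHW with bread wheat
(mixed D) — plus unplanted bulk soil controls, sampled in rhizosphere and
root fractions and profiled with up to four amplicon libraries (prokaryote
16S, eukaryote 18S, fungal ITS1, oomycete ITS1) and 16S/18S qPCR.

The pipeline starts from OTU count tables (OTUs x samples), a per-OTU
taxonomy with host-plant and organelle flags, a sample metadata table of
design factors, and a qPCR Ct table. Raw-read processing (merging, quality
filtering, clustering, database annotation) is out of scope; the count table
is the entry point. Failed samples are encoded as absent columns, never as
zero columns: an all-zero sample is rejected unless explicitly flagged.

The design factors nest: each genotype (line) belongs to exactly one
species, each species to one ancestry class; validation enforces this. The
spec-level factor sets (ancestry in modern/wild/synthetic, ploidy in
2/4/6) cannot describe the unplanted control, so the package reserves
ancestry `"none"` and ploidy `0` for `genotype == "unplanted"`.

## Preprocessing

The order is fixed and mirrors standard practice for this kind of data:

1. **Host/organelle removal** (`remove_host_taxa()`): all OTUs flagged as
   host plant or organelle are removed *before* any standardization; the
   removed fractions are reported per sample on pre-removal totals. The 18S
   plant fraction is the input to the qPCR host correction.
2. **Depth standardization** (`standardize_depth()`): an upper threshold per
   library (defaults 10,000 / 5,000 / 3,000 / 2,000 reads for 16S / 18S /
   fungal ITS1 / oomycete ITS1). "Upper threshold" is implemented as
   subsampling without replacement (rarefaction) to exactly the threshold —
   the only reading that equalizes the number of sequences per sample;
   simple truncation would not. Samples already at or below the threshold
   are kept unchanged by default (nothing in the source protocol indicates
   samples were discarded); `policy = "drop"` exposes the alternative. Each
   sample gets its own RNG substream derived from `(seed, sample_id)`, so
   the subsample cannot depend on column order.
3. **Relative abundance** (`to_relative()`): each sample scaled so all OTUs
   contribute 100%.
4. **Square root** (`sqrt_transform()`): damps dominant OTUs so that
   distance-based analyses also see the less abundant community.

## qPCR eukaryote:prokaryote estimator

Each Ct is transformed to a "value" `2^(-Ct)`; under ideal amplification
efficiency the value is proportional to the initial template. The 18S value
is corrected for host-plant DNA by multiplying with `(1 - plant_frac18)` —
if half the 18S amplicons are of plant origin, the 18S value is halved —
and the eukaryote contribution is `100 * v18c / (v16 + v18c)`. No absolute
quantification is attempted: copy-number differences, extraction and primer
biases cancel only in sample-to-sample comparison, which is all the
estimator claims. The estimator is exactly invertible, and the synthetic
qPCR generator exploits that: it draws a per-sample true eukaryote fraction,
splits a fixed template value sum accordingly, inflates the 18S part by
`1/(1 - plant_frac)` and adds Gaussian Ct noise (default sd 0.15 cycles).
With the noise at zero the estimator recovers the generated fraction to
machine precision, which the tests assert at 1e-9.

Group comparisons use one-way ANOVA plus all pairwise Welch t-tests with
Bonferroni correction (raw p times the number of pairs, capped at 1; the
family is one comparison panel). Welch was chosen because the source tool's
t-variant is unstated and unequal variances are the safer default. A
degenerate pair with two zero-variance groups gets p = 1 when the means are
equal and p = 0 otherwise (the limit behaviour, avoiding NaN).

## Core microbiota and Venn partition

An OTU is stably associated with a species when it is present in **every**
line of that species, in at least a fraction `min_rep_frac` (default 25%)
of each line's biological replicates. With `n` replicates the required
count is `ceiling(0.25 * n)`: "at least 25%" is read as a lower bound on
the realized fraction, so 2 of 7 qualifies while 1 of 7 (14%) does not.
Presence means at least one read after depth standardization; evaluating
presence before standardization is available by passing the unstandardized
matrix. The Venn partition gives the shared core (intersection over all
species), species-specific sets (in one core and no other), and all
2^k - 1 regions. Abundance shares are computed per sample (sum of the
set's percents) and then averaged — not pooled across reads — matching the
per-sample standardization to 100%.

## Distances, PCoA, PERMANOVA, CAP

All distance-based machinery is implemented from first principles in the
package (external packages appear only as independent oracles in the test
suite).

**Distance.** The source analyses standardized, square-root transformed
abundances in PRIMER without naming a metric; Bray–Curtis is the standard
companion of that transform in community ecology and is the default, with
Euclidean and Jaccard selectable. The downstream machinery is
metric-agnostic.

**PCoA.** Gower-centred matrix `G = -1/2 J D^2 J`, eigendecomposition,
coordinates = eigenvectors scaled by the square root of positive
eigenvalues. Negative eigenvalues (Bray–Curtis is not Euclidean-embeddable)
are reported but contribute no axes; no Lingoes/Cailliez correction is
applied by default — transparency over silent distortion. Group centroids
with per-axis standard errors provide the averaged-location presentation
for crowded ordinations; singleton groups report a missing SE.

**PERMANOVA.** Total SS is `tr(G)`. For an ordered term list with
cumulative-design hat matrices, Type I (sequential) SS of term *j* is
`tr(H_j G) - tr(H_{j-1} G)`; Type III (marginal) SS is
`tr(H_full G) - tr(H_{-j} G)`. Sequential SS is the default because it
keeps low-df factors testable. The pseudo-F denominator is the residual
mean square for every term (one pseudo-F per term is reported, matching
the flat "fixed multifactorial" presentation); nested error structures can
be emulated by comparing terms against the nested-term MS externally.
P-values use permutation of residuals under the reduced model, realized as
Freedman–Lane on the Gower matrix: with `H_red` the reduced-model hat
matrix, residual matrix `R = (I - H_red) G (I - H_red)` is
row/column-permuted and added back to the fitted part, and the pseudo-F is
recomputed; `p = (1 + #{F* >= F}) / (1 + n_perm)`, which is valid and never
zero. Terms written `A(B)` are nested (A within B): their permutations are
restricted to within the levels of B, mirroring genotypes nested in
species nested in ancestry. Samples are put into a canonical (sorted)
order internally so the permutation stream — hence the p-value — cannot
depend on input order. With a single factor the reduced model is the
intercept and, because `G` is doubly centred, the scheme reduces exactly
to label permutation; this is what makes the exhaustive-enumeration oracle
in the tests exact. Type III marginal SS is undefined (zero rank) for a
term contained in another term's span — e.g. ancestry once genotype is in
the model — and the package raises a clear error rather than reporting a
0-df test.

**CAP.** PCoA axes are computed; if the number of retained axes `m` is not
given, it is chosen in `1..min(n-2, rank)` to maximize leave-one-out
allocation success of a nearest-centroid classifier on the first `m` axes,
smallest `m` on ties (parsimony, deterministic). Canonical axes come from
the eigen-analysis of the group projection of the orthonormal PCoA axes;
the trace statistic is tested by permuting group labels.

## Taxa screens

`aggregate_taxa()` pools OTU percents by a lineage rank; empty ranks go to
an explicit `"unassigned"` bin so column totals stay at 100. OTUs whose
order is Glomerales, Diversisporales, Archaeosporales or Paraglomerales
(matched case-insensitively, including a variant spelling of the last)
count as Glomeromycetes. Per-taxon screens combine one-way ANOVA, pairwise
Welch/Bonferroni tests, and a compact letter display built by a
deterministic insert-and-absorb pass over levels ordered by decreasing
mean; two levels share a letter exactly when their adjusted p is at or
above alpha. The doubled-abundance screen compares each species' mean
against the **unweighted mean of the other species' means** (robust to
unequal replication and matching the per-species framing), flagging folds
at or above 2; a zero denominator with a positive numerator is flagged with
an infinite fold. The taxon–taxon Pearson correlation defaults to genotype
means as the unit — the comparison is across plant groups, not within-pot
noise — with a per-sample option retained. For taxa-driven ordination,
`taxa_pca()` runs covariance-based PCA on the standardized percent table
(not correlation-based: rescaling every taxon to unit variance would give
rare taxa the same leverage as dominant ones, which is exactly what the
percent scale is meant to convey).

## Synthetic community generator

The generator is first-class, tested code with known ground truth; its
defaults are the study conditions:

* design: the 22-line/6-group table with 8 replicates per line (the study
  used 6–10 per line; a uniform 8 keeps the default balanced) plus 8 bulk
  controls, rhizosphere and root fractions;
* composition: a log-normal baseline OTU profile (meanlog 0, sdlog 1.5, a
  typical steep rank-abundance curve) shared by all samples, multiplied by
  per-group effects and renormalized;
* counts: Dirichlet-multinomial with concentration 200 — overdispersion is
  what PERMANOVA calibration is sensitive to, so a plain multinomial would
  be too clean; `Inf` recovers it for null checks;
* depths: log-normal around twice the per-library threshold (log-sd 0.3),
  so the rarefaction path is genuinely exercised while ≥ 90% of samples
  clear the threshold;
* host contamination: per-sample share of the 18S community drawn uniformly
  from 14–75% in planted samples (the observed range in this system), plus
  a small organelle share (0.5–2%) in planted 16S samples;
* default effects: Proteobacteria 2.5x in rhizosphere and 6x in roots, with
  Actinobacteria/Acidobacteria depleted in roots (the niche gradient);
  Cyanobacteria 8x in bread wheat; Nematoda 4x and Glomeromycetes 3x under
  a wild D genome (2x for the mixed-D F1s), reproducing the observed
  ~8% vs ~2% Nematoda contrast. Tying both taxa to the same factor is what
  generates their across-genotype correlation; no within-sample residual
  coupling is added, because the observed correlation is across plant
  groups;
* qPCR: target eukaryote contributions of 5.4% (bulk) and 6.8% (planted)
  with log-normal per-sample jitter (sd 0.08) and 0.15-cycle Ct noise.

Multiplicative effects act on relative abundances before renormalization,
so a nominal 4x fold is slightly damped in closed compositions; the
parameter-recovery tests account for this. Within-genotype variance has no
empirical anchor in the source system, so the dispersion defaults are free
parameters chosen once to look like real amplicon data; they were not
tuned to any test outcome.

What the generator does **not** emulate: read-level artefacts (chimeras,
PCR bias), taxon-taxon interactions, spatial or temporal structure, and
unbalanced per-line replication. Passing tests therefore demonstrate the
statistical machinery and its calibration under a realistic generative
model, not the biology of any particular soil.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at reduced but
structurally faithful sizes (2–6 species groups, 60–300 OTUs, thresholds
1,000–10,000, 199–9,999 permutations), chosen as the package's own
desk-scale study conditions. Tolerances: ANOVA-equivalence at 1e-10,
Euclidean PCoA reconstruction at 1e-8, estimator inversion at 1e-9,
round-trip floats at 1e-12. Eigenvalues below `max|eig| * 1e-9` are
treated as zero. Ties in permutation tests count as at least as extreme.
Calibration tests use exact binomial 99% intervals around the nominal
rate, so they are strict but have a known 1% false-alarm budget each.

## Known limitations

* Bray–Curtis on sparse, rarefied tables yields negative PCoA eigenvalues;
  axes and explained proportions refer to the positive part only.
* The pseudo-F denominator is always the residual MS; hierarchical designs
  that require synthetic denominators must combine terms manually.
* Type III tests are only available for marginally identifiable terms.
* The compact letter display is deterministic but not guaranteed minimal in
  the number of letters (insert-and-absorb, not clique cover).
* `fold_change_screen()` with near-zero denominators is fragile by
  construction; the infinite-fold sentinel marks, not hides, this.
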