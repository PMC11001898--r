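---
title: "Methods: transcriptional noise, module scores and time-course modules in lungspan"
author: "lungspan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional noise, module scores and time-course modules in lungspan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungspan)
ls_quiet(TRUE)
```

# Scope

`lungspan` packages the bespoke computations used in single-cell RNA-seq
studies of organ development and aging that compare five ordered life-stage
groups (T1 < T2 < T3 < T4 < T5, spanning development through the aging
adult): per-cell transcriptional-noise estimation, gene-signature scoring
against abundance-matched random controls, pseudobulk time-course
co-expression modules, per-gene t-test differential expression with
Benjamini-Hochberg FDR control, score-gated Pearson correlation, and the
statistical decision tree used for cohort tables. A negative-binomial
simulator plants all of these structures with known ground truth, so that
every estimator in the package can be validated by parameter recovery.

Alignment, batch integration, clustering/annotation, pseudotime, regulon
and cell-cell-interaction analyses are out of scope: they are served by
established tools and the package assumes their outputs (a count matrix
with cell-type labels) as its input.

# QC and normalization

Cells with fewer than 200 detected genes or more than 10% mitochondrial
UMIs are removed, then genes with total UMI counts of 5 or fewer (the
threshold is strict: a total of exactly 5 is removed, 6 is kept). Order
matters and is fixed — cells first, then genes — and the filter is
idempotent. Both boundaries are deliberate readings of the conventional
thresholds: "at least 200 features" keeps the boundary cell, "max 10%"
keeps a cell at exactly 10%. Mitochondrial genes are recognized by the
symbol prefix `MT-` (configurable); percent.mt is computed on the
unfiltered matrix.

Normalization is CP10K-log: each cell is scaled to 10,000 transcripts and
natural-log transformed, `value = ln(1 + 10000 * count / total)`. Cell
totals are taken on the post-filter gene universe, so downstream
`sum(expm1(value))` is exactly 10,000 per cell. Natural log is the
convention of the single-cell ecosystem this pipeline mirrors.

# Transcriptional noise

Noise is a per-cell distance: how far a cell's expression profile sits
from a reference profile, in log-normalized space. Two variants:

* **Cell-type centroid** (`noise_to_celltype_mean`): the reference is the
  arithmetic mean vector of the cell's stratum, and the statistic is the
  Euclidean distance over all retained genes. By default strata are
  cell-type × group; pooling groups within a cell type
  (`grouping = "by_celltype"`) is also available, because with pooled
  centroids an age trend in mean expression inflates the distance even
  when cell-to-cell variability is unchanged. The per-group default keeps
  centroid shifts out of the noise statistic, which is what a dispersion
  (variability) measure should isolate; both modes are exposed since
  either reading of "the cell type mean vector" is defensible.
* **Invariant genes** (`noise_invariant_variant`): genes are ranked by mean
  abundance, split into 10 equal-size bins (remainder genes join the
  highest bins — an arbitrary but fixed convention), and the 10% of genes
  with the lowest coefficient of variation within each bin (at least one
  per bin) form the invariant set. "Invariant" is operationalized as
  lowest within-bin CV: CV is the standard scale-aware stability
  criterion, and binning keeps the selection even across the abundance
  range. The noise statistic is then each cell's distance to the global
  mean profile over this gene set, with no cell-type stratification.
  Selection uses all cells rather than per-cell-type subsets.

Distances are computed on log-normalized values, not z-scored residuals:
noise is estimated right after normalization and the procedure mentions no
further scaling. Degenerate strata (fewer than 2 cells) are skipped with a
warning rather than an error, since a single odd cluster should not kill
a whole run. Summaries report median and quartiles per cell type × group
(the boxplot quantities), using linear-interpolation quantiles.

The estimator's contract is testable: identical cells give distance zero,
scaling all within-stratum deviations by c scales every distance by c,
and appending constant genes or permuting gene order changes nothing.

# Signature (module) scores

For a cell *i* and gene set *G~j~*, the score is

$$SC_j(i) = \mathrm{avg}(Er(G_j, i)) - \mathrm{avg}(Er(G_j^{cont}, i))$$

where *Er* is log-normalized expression and *G~j~^cont^* is a random
control gene set matched to *G~j~* on expression: all genes are cut into
25 equal-size bins by mean expression, and each target gene draws 100
controls uniformly from its own bin (without replacement when the bin is
large enough; a bin emptied by set-gene exclusion falls back to the
nearest non-empty bin with a warning). The pooled control draws — kept
with multiplicity — give a control average with the same expression
distribution as the set but no coherent signal, so the score's null
expectation is zero and adding a per-cell constant to all expression
values leaves the score unchanged. Bin count 25 and 100 controls per gene
are the defaults of the method family this implements; both are exposed.
*Er* is taken as the log-normalized value itself, with no further per-gene
centering — the formula-exact, default-settings reading.

# Time-course co-expression modules

The time-course input is a pseudobulk matrix: per gene, the mean
log-normalized expression over the selected cells of each of the five
groups, z-scored per gene (constant genes are dropped with a warning).
This is the conventional time-course-clustering input; it makes trajectory
*shapes* comparable across expression magnitudes, which is what co-expression
modules are about. The construction of the matrix entering clustering is a
design decision of this package — exact upstream preprocessing choices of
any particular study are rarely published — and is documented as such.

Modules come from standard fuzzy c-means with k = 6 and fuzzifier m = 2:

$$u_{gk} = \Big(\sum_l (\lVert x_g - c_k\rVert / \lVert x_g - c_l\rVert)^{2/(m-1)}\Big)^{-1},
\qquad c_k = \frac{\sum_g u_{gk}^m x_g}{\sum_g u_{gk}^m}$$

minimizing $J = \sum_{g,k} u_{gk}^m \lVert x_g - c_k\rVert^2$. The
alternating updates make J non-increasing (asserted in tests); a gene
landing exactly on a centroid gets membership 1 there. Because c-means is
initialization-sensitive, 20 seeded restarts are run (centroids drawn from
data rows) and the lowest-J fit kept; with a fixed seed the result is
bit-reproducible. k = 6 is the package default; m = 2 is the usual choice
and exposed as a parameter.

Centroid trajectories are labeled by a step rule: consecutive differences
are thresholded at ε = 0.1 (on the z scale) into +/0/−;
`development_up` requires non-negative T1→T3 steps with at least one
positive, `t3_peak` additionally requires negative steps T3→T5,
`aging_down` requires a negative T4→T5 step. Flags are non-exclusive and
the primary label follows the precedence t3_peak > development_up >
aging_down > flat. The rule (and ε) is a labeling convention of this
package, not an estimate. Note the label vocabulary has no "down" mirror
labels: a development-down trajectory typically carries a negative late
step and labels as `aging_down`, and a T3-trough trajectory matches no
flag and labels `flat`.

# Differential expression and overlap lists

Per-gene two-group testing mirrors the standard single-cell marker test:
genes are pre-filtered to those detected in ≥ 10% of cells in at least one
group and with |log2FC| ≥ 0.25, then tested with the Welch
(unequal-variance) two-sample t-test on log-normalized values; BH
adjustment runs over the tested genes only. Welch rather than pooled is
the robust default for unequal group sizes. log2FC is computed on
de-logged means with a pseudocount,
`log2((mean(expm1(x_A)) + 1) / (mean(expm1(x_B)) + 1))` — the common
single-cell convention, which tolerates all-zero groups; the pseudocount
is a parameter. Disease-list overlaps intersect each list with genes at
unadjusted p < 0.05 and log2FC > 0.25 (up-regulated), reporting counts and
identities. Disease lists are user-supplied plain-text files; the package
does not retrieve any database.

# Score-gated correlation

The correlation stage selects cells of the adult groups (T4, T5 by
default) whose supplied scores are **all** strictly greater than 0.01 —
"greater than" is read strictly, so boundary cells are excluded, and the
gate is a conjunction over every supplied score — then computes Pearson's
r between a gene's log-normalized expression and each score over that
subset, with the usual t approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ for the two-sided p-value (a permutation
p-value would also be defensible; the t approximation is what standard
tooling reports and is accurate at the cell numbers involved). Fewer than
3 gated cells is an explicit error, never a NaN.

# The synthetic-data generator

`simulate_dataset` draws UMI counts gene-by-gene as negative binomial
(Gamma-Poisson) with lognormal cell size factors (mean 1) — the standard
generative model for droplet scRNA-seq, sufficient to exercise every
downstream stage. Its planted structures, all recorded in the returned
ground truth:

* **Cell types** with marker blocks (default two types, 25 markers each at
  4-fold) assigned uniformly to cells.
* **Temporal programs**: per-gene multiplicative trajectories on group rank
  1..5 (not chronological age — the analysis only ever sees the five
  ordered groups), in log2 units scaled by an amplitude. Shapes:
  `dev_up` strictly increasing (0, 0.35, 0.6, 0.8, 1) so that pseudobulk
  trajectories are monotone up to sampling noise; `t3_peak`
  (0, 0.6, 1, 0.6, 0); `aging_down` (1, 1, 1, 1, 0); plus negations and
  flat. Program genes are planted on the upper half of the abundance
  distribution: trajectories of near-zero-expression genes are not
  recoverable from pseudobulk means and are not what time-course
  clustering targets.
* **Aging noise** as dispersion inflation: the NB size of every gene is
  divided by a per-group multiplier (default 2 in T5). Inflating
  dispersion rather than shifting means raises distance-to-centroid
  without moving the centroid, isolating exactly what the noise statistic
  measures.
* **A focal gene** ("FTL"-like: highly expressed, tightly dispersed) with a
  development-up / aging-down trajectory (0, 0.5, 1, 1, 0.45).
* **Housekeeping genes** (optional): near-Poisson genes placed at evenly
  spaced abundance quantiles — planted targets for invariant-gene
  selection. Their low-CV signature is only resolvable where counts are
  high enough that overdispersion, not detection noise, dominates
  variability; recovery tests therefore use a well-measured configuration
  (tight Gamma abundance distribution, tens of counts per cell).
* **A signature link**: a per-cell latent factor u loads on the signature
  gene set (natural-log loading 0.8 by default) and, mixed with an
  independent factor, on the focal gene, so that the focal gene's
  expression correlates with the set's module score at a configured
  target r (default 0.8) on the score-gated cell population.

The signature-link calibration deserves detail, because three mechanisms
attenuate a naively planted correlation: (1) NB count noise in both the
focal gene and the score (delta-method variance ≈ 1/μ + 1/size per gene);
(2) the focal gene's own T4-vs-T5 trajectory step, which adds variance
uncorrelated with the latent factor; (3) CP10K compression — the latent
genes are a non-negligible share of the library, so the per-cell total
co-varies with u and normalization subtracts part of the swing from every
gene. The binned-control construction cancels (3) for scores (set and
control averages are compressed equally) but not for the focal gene's raw
expression. On top of these, the downstream gate (score > 0.01) truncates
the score distribution near its mean and shrinks the observed correlation
further. The generator therefore plants the latent mixing coefficient by
simulating its own Gaussian abstraction of this chain (fixed internal
seed, 2×10^5 draws, bisection) so that the correlation on the *gated*
population equals the configured target; the control-average noise
coefficient in that abstraction (three times the set-average count-noise
variance) comes from the generator's design analysis of the pooled,
weighted control draws. The calibration is part of the generator's
definition, fixed a priori, and recovery to within ±0.05 across seeds is
what the tests verify.

Mitochondrial genes (default 10, `MT-1`…) share a fixed expected fraction
of the library (default 5%). With all plantings switched off (flat
programs, unit dispersion multipliers, no link, zero focal amplitude) the
generator is an exact group-null: per-gene group-ANOVA p-values are
uniform, which the suite checks by a KS test.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, cell-type compositional shifts across groups, or the count depth and
cell numbers of any real atlas. Passing recovery tests on it demonstrates
that the estimators measure what they claim under the stated generative
model — not that any particular biological dataset satisfies that model.

# Group statistics for cohort tables

`check_assumptions` implements the usual two-group decision tree:
Shapiro-Wilk normality per sample, a Variance Ratio test
(F = larger/smaller variance, two-sided p from the F distribution), then
pooled t when both samples are normal with homogeneous variances, Welch t
when normal with unequal variances, Mann-Whitney otherwise. Constant
samples (Shapiro-Wilk undefined) route to Mann-Whitney with a warning.

`two_sample_t_from_summary` reconstructs the two-sided t-test exactly from
printed (mean, SD, n) pairs — pooled by default, since published cohort
tables typically footnote a plain "t-test"; the Welch variant is one flag
away and both agree to the printed precision on well-behaved tables.
Mann-Whitney rows of such tables are *not* reconstructible from medians
and IQRs, and the package does not pretend to: `mann_whitney_test`
requires raw samples (exact enumeration when both n ≤ 20 without ties,
normal approximation with tie correction otherwise).

The 2×2 chi-square uses the Yates continuity correction,
χ² = n(|ad−bc|−n/2)²/((a+b)(c+d)(a+c)(b+d)), algebraically identical to
summing (|O−E|−0.5)²/E over cells with the correction capped so
over-correction cannot flip a sign; a zero marginal returns p = 1 with a
warning.

`anova_dunnett` pairs the classical one-way ANOVA F with Dunnett
many-to-one comparisons. Adjusted p-values come from the null distribution
of max|T~j~| over the correlated comparison statistics, simulated by
seeded Monte Carlo (default 10^5 draws; group means ~ normal, pooled
variance ~ scaled χ²) rather than multivariate-t quadrature: simpler, with
accuracy that is controlled and reported (the MC standard error
accompanies each adjusted p, and adjusted p-values are floored at the
unadjusted ones). Large-scale FWER calibration runs in the test-suite use
3×10^4 draws per simulation, which bounds the per-p MC error near the 0.05
threshold at about 0.0013 — negligible against the ±0.02 calibration band.

# Problem sizes and numerical choices

Simulation-based checks in the tests and the acceptance script use these
sizes, chosen to give each property clear statistical resolution: noise
ordering, 100 datasets of 1,000 genes × 1,000 cells (200 per group, κ = 2
in T5); score null calibration, 50 random 50-gene sets on one null
dataset of 2,000 genes; planted-program sign recovery, 20 datasets;
module recovery, 600 trajectories (100 per pattern, noise σ = 0.3 added
directly in z space — z-scoring a flat noisy count trajectory would yield
an isotropic direction no clustering could group, so the flat cluster is
planted as a zero prototype plus noise); null FDR, 100 datasets of 500
genes with 200 cells per compared group; gated-correlation recovery, 100
datasets of 2,000 genes with ~1,000 gated cells; Dunnett FWER, 2,000
4-group null experiments. Tolerances: membership rows sum to 1 within
1e−9; BH agrees with brute force within 1e−12; convergence of c-means at
relative objective change 1e−6 with a 500-iteration cap; ties in
abundance ranking break by input order.

# Known limitations

* The noise statistic conflates any unmodeled within-stratum heterogeneity
  (subtypes, cell-cycle phase) with "noise"; on real data the stratum
  definition matters and both grouping modes should be compared.
* Module scores inherit the binning resolution: gene sets concentrated in
  one extreme abundance bin get poorly matched controls (the fallback
  warns).
* The t approximation for gated correlations ignores the gating-induced
  selection; planted-truth recovery shows the estimate itself is unbiased
  for the gated-population correlation, but p-values near the gate are
  approximate.
* Summary-statistics t-tests can only reproduce what (mean, SD, n)
  determine; any row computed by rank tests needs raw data.
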