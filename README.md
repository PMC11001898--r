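# lungspan

Analysis toolkit for single-cell RNA-seq studies of organ development and
aging that compare five ordered life-stage groups `T1 < T2 < ... < T5`
(development through aging adulthood). It is written for the computational
biologist who has already aligned, integrated and annotated an atlas and now
needs the downstream, study-specific statistics:

* **Transcriptional noise** — per-cell Euclidean distance to a reference
  expression profile in log-normalized space; either the cell-type centroid
  (optionally per group, so age shifts in the mean don't masquerade as
  noise) or the all-cell mean over a low-variability "invariant" gene set
  selected evenly across 10 abundance bins.
* **Signature (module) scores** — for cell *i* and gene set *G*<sub>j</sub>:
  `SC_j(i) = avg(Er(G_j, i)) − avg(Er(G_j^cont, i))`, where the control set
  `G_j^cont` is drawn at random from 25 expression bins to match the
  target's abundance distribution (100 controls per gene).
* **Time-course co-expression modules** — per-group pseudobulk means,
  z-scored per gene, clustered by fuzzy c-means (k = 6, m = 2, seeded
  restarts), with trend labels (`development_up`, `t3_peak`, `aging_down`,
  `flat`) assigned to module centroids.
* **Differential expression** — per-gene Welch t-test on log-normalized
  values with detection/fold-change pre-filters and Benjamini-Hochberg FDR,
  plus intersection of significant up-regulated genes with user-supplied
  disease gene lists.
* **Score-gated correlation** — Pearson correlation between a gene's
  expression and signature scores over T4/T5 cells whose scores all exceed
  0.01.
* **Cohort statistics** — the two-group decision tree (Shapiro-Wilk →
  pooled/Welch t or Mann-Whitney), exact reconstruction of two-sample
  t-tests from printed mean ± SD and n, Yates-corrected 2×2 chi-square, and
  one-way ANOVA with Monte-Carlo Dunnett many-to-one comparisons.
* **A synthetic-data generator** — negative-binomial counts with lognormal
  library sizes, marker-gene blocks, planted temporal programs, aging
  implemented as T5 dispersion inflation, and an FTL-like focal gene whose
  expression is latently linked to a planted signature score at a
  configured gated correlation. Ground truth is returned for every planted
  structure, so each estimator is validated by parameter recovery.

Inputs are the standard plain-text formats: Matrix Market counts with
gene/barcode TSVs, a cell-metadata TSV (`cell`, `sample`, `group`,
`cell_type`), GMT or two-column CSV gene sets, and one-gene-per-line
disease lists (e.g. DisGeNET exports such as Pulmonary Hypertension
C0020542, Emphysema C0034067, COPD C0024117, Asthma C0004096).

## Worked example

```r
library(lungspan)

sim  <- simulate_dataset(simulation_config(n_genes = 1000, seed = 1))
qc   <- qc_filter(sim$counts, sim$annotation)
norm <- normalize_cp10k(qc$counts)

summarize_noise(noise_to_celltype_mean(norm, qc$annotation))
#>  cell_type group   n   q1 median   q3
#>        AT2    T1  98 26.0   28.1 30.0
#>        AT2    T2 104 23.9   25.9 28.3
#>        AT2    T3 107 22.8   25.0 27.9
#>        AT2    T4 122 23.3   25.4 28.4
#>        AT2    T5 107 26.3   27.7 30.2
```

The T5 median (27.7) exceeds the T4 median (25.4): the generator draws T5
counts with doubled negative-binomial dispersion, and the estimator reads
that back as increased transcriptional noise in the aging group (the
T1-T3 medians also reflect the planted developmental programs, which shift
expression levels and with them per-gene variability).

```r
a   <- assign_control_genes(norm, sim$truth$signature_genes, seed = 2)
sc  <- module_score(norm, sim$truth$signature_genes, a)
score_gene_correlation(norm, qc$annotation, "FTL", list(signature = sc))
#>  gene score_name     r       p n_cells
#>   FTL  signature 0.745 7.2e-40     218
```

218 of the T4/T5 cells pass the score gate (> 0.01) and the focal gene's
expression correlates with the planted signature score at r = 0.745 on
them (the configured target for this generator is r = 0.8 on ~1,000 gated
cells; at 218 cells the estimate is within sampling error).

```r
two_sample_t_from_summary(summary_stats(3.17, 0.58, 18),
                          summary_stats(2.50, 0.64, 16))
#> t_pooled: statistic = 3.203, df = 32, p = 0.003075
```

This reconstructs a pooled two-sample t-test exactly from a published
mean ± SD / n summary — here a forced-vital-capacity comparison between
18 non-aging and 16 aging adults, giving p = 0.003.

A YAML-driven pipeline runs all stages in one call and writes TSV outputs
plus a run manifest with per-stage output hashes:

```sh
Rscript inst/cli/lungspan.R run --config inst/extdata/demo_config.yaml
```

## Repository layout

* `R/` — implementation; `man/` pages are generated from the roxygen
  comments.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
* `vignettes/lungspan-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, generator design and known limitations.
* `inst/cli/lungspan.R` — thin command-line wrapper
  (`simulate|qc|noise|score|tca|deg|stats|correlate|run`).
* `inst/extdata/` — demo configuration and example gene sets.
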