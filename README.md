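# abatime

Tools for analysing the early transcriptome response of the moss
*Physcomitrella patens* to the stress hormone abscisic acid (ABA). ABA
triggers protonema cells to differentiate into thick-walled vegetative
diaspores (brachycytes); the decision is made within the first three hours,
so the interesting signal sits in a short two-condition time course
(treated vs mock control at 30, 60 and 180 min, three replicates each,
normalized log2 microarray intensities). The package is aimed at anyone who
wants to re-run, audit, or stress-test this style of analysis on their own
matrices or on fully synthetic data with known truth.

Five statistical components, each exposed as plain R functions:

- **Pairwise DEG calling** — Bayesian-regularized t-test (Cyber-T style):
  gene variances shrunk toward a sliding-window background variance of
  expression-rank neighbours, `s̃² = (ν₀·bg + (n−1)s²)/(ν₀ + n − 2)`,
  `df = n_T + n_C − 2 + 2ν₀`, Benjamini–Hochberg FDR at q ≤ 0.05, signed
  reciprocal fold changes, and temporal classification of the call patterns
  (early sustained / early transient / mid transient / mid sustained /
  late up / late down).
- **Time-course ANOVA** — per gene, nested polynomial fits (one shared
  curve vs one curve per condition), F-test
  `F = ((RSS_red − RSS_full)/Δdf) / (RSS_full/df_full)`, Storey q-values,
  calls at q < 0.001.
- **Global subset dynamics** — genes ranked by temporal response variance;
  windows of 50–500 genes compared with the whole transcriptome by the
  Euclidean distance over paired Pearson-correlation and (normalized)
  mutual-information entries of their association profiles; plus sample
  PCA.
- **Set comparison** — exact Venn/UpSet partitions, cross-study overlap
  tables, single-best-hit ortholog collapse, condition-specific expression
  filtering, and summary-statistics t-tests for morphometry claims.
- **Enrichment** — two-sided Fisher's exact test per term with Bonferroni
  correction against a declared background.

A synthetic-data module generates the full design with planted response
archetypes and gene-specific noise, so every stage is testable offline, and
the package ships the published summary tables of cell-wall, ABA-pathway
and early-induced genes as plain-text fixtures.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a seeded
2,000-gene simulation (70% null genes; log2 effects of ±2 on the planted
archetypes; noise SD ≈ 0.25):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_timecourse.R
Rscript analysis/04_dynamics.R
Rscript analysis/05_tables_and_comparisons.R
Rscript analysis/06_enrichment.R
```

`02_differential_expression.R` prints

```
 30 min: 204 DEGs (202 up, 2 down)
 60 min: 411 DEGs (407 up, 4 down)
180 min: 429 DEGs (364 up, 65 down)
sensitivity at planted cells: 1.000; empirical FDR: 0.023
```

— the per-timepoint call counts track the planted archetype design
(200/400/400 truly responsive genes at 30/60/180 min), every planted
(gene, timepoint) effect is recovered, and the fraction of false calls
stays under the nominal q ≤ 0.05. `03_timecourse.R` reports the nested
polynomial ANOVA (`genes called at q < 0.001: 580 of 2000`, sensitivity
0.965, precision 0.998), `04_dynamics.R` the PCA separation of treated vs
control along PC1 and the subset distance curve, `05` the published-table
classifications (14 early-sustained + 2 early-transient of the 16 early
ABA-induced genes; the two responsive NCED genes; the 43% cell-wall
thickening, Welch t = 3.90, p ≈ 0.001), and `06` the recovery of the
planted archetype terms by Fisher/Bonferroni enrichment.

The same machinery in a session:

```r
library(abatime)
sim  <- generate_timecourse(sim_config(n_genes = 2000, seed = 1))
degs <- call_degs(sim$matrix, q_cutoff = 0.05)
table(degs$temporal_class)
tc   <- call_timecourse(sim$matrix, q_cutoff = 0.001)
sum(tc$called)
```

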