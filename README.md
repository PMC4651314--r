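# difcore

Differential co-expression network analysis with k-core hub ranking for
two-condition RNA-seq studies with few replicates.

## The problem

Comparing a "case" and a "control" transcriptome (the motivating design is
gonad tissue from fertile vs sterile double-haploid fish, 3 biological
replicates each) involves more than a differential-expression list. Genes
that drive a phenotype often change their *position in the co-expression
network* between conditions, not just their mean expression. `difcore`
implements that full workflow as composable, tested R functions:

1. **Read filtering** — discard reads with > 5 % ambiguous bases (`N`) or
   > 30 % of bases below Phred Q20 (strict inequalities), with
   base-retention statistics.
2. **Differential expression** — median-of-ratios size factors
   `s_j = median_g (k_gj / (∏_j k_gj)^{1/m})`, a fitted mean–dispersion
   trend `α(μ) = a₀ + a₁/μ` over method-of-moments estimates, and an exact
   conditioned negative-binomial test: conditional on a gene's total count
   `K`, the two-sided p-value sums the probabilities of all splits of `K`
   between the group-pooled counts (each `NB(μ·S_group, α·Σs²/S²)`) no more
   probable than the observed split. Genes are selected by fold change > 2
   or < 0.5 and Benjamini–Hochberg FDR < 0.05.
3. **Enrichment** — one-sided Fisher's exact (hypergeometric
   over-representation) tests of GO/pathway terms, run separately on up-
   and down-regulated genes, FDR-adjusted within each category.
4. **Co-expression networks** — per-condition Pearson correlation over a
   selected gene panel; edges by `|r|` threshold (default 0.95) or BH FDR.
5. **Hub ranking** — degree centrality, k-core decomposition
   (Batagelj–Zaveršnik bucket algorithm), and the differential k-core
   statistic

   `dif_kcore(g) = kcore_F(g) − kcore_S(g)`,

   which is strongly negative for genes that gained network centrality in
   the case condition.
6. **qPCR validation** — 2^−ΔΔCt relative quantification
   (`ΔΔCt = (Ct_target − Ct_ref)_case − (Ct_target − Ct_ref)_calibrator`)
   and sign-concordance against the RNA-seq fold changes.

A synthetic-data module (`sim_config()`, `simulate_counts()`,
`simulate_annotations()`, `simulate_fastq()`, `simulate_qpcr()`) generates
every input with known ground truth — planted fold changes,
copula-injected co-expression blocks, planted enriched terms — so the whole
pipeline is testable offline.

## Worked example

```r
library(difcore)

cfg <- sim_config(n_genes = 400, de_fraction = 0.15, lfc_values = c(-2.5, 2.5),
                  n_terms = 40, enriched_term_fraction = 0.1,
                  block_spec = list(list(size = 8, rho = 0.95, condition = "S")),
                  seed = 1)
res <- run_pipeline(pipeline_config(tempfile("difcore_"), simulate = cfg,
                                    n_network_genes = 40))
res$de_selected[c("n_up", "n_down", "n_total")]
head(res$kcore_table, 5)
```

prints

```
DE: 26 up, 33 down, 59 total

   gene degree_f kcore_f degree_s kcore_s dif_kcore direction
1 g0321        3       3       10       8        -5        up
2 g0181        4       3       10       7        -4      down
3 g0150        7       5       13       8        -3      down
4 g0162        7       5       11       8        -3      down
5 g0260        5       4        9       7        -3      down
```

59 of the 60 planted DE genes pass the fold-change/FDR filter, and the top
of the dif-k-core ranking is dominated by members of the 8-gene block that
was planted to be co-expressed only in condition S: they hold k-core 7–8 in
the sterile network against 3–5 in the fertile one. The planted enriched
terms lead the enrichment tables (`res$enrichment$up`, q < 1e-6), and the
synthetic qPCR panel is 100 % sign-concordant with the RNA-seq fold changes
(Pearson r = 0.98).

The 18-gene hub table from the motivating study ships as a plain-text
fixture (`published_hub_genes()`) and is used as a regression test of the
dif-k-core identity.

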