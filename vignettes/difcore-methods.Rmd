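---
title: "Methods: differential co-expression networks and the dif-k-core statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression networks and the dif-k-core statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`difcore` implements a two-condition transcriptome comparison for small
replicated designs — the motivating study compared gonads of fertile ("F")
and sterile ("S") double-haploid Japanese flounder, three biological
replicates per condition — ending in a differential network-centrality
ranking of candidate hub genes. This vignette explains each model, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data module does and does not emulate.

## Read filtering

A read is discarded iff strictly more than `max_n_frac` (default 0.05) of
its bases are ambiguous (`N`/`n`), or strictly more than `max_lowq_frac`
(default 0.30) of its bases have Phred quality below `min_q` (default 20,
Phred+33). Both comparisons are strict, so a 100-bp read with exactly 5 Ns
and exactly 30 bases at Q19 is retained. Filtering is per-read, hence
order-invariant and idempotent. Adapter trimming is out of scope: it
requires the library kit's adapter sequences, which are not part of the
data model; the filter assumes adapter-free input. Retention is reported as
`100 · bases_after / bases_before`, rounded half-up to two decimals, the
convention of sequencing-run summary tables. Other IUPAC ambiguity codes
are deliberately counted as ordinary bases — only `N` is treated as
ambiguous.

## Differential expression

**Normalisation.** Median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_g \, k_{gj} / (\prod_{j'} k_{gj'})^{1/m}$, the
median taken over genes whose geometric mean is positive. This is robust
to a modest DE fraction and is the standard for count data.

**Dispersion.** Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. The gene-wise method-of-moments estimate is
$\hat\alpha_g = (v_g - \hat\mu_g \overline{1/s}) / \hat\mu_g^2$ with $v_g$
the pooled within-condition variance of normalised counts (the
$\hat\mu_g \overline{1/s}$ term removes shot noise). With three replicates
per group this estimator is extremely noisy — roughly half the genes land
at or below zero — and plugging it into the test directly makes the test
strongly anti-conservative, because underdispersed-looking genes are
treated as Poisson. The default therefore shares information across genes:
the *unfloored* gene-wise estimates are regressed on $1/\mu$ (parametric
mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$, the classical NB
variance-function shape) and each gene receives the fitted value, floored
at 0. On a 2,000-gene null simulation at the study's scale the gene-wise
plug-in rejects at 0.114 at nominal 0.05, the trend fit at 0.0545 (inside
the 99 % binomial interval), and the more conservative
max(gene-wise, trend) rule at 0.032; all three are exposed via
`estimate_dispersion(method = )`, with `"trend"` the default.

**Test.** An exact conditioned two-group test. For gene $g$ let $K_A, K_B$
be the group-pooled counts and $K = K_A + K_B$. Group-pooled counts are
modelled as NB with mean $\hat\mu_g S_A$ ($S_A = \sum_{j \in A} s_j$) and
dispersion $\alpha_A = \alpha_g \sum_{j\in A} s_j^2 / S_A^2$. The
dispersion scaling is moment-matched: a sum of $n$ iid NB($\mu, \alpha$)
variables is NB($n\mu, \alpha/n$), and the general form reproduces the
variance $\sum_j (\mu s_j + \alpha \mu^2 s_j^2)$; carrying $\alpha$ over
to the group sum unscaled would inflate the group variance roughly
$n$-fold and destroy calibration. Conditional on $K$, the two-sided
p-value sums the probabilities of all splits $a + (K - a) = K$ whose joint
probability does not exceed that of the observed split (with a $1 +
10^{-7}$ relative tolerance for ties). Enumeration is exact and vectorised
up to a total of `approx_total` (default 10,000); above that, the
conditional law is approximated as normal with mean
$\mu_A + (K - \mu_A - \mu_B)\,v_A/(v_A+v_B)$ and variance
$v_A v_B/(v_A+v_B)$.

One stated invariance deserves a caveat: multiplying one sample's counts
and its size factor by $c$ leaves every *normalised* quantity — means,
fold changes, dispersions — exactly unchanged, but not the p-values of any
count-based conditioned test, because the scaled sample's realised
deviation enters the conditioning total with a different weight than its
variance. Rescaling the whole matrix and all factors together changes
p-values only through discretisation (measured max $|\Delta p| \approx
0.014$).

**Selection.** Fold change is $(\bar q_S + 0.5)/(\bar q_F + 0.5)$ on
normalised means — the 0.5 pseudocount keeps zero-expressed genes finite
and makes the label-swap symmetry $FC \mapsto 1/FC$ exact. "Up" means
higher in the sterile-style (non-reference) condition. Selection uses the
strict rules fold change > 2 or < 0.5 and BH FDR < 0.05; there is no
independent mean-count prefilter. The fold-change sign convention is fixed
here once (case over control) because published tables in this area are
not always internally consistent about it.

## Enrichment

One-sided over-representation only: $p = P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$, computed by `phyper`. The universe
is the intersection of annotated genes and the count matrix. FDR families
are per category (BP/MF/CC/pathway) per direction, matching the practice
of reporting separate GO and pathway significance lists; up- and
down-regulated genes are tested as independent runs. Terms with fewer
than `min_term_size = 2` universe genes are skipped. A two-sided test is
deliberately not offered: depletion of a term in a small DE set carries
almost no information at these sizes.

## Co-expression networks and dif-k-core

Expression is $\log_2(k_{gj}/s_j + 1)$ (transform optional). Pearson
correlations are computed per condition from that condition's samples
only — two graphs are required to compare centralities. P-values use the
$t$ transform with $n - 2$ df; pairs at $|r| = 1$ (within $10^{-10}$) are
assigned $p = 0$, and constant genes are dropped with a warning.

Two edge rules are provided. `mode = "fdr"` keeps pairs with BH-adjusted
correlation $q$ below the cutoff — the rule stated for the original
analysis. With $n = 3$ samples per condition, however, the correlation
$t$-test has 1 df and FDR < 0.05 is essentially unattainable, so the
study-scale default is `mode = "abs_r"` with cutoff 0.95. Edges keep
signed $r$; thresholding always uses $|r|$. The construction metadata
(mode, cutoff) is stored in the graph and its edge-list output.

Degree is the number of incident edges. Core numbers come from the
linear-time bucket (Batagelj–Zaveršnik) peeling algorithm; the test suite
checks it against a brute-force iterative-peeling oracle and against
`igraph::coreness()`. The ranking statistic is

$$\mathrm{dif\mbox{-}k\mbox{-}core}(g) = \mathrm{kcore}_F(g) - \mathrm{kcore}_S(g),$$

with genes missing from one condition's graph scored (degree 0, core 0)
there rather than dropped — the published hub table itself contains a gene
with fertile degree 0. Rows are ordered by ascending dif-k-core (largest
sterile-side centrality gain first), ties broken by descending sterile
degree then gene id, for deterministic output. The sign convention
(fertile minus sterile) was fixed by verifying it against all rows of the
published 18-gene table; 17 of 18 printed values satisfy it exactly, and
the remaining row (CXCR3) prints its *degree* difference instead — pinned
as a known inconsistency in the regression test rather than silently
"corrected".

## qPCR

Standard comparative Ct: replicate Ct values are averaged arithmetically
per (gene, condition) before differencing (never averaged as folds), then
$\Delta Ct = Ct_{target} - Ct_{ref}$, $\Delta\Delta Ct = \Delta Ct_{test}
- \Delta Ct_{calibrator}$, fold $= 2^{-\Delta\Delta Ct}$. Amplification
efficiency is fixed at 2, as the method assumes. Two exact invariances are
tested: a constant plate shift on every Ct cancels, and swapping
calibrator and test negates $\Delta\Delta Ct$. Concordance with RNA-seq is
per-gene sign agreement of the two log2 fold changes plus their Pearson
correlation across the panel.

## The synthetic-data module

`simulate_counts()` draws NB counts via a latent-uniform quantile map:
every gene/sample cell has a uniform $u_{gj}$, and counts are
$F^{-1}_{NB(\mu_{gj}, \alpha)}(u_{gj})$. Co-expression blocks replace the
independent uniforms, within the block's condition only, by
$\Phi(z)$ for equicorrelated multivariate normal $z$ (correlation $\rho$,
Cholesky of the compound-symmetry matrix). This Gaussian copula leaves
every marginal count law untouched while controlling within-condition
gene–gene correlation — chosen because it decouples margins from
dependence, which no direct NB construction does. Defaults mirror the
motivating design: 2 × 3 replicates, dispersion 0.1, baselines drawn
log-uniformly in [20, 500], symmetric planted log2 fold changes ±2, and a
network stage on a ~72-gene panel. Library-size variation is exposed as a
log-uniform size-factor range, default [0.8, 1.25] (modest, typical of a
single-platform experiment; the study reports none, so it is a parameter
rather than an assumption).

What the generator does *not* emulate: mappable read sequences, assembly
artefacts, GC/length biases, correlated library-preparation batch effects,
annotation incompleteness, or heavy-tailed dispersion across genes
(a single $\alpha$ is used unless varied by the caller). Passing
recovery tests therefore demonstrate correctness of the statistics under
the stated model, not robustness to every artefact of real libraries.

Two test-design notes. First, under a true null the discrete
hypergeometric p-values are *super*-uniform, so uniformity of the
enrichment nulls is checked with a one-sided Kolmogorov–Smirnov statistic
against the anti-conservative direction (the substantive claim), not a
two-sided KS, which rejects discreteness itself. Second, with 3 samples
the null Pearson $|r|$ exceeds 0.9 about 29 % of the time (1 df), so
planted-block recovery properties are exercised at 10 samples per
condition, where the inside/outside edge-density contrast (measured
0.96 vs 0.00 at $|r| \ge 0.9$) is informative; study-scale defaults are
unchanged.

## Problem sizes and determinism

All simulation-based tests run at 2,000 genes or fewer (10,000 for
moment-level checks), sizes at which the exact test enumerates totals
directly and the full suite completes in seconds. Every generator takes an
explicit integer seed and is byte-deterministic given it;
`run_pipeline()` writes a JSON manifest with thresholds, the seed, row
counts and md5 checksums of all tabular outputs, and a rerun with the same
configuration reproduces the checksums exactly.

## Known limitations

* No multi-factor or covariate-adjusted designs; exactly two conditions.
* No shrinkage of log fold changes; small-count fold changes are stabilised
  only by the 0.5 pseudocount.
* No GO DAG propagation or pathway topology; terms are flat gene sets.
* No module detection or soft-thresholding (WGCNA-style) in the network
  stage; the gene panel is user-supplied or taken from the top DE genes.
* qPCR efficiency correction (standard-curve calibration) is out of scope.
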