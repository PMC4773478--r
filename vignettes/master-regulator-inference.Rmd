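---
title: "Inferring Polycomb-silenced master regulators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Polycomb-silenced master regulators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimr)
```

# The model

`epimr` addresses a recurring design in cancer epigenomics: an *origin*
cell population (e.g. tumour-initiating astrocytes) and the
*tumour*-derived cells it gives rise to are profiled by RNA-seq and by
ChIP-seq for the repressive Polycomb mark H3K27me3. The hypothesis is
that a small number of transcription factors, silenced by de novo
H3K27me3 deposition at their promoters, indirectly drive a large part of
the transcriptional change. A candidate *master regulator* must
therefore satisfy three independent conditions simultaneously:

* its binding motif is over-represented in the promoters of the
  differentially expressed genes (DEGs) of the transition;
* its own gene is significantly downregulated in tumour;
* its own promoter acquires H3K27me3 de novo (marked in every tumour
  sample, unmarked in every origin sample).

Each condition is computed by a separate module and intersected by
`rank_master_regulators()`. Requiring the conjunction keeps the false
discovery rate of the shortlist far below that of any single signal.

# Stage-by-stage methods

## Differential expression

Counts are modelled per gene as negative binomial. Normalization uses
the median-of-ratios estimator: for sample $j$,
$s_j = \mathrm{median}_g \, k_{gj} / (\prod_{j'} k_{gj'})^{1/m}$ over
genes expressed in all samples. The estimator is reported raw (its
geometric structure, not its absolute level, is what matters; only
ratios of size factors enter the test).

Dispersion is estimated by method of moments on normalized counts,
pooled within groups, and shrunk toward a $a_0 + a_1/\mu$ trend fitted
across genes. With the 3-vs-3 replicate structure this package targets,
per-gene residual degrees of freedom are tiny (4), so the shrinkage
weight (`prior_df`, default 6) contributes about 60% trend. The Wald
statistic is the log2 fold change of (pseudocount-shifted) normalized
group means over its delta-method standard error, referred to the
standard normal. We verified the choice of reference distribution by
simulation under the null: the normal reference gives an empirical
type-I error of about 0.055 at nominal 0.05, whereas a $t_{n_1+n_2-2}$
reference is far too conservative (about 0.008), which would defeat the
null-calibration property the package promises. P-values are BH-adjusted
and a gene is a DEG when $q \le \alpha$ (default 0.05) and
$|\mathrm{log2FC}| \ge$ `lfc_min` (default 0; the classic analyses this
mirrors print no fold-change cutoff).

## H3K27me3 quantification and target calling

Coverage is averaged in 100-bp bins across a 6-kb window centred on the
TSS (3 kb upstream, 3 kb downstream), with minus-strand genes' bins
reversed so that negative coordinates are always biologically upstream.
Windows that run off the covered coordinate space are trimmed to `NA`
and excluded from downstream means. Genomic intervals are handled
half-open and 0-based at the BED boundary; the TSS of a minus-strand
gene is the interval end.

Per-sample target calling compares the summed window count $x$ with the
control window count $c$ under the two-Poisson model with known library
ratio: conditional on $x + c$, $x$ is binomial with success probability
$t_s/(t_s + t_c)$, giving an exact one-sided enrichment p-value (the
conditional form of the Poisson rate comparison, as in
`stats::poisson.test`). We deliberately did not treat the control sum as
a *known* Poisson mean: the control is itself a noisy count, and
plugging it in doubles the null variance (analytically about 12% type-I
error at nominal 5%). The whole-window sum, rather than a per-bin
maximum, is the default statistic because H3K27me3 is a broad mark; a
per-bin mode with Bonferroni correction over bins is available.

De novo targets use the strictest reading of "consistently acquired":
marked in **every** tumour sample and in **no** origin sample
(intersection minus union). The output is therefore monotonically
non-increasing as tumour samples are added, a property the tests assert.

## Spatial pattern classification

Marked genes fall into three spatial classes: TSS-centred (both flanks
enriched with a sharp dip at the TSS itself), upstream-skewed, and
downstream-skewed. With $U$ and $D$ the mean densities over the upstream
and downstream flank, a gene is UP/DOWN when $|\log_2(U/D)| \ge 1$ and
TSS otherwise. The 2-fold threshold is the smallest interpretable
asymmetry; it is exposed as a parameter. Classes are compared on
expression change with the two-sided Mann-Whitney test, implemented with
an exact midrank-tie null (dynamic programming over doubled midranks)
when both classes have at most 12 members, and the tie-corrected normal
approximation otherwise.

## Promoter motif enrichment

PWMs are parsed from JASPAR PFM text; each frequency cell receives a
pseudocount of 0.01 before renormalization, and scores are natural-log
odds against a uniform background (both configurable). A promoter's
score for a motif is the best log-odds sum over all offsets and both
strands, min-max normalized to $[0,1]$ by the motif's best and worst
possible site scores. Enrichment of a foreground gene set is the
population z-test used by promoter-scanning tools: the full promoter
universe is the population, so
$z = (\bar{x}_{fg} - \mu_{bg}) / (\sigma_{bg}/\sqrt{n_{fg}})$ with the
population (denominator $N$) standard deviation, one-sided upper
p-values, and Bonferroni correction across motifs. Sampling the
foreground without replacement makes the test slightly conservative
(finite-population correction is not applied), which is the safe
direction for a discovery screen. The default promoter window for real
data is 500 bp (the synthetic generator's default promoter length);
the scanning window is wholly determined by the supplied FASTA.

## Integration and ranking

`rank_master_regulators()` keeps the motif-enriched TFs
(Bonferroni p < α), maps each motif to the TF's own gene through an
explicit two-column table (no fuzzy name matching), joins the DE
statistics and the de novo status, and sorts by DE q ascending, then
absolute log2 fold change descending, then gene id (a documented,
deterministic tie-break). The shortlist rule is the conjunction above.
The universe for all overlap statistics is the set of genes present in
both the annotation and the expression matrix.

## Co-expression, GSEA, retention

Co-expression neighborhoods are Pearson correlations against a focal
gene across an expression compendium; "high confidence" defaults to
$|r| \ge 0.5$ (a `top_k` alternative is exposed) — the compendium scale
this mirrors (about 106 profiles) makes $|r| \ge 0.5$ a stringent
threshold (null tail probability below $10^{-7}$).

GSEA uses the weighted Kolmogorov-Smirnov running sum: hits increment by
$|s|^w$ (normalized over set members), misses decrement by $1/(N-|S|)$;
the enrichment score is the signed maximum deviation, with the positive
peak winning a magnitude tie. Because the designs here have three
replicates per arm, the permutation null is over **gene labels**, not
samples; the nominal p uses the add-one correction
$(1 + \#\{|ES_\pi| \ge |ES|\})/(n_{perm}+1)$ and is bit-reproducible
given `(n_perm, seed)`.

Cluster retention asks what fraction of a batch-specific gene cluster
keeps its expression status in the matched tumour. "Retained" means the
gene is on the same side of the `quantile_threshold` (default median) in
tumour as in the batch; the null re-draws size-matched random gene sets
(`n_shuffles`, default 1000) and yields a z-score and add-one empirical
p. The original analyses' exact retention statistic lives in
supplementary material we do not reproduce; this operationalization is
our own and is stated as such.

## Survival

Patients are stratified by focal-gene expression fold change against the
cohort median: HIGH above `high_fc` (default 2), LOW below `low_fc`
(default 0.5), MID otherwise, with boundaries falling in MID. The
published text this mirrors prints "low (f.c.<2)", which cannot coexist
with a three-group split; since three groups plainly exist, we read LOW
as the mirror cutoff 0.5 and expose both thresholds. Kaplan-Meier
curves and the log-rank (Mantel-Cox) test are delegated to the
`survival` package (`survfit`/`survdiff`) behind the module interface —
they are textbook estimators, not this package's contribution — and are
validated in the tests against hand-computed product limits, the
explicit $O-E/V$ worked example, a full permutation oracle, and type-I /
power simulations.

# The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, with one seed determining every output byte:

* **Genome**: genes on one synthetic chromosome with non-overlapping
  6-kb TSS windows; promoters i.i.d. from a configurable base
  composition (uniform ACGT by default — the simplest null for motif
  scoring).
* **Counts**: negative binomial with log-normal baselines
  (meanlog = log 100, sdlog = 1), dispersion 0.05, and planted log2 fold
  changes applied in the tumour condition; 3 replicates per condition by
  default.
* **ChIP**: independent Poisson per bin (background 10 reads/bin),
  enriched bins multiplied by `enrichment_factor` (default 8) according
  to the gene's spatial class; the TSS class holds exactly the two
  central bins at background — the operational form of the sharp dip at
  the TSS. The control track is pure background. Read-level simulation,
  fragment-size effects and batch effects are deliberately out of scope.
* **Survival**: exponential event times per group (one parameter, so
  closed-form oracles exist) with independent uniform censoring whose
  upper bound is solved numerically to hit the requested censoring
  fraction.
* **Planted regulator** (`plant_master_regulator()`): 100 genes down and
  100 up at |log2FC| = 2; the regulator's 8-bp information-rich motif
  (dominant base weight 0.85) planted twice in 70% of the
  downregulated promoters; tumour-only TSS-class marks on 60 of the
  downregulated genes including the regulator's own; 40 stably marked
  genes in both conditions. The regulator's own baseline expression is
  fixed at one log-sd above the typical gene: a master regulator is by
  definition an expressed TF in the origin cells, and a random low
  baseline would make any method's detection of its repression a coin
  flip at three replicates.

Sub-seeds for each output stream are derived from the design seed by a
fixed offset schedule, so partial re-runs reproduce the full run.

What passing tests on these data do **not** show: robustness to
GC-dependent coverage bias, fragment-length artefacts, correlated genes,
isoform complexity, batch confounding, or non-exponential hazards. The
generator validates the statistical machinery, not those data
pathologies.

# Problem sizes and determinism

The packaged tests and the acceptance script run the full pipeline at
1000 genes x 6 samples x 50 motifs (a few seconds per seed), 20-seed
end-to-end recovery, null calibrations with 300-500 simulated data sets
per caller (plus 1000-2000 cheap draws where a statistic can be
precomputed), and enumeration oracles over every universe size up to 60.
All Monte-Carlo stages take explicit seeds and record them in their
outputs; `run_pipeline()` writes a manifest with MD5 hashes of every
stage table, and identical configurations reproduce identical hashes.

# Known limitations

* The DE engine is a transparent single-estimator implementation chosen
  so that its operating characteristics are fully verifiable by
  simulation; it will not numerically reproduce the gene lists of any
  specific published tool chain.
* The Poisson window test has no local background; with only 6-kb
  windows and a genome-wide control this is adequate, but copy-number
  variation would confound it.
* The motif z-test inherits Pscan's population assumption; heavily
  skewed best-score distributions at very small foregrounds can deviate
  from nominal.
* `batch_specific_clusters()` falls back to a fold-change rule when a
  batch has fewer than 2 replicates, with a warning.
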