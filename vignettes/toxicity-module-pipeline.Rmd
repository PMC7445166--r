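---
title: "From germline genotypes to a toxicity module and a sparse prediction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From germline genotypes to a toxicity module and a sparse prediction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmod)
```

## The problem

Gemcitabine/carboplatin chemotherapy routinely suppresses bone-marrow
function: neutropenia, leukopenia and thrombocytopenia, graded 0-4 on the
CTCAE scale.  Roughly half of treated patients experience severe (grade
3-4) myelosuppression while others sail through, and germline genetic
variation is believed to drive much of that difference.  `toxmod`
implements an analysis chain that starts from bi-allelic germline
genotypes and per-patient CTCAE grades and produces

1. a **toxicity module** — a set of genes, found on a protein-protein
   interaction (PPI) network, that concentrates the genes to which
   toxicity-associated variants map, and
2. a **sparse prediction model** of maximal myelosuppressive toxicity,
   selected by a random-LASSO selection-frequency procedure over the
   variants that map into the module.

Patient-level whole-genome data of this kind cannot be shared, so the
package ships a synthetic-data generator with the statistical structure
the analysis assumes; every stage is testable against it.

## Stage by stage

### Variant QC

`qc_filter_variants()` keeps records that are labeled PASS, have a
genotyping rate ≥ 0.95, no called genotype with read depth < 5, and mean
depth across samples ≥ 10.  The depth rules read FORMAT/DP: the
per-genotype rule looks only at called genotypes, the mean-depth rule
averages over all samples.  Files without DP skip the depth rules with a
warning rather than failing.  Coordinates are 1-based inclusive
throughout the package; BED input is shifted at the boundary
(`read_gene_models()`), so no other code ever reasons about conventions.

### Allelic association

Cases are patients with CTCAE grade 3-4 for the phenotype under test,
controls grade 0-1; grade-2 intermediates are excluded.  Each called
sample contributes two alleles to a 2×2 table (missing genotypes
contribute none — they are *not* imputed for testing), and
`allelic_fisher()` computes the two-sided Fisher exact p-value as the sum
of hypergeometric probabilities of tables no more probable than the
observed one — the PLINK `--fisher` convention, with a `1e-7` relative
tolerance for probability ties and no mid-p.  The odds ratio is the
cross-product, with the Haldane-Anscombe +0.5 added to all four cells
only when some cell is zero, and only for reporting.  The nominal
threshold is *inclusive*: `p ≤ 1e-3`.

Monomorphic tables return p = 1 with a flag instead of an error: at
genome scale such variants are routine and must not abort a scan.

### Mapping variants to genes

Nominally significant autosomal variants are mapped to their nearest
protein-coding gene within 3,000,000 bp (`nearest_gene()`).  That radius
is unusually generous but deliberate — intergenic variants are the bulk
of the signal and should still anchor a gene.  Distance is 0 inside the
gene body, otherwise distance to the nearer boundary; ties go to the
smaller start coordinate, then lexicographic id, so runs are
deterministic.  `annotate_variants()` classifies each variant as
promoter (TSS ± 3 kb, strand aware), exon, intron or distal intergenic,
in that priority order.  Sex-chromosome variants are tested but excluded
from seeding (`autosomal()`).

### MCODE on the PPI network

The network is a STRING-style weighted edge list; only combined scores
*strictly* above 700 (high confidence) are loaded.  Scores are not used
further: module detection is purely topological.

`mcode_vertex_weights()` implements the classic vertex weighting: for
each vertex, take the subgraph induced by its closed neighborhood, find
its highest k-core, and set `weight = k × density(core)`.
`mcode_find_complexes()` grows complexes greedily from the heaviest
unvisited vertex, admitting unvisited neighbors whose weight is at least
`(1 − vwp) ×` the seed weight (vertex weight percentage, default 0.5;
0.1 in validation mode to compensate for a weaker association sample).
Complexes without a 2-core are discarded (checked before haircut), then
the haircut iteratively removes degree-1 vertices.  Equal-weight seed
choices break lexicographically.

The overlay of association seeds onto the network is the main open
design point: we run MCODE on the *full* network and then keep the union
of complexes over-represented for seed genes (one-sided Fisher against
the network node universe, include when `p < 0.05`).  This reproduces
the signature of large modules containing a modest number of seeds,
which is what the analysis banks on; the alternative (cluster only the
seed-induced neighborhood) produces small seed-dominated clusters and
was rejected.

### The toxicity module

`toxicity_overlap()` intersects the three per-phenotype modules: genes
present in ≥ 2 of them (main analysis) or all 3 (validation analysis)
form the toxicity module, and the nominal variants mapping into it are
its *member variants* — the design matrix columns for prediction.

### Expression diagnostics

`tpm()` computes transcripts per million (columns sum to 1e6);
`expressed_set()` applies the strict `TPM > 1 in ≥ 2 samples` rule;
`expression_permutation()` draws `|module|` genes from the nonzero-count
background 10,000 times and reports the mean expressed count and an
empirical p-value with the +1 correction (it can never return 0).
`overlap_fisher()`, `fisher_method()`, `bonferroni()` and `ora()` cover
the enrichment arithmetic for external DEG lists and GMT collections;
multiple-testing style (Bonferroni vs BH) is an argument because the
upstream conventions mix both.

### Random-LASSO selection and the final model

With `y` = high/low maximal toxicity and `X` the member-variant dosages
(missing values mode-imputed — the only place genotypes are imputed),
`random_lasso_frequencies()` repeats, `n_perm` times:

* draw per-variant penalty multipliers from Normal(1, 0.25), truncated
  below at 0.01 — the "random" in random LASSO; without per-feature
  randomization the selected set would barely vary across repetitions;
* fit an L1-penalized logistic path (`alpha = 1`, 100 lambdas) with
  10-fold stratified cross-validation and take the deviance-minimizing
  penalty (`lambda.min`);
* increment the selection count of every variant with a nonzero
  coefficient there.

Rows are never resampled by default (a `row_subsample` switch exists);
the master seed spawns one seed per permutation, so the loop is
reproducible and shardable.  The full-scale default is 100,000
permutations; tests run 15-1000.

`quantile_sets()` turns frequencies into nested candidate sets: the
`q`-set keeps variants with frequency ≥ the empirical `q`-quantile
(type-7, ties included).  With distinct frequencies this yields the
familiar "50th percentile most selected" arithmetic — 62 of 123, 52 of
104.  With heavy ties (e.g. few permutations, many never-selected
variants) the rule degenerates gracefully toward larger sets; that is a
property of the stated rule, not a bug.

Each candidate set is refit with `refit_no_shrinkage()`: ridge
(`alpha = 0`) over a CV-selected penalty.  "No further shrinkage" is
read as *no further L1 selection* — every candidate variant keeps a
coefficient — not as an unpenalized fit; the ridge penalty also keeps
coefficients finite under complete separation, which perfect training
fits otherwise produce.  `evaluate_quantile_sets()` picks the set with
the best held-out AUC (ties: fewer variants, then higher training AUC);
`roc_auc()` is the Mann-Whitney statistic with half-credit ties.
Intermediates are scored by `predict_probability()` like anyone else but
never enter training or ROC computation.

### Train/validation split

`stratified_split()` withholds `floor(0.2 × n)` per high/low stratum;
intermediates go to a prediction-only pool.  On the stated 54/8/34
cohort this reproduces the 44/10, 0/8, 28/6 design exactly.  In main
mode the split happens after association (all samples test); in
validation mode the split comes first and association sees training
samples only — the two modes differ in exactly three knobs (split-first,
`min_overlap`, `vwp`), which a test asserts.

## The synthetic world

`sim_config()` defaults state the emulated cohort:

* 96 samples, maximal-toxicity classes exactly 54 high / 8 intermediate /
  34 low, enforced by *rank*-thresholding the liability (fixed cutoffs
  would make class counts random and every downstream test flaky);
* a few thousand bi-allelic variants, Hardy-Weinberg genotypes at MAFs
  uniform on [0.05, 0.5]; ~1% missing genotypes, ~2% of variants with
  poor call rate, non-PASS labels, or a low-depth genotype, so QC has
  work to do; ~2% on chrX to exercise the autosomal filter;
* 5 planted causal variants in distinct genes of one planted network
  module, liability = Σ log(OR)·dosage + standard logistic noise.
  Causal MAFs are drawn from [0.2, 0.5]: at n = 96 a rare planted
  signal has next to no allelic power at `p ≤ 1e-3`, and a benchmark
  whose ground truth is undetectable by design tests nothing;
* component-phenotype grades are the maximal grade minus a
  Bernoulli(0.3) single-grade decrement, with one phenotype per sample
  forced to attain the maximum.  A one-grade drop can demote a case to
  the excluded intermediate class but never into the controls, keeping
  the three phenotypes' case/control classes consistent with the shared
  liability while making them imperfectly correlated;
* a planted-partition PPI network: 50 module genes wired at p = 0.8 with
  scores in [701, 999], background pairs at p = 0.02 with scores in
  [150, 999] (so the >700 loader thins them further);
* negative-binomial expression for 3 cell lines × {untreated, drugA,
  drugB} × 2 replicates, dispersion 0.15, with 18 module genes shifted
  by 2 log2 units in a line-specific pattern (drugA acts in line 1,
  drugB in line 3), and ~10% near-silent genes so the expressed-gene
  filter bites.

It deliberately does **not** emulate linkage disequilibrium, population
stratification, relatedness, sex chromosomes beyond a token chrX share,
indel realism, or genome-scale variant counts.  Green tests therefore
establish that the machinery is correct and that planted signal of the
stated size is recovered — not that the pipeline's error rates on real
WGS cohorts are as advertised.

### A known red: perfect training separation

The source analysis reports training AUC = 1.0 for a model of 62
variants chosen from 123 member variants on 78 training samples.  That
perfect separation is a property of the regime `p ≈ 1.6 × n`: a ridge
fit with that many columns can interpolate the training labels.  The
member-variant count is itself a child of genome scale — thousands of
nominal variants (mostly chance at `p ≤ 1e-3` over 15.7 million loci)
rain onto the module's genes.  A desk-scale synthetic cohort with a few
thousand candidate variants and 5 causal ones yields ~5-8 member
variants, and the best linear score on 5 discrete dosages under logistic
liability noise tops out near AUC 0.94 in-sample (and exact ties across
classes forbid 1.0 even without noise).  Raising the causal count or
odds ratio does not help: each variant's marginal allelic power is
capped by the polygenic background of the others (the effect-to-noise
ratio saturates at `1/sqrt(0.4 (n_causal − 1))`).  The end-to-end
acceptance check therefore asserts the stated expectation faithfully and
is expected to stay red on its training-AUC clause; the held-out-AUC
clause and every other stage property are exercised on their own merits.

## Numerical choices

* Fisher two-sided p: probability-tie tolerance `1e-7` (relative),
  matching common exact-test practice; the test-suite oracle enumerates
  tables from binomial coefficients independently and agrees to `1e-9`.
* Quantile rule: `stats::quantile` type 7, ties included — reproduces
  62/123 and 52/104 under distinct frequencies.
* glmnet: binomial deviance as CV criterion, `lambda.min`; the selection
  loop relaxes the convergence threshold to `1e-5` (halves runtime, no
  observed effect on selected sets); ridge refits use `cv.glmnet`
  defaults.
* Mode imputation for design matrices keeps dosages in {0, 1, 2}; ties
  resolve to the smaller dosage.
* PCA scales variants to unit variance, drops monomorphic and >5%
  missing variants, mean-imputes the rest, and fixes component signs by
  making the largest-magnitude loading positive.
* All randomness flows from explicit seeds; per-permutation seeds are
  spawned from a master seed below 2^31.

## Limitations

Covariate adjustment, genomic-control inflation correction, LD-aware
modeling, multi-allelic decomposition and external-cohort transfer are
out of scope.  Enrichment odds ratios depend on the chosen universe;
where an upstream universe is unknowable the package computes the
arithmetic but makes no claim of reproducing published OR values.
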