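# ervrates

Context-dependent germline mutation-rate estimation from extremely rare
variants (ERVs), for population and statistical geneticists who want
per-context mutation rates, their quality control, and their validation
against de novo mutations — without waiting on cohort-scale raw data to
prototype any of it.

## The model

Singletons — variants seen exactly once in a cohort — are recent
mutations, nearly untouched by selection and GC-biased gene conversion.
For each mutation subtype, a substitution with its centered K-mer
context collapsed so the central reference base is A or C (K ∈ {1, 3,
5, 7}; 6·4^(K−1) subtypes), the **relative mutation rate** is

    rate = (# singletons of that subtype) / (# motif occurrences in the mappable genome)

a proportion, not a per-generation rate. Around this estimator the
package provides:

* **Taxonomy and counting** — canonical subtype folding, 1-bp
  sliding-window motif counts with N exclusion and an optional
  accessibility mask (central-base semantics).
* **Nested heterogeneity tests** — Pearson chi-squared on the 16×2
  table of each subtype's (K+2)-mer constituents, 15 df.
* **Sample QC** — per-individual 3-mer spectra, rank-3 non-negative
  matrix factorization, and a 2-SD signature-contribution outlier rule.
* **De novo validation** — logistic regression of the de novo indicator
  on the rate covariate, `logit Pr(d=1) = α₀ + α₁·r`; models ranked by
  AIC (= 2p − 2lnL with p = 1) and Nagelkerke's pseudo-R², with the
  three-way background partition (1M sites → 333,334/333,333/333,333)
  and 9-type CpG-aware stratification.
* **Feature effects** — per-7-mer-subtype multiple logistic regression
  of mutability on 11 binary + 3 continuous genomic features plus read
  depth (≥ 20 singletons per subtype; BH FDR 0.05 per feature), exact
  binomial enrichment tests, and de novo corroboration chi-squared
  tests.
* **Rate map** — per-site predicted probabilities for the three
  alternative alleles via the fitted subtype models (marginal-rate
  fallback near contig ends), exported as TSV/bedGraph, plus VCF INFO
  annotation.
* **Synthetic data** — genomes, feature tracks, per-sample singleton
  sets, de novo sets and QC spike-ins generated from a serializable
  ground truth, so every stage has parameter-recovery tests.

## Worked example

```r
library(ervrates)

g     <- gen_genome(5e5, gc_fraction = 0.4, seed = 1)   # 500-kb synthetic contig
truth <- make_ground_truth(seed = 2)                    # known 7-mer rates
v     <- gen_singletons(g, truth, n_samples = 100, seed = 3)

rt <- estimate_rates(v, g, K = 7)
print(rt, n = 5)
```

```
<rate_table> K = 7: 24576 subtypes, 9,124 ERVs / 1,499,982 motif occurrences
     subtype erv_count motif_count   rate
 CGG[C>T]GTA        12          23 0.5217
 GTT[C>T]GAC        24          50 0.4800
 CGC[C>T]GTG         6          13 0.4615
 ACA[C>T]GGT        22          48 0.4583
 CTC[C>A]GAG        15          36 0.4167
```

Each row is one subtype: how many singletons hit it, how often its
motif occurs, and the ratio — here the hottest contexts are CpG
transitions, as they should be. Validating two strategies against a
synthetic de novo set:

```r
dn <- gen_denovo(g, truth, 2000, seed = 4, exclude = v)
bg <- partition_background(sample_background(g, 40000, exclude = dn, seed = 5), seed = 6)
t7 <- truth_rate_table(truth, g)
t1 <- aggregate_rates(aggregate_rates(aggregate_rates(t7)))  # 1-mer strategy
validate_strategies(dn, bg, list(`7mer` = t7, `1mer` = t1), g)$comparison
```

```
<model_comparison> 2 model(s), N identical
 label rank delta_aic     r2 comparable
  7mer    1       0.0 0.1354       TRUE
  1mer    2     801.9 0.0774      FALSE
```

The 7-mer covariate fits the de novo incidence far better (ΔAIC ≈ 802,
higher pseudo-R²): context resolution carries real information about
where mutations occur.

A thin command-line front end for simulation, map export and VCF
annotation lives at `inst/cli/ervtools.R` (subcommands `simulate`,
`map`, `annotate`).

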