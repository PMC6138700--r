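---
title: "Modeling context-dependent germline mutation rates from singleton variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling context-dependent germline mutation rates from singleton variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Common genetic variants are a poor readout of the mutation process: most
are old, and their frequencies have been reshaped by selection and
GC-biased gene conversion. Singletons — variants observed exactly once in
a large cohort, here called extremely rare variants (ERVs) — are young
enough that these filters have barely acted, so their distribution over
sequence contexts tracks the mutation process itself.

`ervrates` estimates, for every K-mer mutation subtype, a **relative
mutation rate**

> rate(subtype) = (# singletons whose central position carries that
> substitution in that motif) / (# occurrences of the motif in the
> mappable reference genome).

This is a unitless proportion — a rate *relative* to other subtypes, not
a per-site per-generation rate; no generational calibration is attempted.

A subtype is a substitution plus its centered K-mer context, collapsed
onto the strand whose central base is A or C (a T>G variant is the A>C
variant of the opposite strand). This yields 6 basic types and
6·4^(K−1) subtypes: 6, 96, 1536 and 24,576 for K = 1, 3, 5, 7. Motifs in
the reference are counted by a 1-bp sliding window, so a run of four As
contains two AAA 3-mers; windows containing N or crossing a contig end
are excluded; with an accessibility mask, only windows whose *central*
base is accessible count (the flanks may leave the mask — the mask
expresses per-site callability, not per-window callability; whether the
original analyses filtered whole windows or central bases is not
documented, and the central-base choice matches per-site semantics).

Nested context widths satisfy an aggregation identity: each K-mer
subtype's rate is the motif-count-weighted mean of its 16 (K+2)-mer
constituents' rates. `aggregate_rates()` implements this by summing ERV
and motif counts. One caveat that the tests make explicit: a directly
estimated coarse table and an aggregated fine table differ in exactly
the windows only one width can see — a 5-mer window exists at two
positions per contig end where a 7-mer window does not. The identity is
exact on common window support; at genome scale the discrepancy is a few
windows out of billions.

## Heterogeneity between nested contexts

To ask whether the 16 (K+2)-mer constituents of a K-mer subtype share
one rate, `heterogeneity_test()` forms the 16×2 contingency table of
(singleton, non-singleton) counts and computes the Pearson chi-squared
statistic with **15 degrees of freedom**. The df is a design commitment:
constituents with zero motif occurrences contribute nothing to the
statistic but do not reduce the df, so every test is on the same scale.
A parent with zero singletons is reported as untestable rather than as
p = 1. Under a simulated null (all 16 children sharing one rate,
motif counts 5000, rate 0.05 — large enough for the chi-squared
approximation), the p-values are uniform; the test suite checks this
with a Kolmogorov–Smirnov test over 2000 replicates.

## Comparing rate tables

`compare_rate_tables()` compares two tables of the same K after
normalizing each subtype's rate by its table-wide sum — the comparison
is of *spectra*, deliberately insensitive to overall singleton yield.
The normalization scheme is a package choice (the convention used when
two estimates are compared "after normalization" is not otherwise
pinned down) and is recorded in the output. Reported quantities:
Spearman correlations (overall and per basic type), per-subtype
normalized ratios, and the fraction of subtypes whose normalized rates
differ by ≥ 50%. `gc_strata_test()` stratifies 7-mer motifs of a type
by flanking G/C count (4–6 = high, ≤ 3 = low; the central base is never
counted) and t-tests the log rate ratio between strata — the signature
expected if gBGC inflates common-variant–derived estimates in GC-rich
contexts.

## Sample QC by spectrum decomposition

Systematic sequencing artifacts show up as individuals whose private
singletons have an unusual 3-mer spectrum. `per_sample_spectra()` builds
the n×96 matrix of per-individual 3-mer rates; `nmf_decompose()`
factorizes it into `rank = 3` non-negative signatures; a sample is
flagged when any signature's contribution lies more than `k_sd = 2`
standard deviations from the cohort mean for that signature.

Numerical choices:

* **Objective and algorithm.** Frobenius reconstruction error, minimized
  by hierarchical alternating least squares (HALS): each column of W and
  row of H is replaced by its exact non-negative block minimizer, so the
  objective is non-increasing (asserted every sweep). HALS was chosen
  over Lee–Seung multiplicative updates after the latter proved too slow
  to reconstruct an exactly rank-3 matrix to 1e-6 relative error within
  any reasonable sweep budget (2×10⁻⁵ after 20,000 multiplicative
  updates on an 80×96 instance; HALS reaches 1e-8 in ~17,000 sweeps on
  200×96). Defaults: 5 random restarts, at most 20,000 sweeps, stopping
  when the objective falls below 1e-8 of the input norm or stops
  improving relatively by 1e-8. The seed is a required argument and is
  stored in the fit.
* **Contributions are row-normalized to proportions** before the 2-SD
  rule ("relative contribution" is compositional); the raw-loadings
  behavior is available via `normalize = FALSE` since the original
  convention is not documented.
* A signature with zero SD across samples flags nobody (degenerate
  case); `k_sd = 0` flags every sample off the mean.

What passing the QC criteria shows, and does not: with ~100–200
singletons per synthetic sample, spiked samples drawn from a grossly
aberrant spectrum are separable at 2 SD with few false flags. Much
sparser cohorts (tens of variants per sample) push the per-sample
spectra into the Poisson-noise regime where the 2-SD rule flags heavy
tails of ordinary sampling noise; real cohorts with thousands of
singletons per individual are far inside the comfortable regime.

## Validating rate estimates against de novo mutations

Given a set of de novo mutations and a nonmutated background of sites
(drawn uniformly from mappable positions, excluding the de novo
positions so no site carries both labels), each testing site i gets an
indicator d_i and a covariate r_i,M — the relative rate of the site's
subtype under rate-estimation strategy M. The model is the
single-covariate logistic regression

> logit Pr(d_i = 1) = α₀ + α₁ · r_i,M

fitted by IRLS (deviance tolerance 1e-8, 100 iterations). Model quality
is summarized by AIC = 2p − 2lnL with **p = 1 covariate parameter**, and
Nagelkerke's pseudo-R² against the intercept-only null. When the
covariate is constant the slope is unidentifiable: the fit collapses to
the null model, flagged, with p = 0 in its AIC (it has no covariate
parameter) and R² = 0. Models are comparable only at identical N —
`compare_models()` enforces this — and a model within 10 AIC units of
the best is marked comparable.

Because every background site could serve as the nonmutated analogue of
three different substitutions, the background is partitioned into three
disjoint sets interpreted as A>G/C>T, A>C/C>G and A>T/C>A respectively
(reference bases read on the canonical strand). Set sizes are
ceiling(n/3) then an even split of the remainder, so one million sites
partition as 333,334/333,333/333,333. For type-stratified comparisons
the C-types are split by CpG status — a C immediately followed by G on
the canonical strand — giving 9 basic types.

### A caveat on the untransformed covariate

The covariate enters on the probability scale, untransformed, exactly as
the model equation specifies. When de novo sites are *sampled in
proportion to the rate* — the synthetic generator's forward model — the
implied true relation is odds ∝ r, i.e. logit = log r + constant, so the
linear-in-r logistic is misspecified. A consequence worth knowing: if
between-class rate differences are large (hypermutable CpG transitions)
while within-class context spread is small, a *coarser* covariate can
fit the misspecified linear link better than the exact generative 7-mer
covariate, inverting the expected ranking even though a log-transformed
covariate ranks the widths decisively in information order. The
synthetic generator's default context spread (lognormal, sd 1.0 on the
log scale) is wide enough that within-class resolution dominates this
link-approximation error and the generative width wins the comparison,
as the framework is designed to demonstrate; the resulting truth tables
span a somewhat wider dynamic range than real 7-mer estimates do. With
narrower context spread the inversion is reproducible and is a property
of the linear link, not of the likelihood machinery.

## Per-subtype effects of genomic features

For each 7-mer subtype with at least 20 singletons, every genome site
centered at the motif is an observation: Z = 1 if it carries a singleton
of the subtype. `fit_subtype_model()` fits

> logit Pr(Z = 1) = β₀ + β₁F₁ + … + β₁₄F₁₄ + β_DP·DP

by maximum likelihood. Binary features (histone marks, lamin-associated
domains, CpG islands, DHS, exons) are 1 iff the central site is inside
an interval (BED half-open semantics, boundary-tested). Continuous
features (recombination rate in cM/Mb, replication timing, GC fraction)
are the overlap-weighted mean over a 10-kb window centered at the site,
truncated at contig edges; read depth is the value at the central site.
Continuous predictors are rescaled so one unit is 10% of the observed
range — odds ratios read "per 10% increase"; the precise scale behind
that phrase is not documented, so the implementation declares its
choice (range/10) in the fitted object. Zero-variance predictors get a
zero coefficient by construction; separation or collinearity withholds
coefficients with a flag rather than reporting garbage. The intercept's
inverse logit is the feature-adjusted relative rate, and with all
features zero it equals the marginal rate to numerical precision
(tested at 1e-9).

Significance is controlled per feature across subtypes with
Benjamini–Hochberg at FDR 0.05 (the procedure behind a bare "false
discovery rate cutoff" is a package choice; BH is the default
convention). Interaction terms are deliberately excluded. Enrichment of
a category among flagged subtypes (e.g., A>G subtypes among those
positively associated with H3K36me3; W[A>G]W contexts among those) uses
an exact binomial upper tail with the null proportion implied by the
enumeration — 1/6 for one basic type, 1/4 for W_W flanks — these nulls
are derived, not free parameters. De novo corroboration pools subtypes
sharing a (feature, direction) flag and runs a 1-df Pearson chi-squared
on the 2×2 of de novo/background × inside/outside counts, falling back
to Fisher's exact test (labelled) when an expected cell is zero.

## The per-site rate map

`predict_site_rates()` emits, for every predictable site, three
probabilities — one per alternative allele — from the corresponding
subtype model's full coefficient vector (all estimated effects, not
only the FDR-significant ones). Sites within a configurable telomeric
exclusion or with no fitted model receive the marginal 7-mer rate, with
provenance recorded. The exclusion default is 0 bp because synthetic
contigs are short; 5 Mb matches the span near real chromosome ends
where recombination maps are unavailable. The three probabilities are
deliberately not renormalized against a no-mutation probability. Output
is a 6-column TSV or per-alternative bedGraph with runs of equal
formatted values merged; numbers are printed to 6 significant digits so
byte output is deterministic. `annotate_vcf()` adds the subtype, table
rate, and (optionally) model probability to INFO; records whose REF
disagrees with the genome are flagged, never silently annotated, and
non-SNVs pass through flagged.

## The synthetic-data generator

Every stage is testable against known truth without external data:

* `gen_genome()` — i.i.d. bases at a requested GC fraction (default
  0.4, matching mammalian bulk composition), optional random
  accessibility mask. Real genomes are not i.i.d. — no CpG islands,
  isochores or repeats — so motif counts are near-uniform across motifs
  of the same composition; tests that need motif-count contrast
  construct it explicitly.
* `make_ground_truth()` — per-subtype rates: per-type means (defaults:
  transitions ~4× transversions, overall ~0.0063 mean per subtype so a
  1–2 Mb contig yields tens of thousands of singletons), a CpG
  transition boost (default 6), and lognormal context modulation
  (default sd 1.0 — see the covariate caveat above for why a wide
  within-class spread is the regime the validation framework is meant
  for). Optional per-feature log-odds effects by basic type.
* `gen_singletons()` — independent Bernoulli per (site, alternative)
  with logit = logit(subtype rate) + Σ β·F; each variant becomes a
  singleton (AC = 1) assigned to a sample. Sites are independent — no
  clustered or multinucleotide events. Rates whose expected total
  exceeds the site count are rejected.
* `gen_denovo()` — n distinct (site, alternative) pairs drawn with
  probability proportional to the truth rates, via with-replacement
  draws thinned to unique pairs (weighted draws *without* replacement
  measurably distort heavy-tailed spectra). An optional "uniform"
  perturbation ignores the rates, for ranking-robustness checks.
* `spike_outliers()` — resamples chosen samples' variants from an
  aberrant 3-mer spectrum (default: 90% of mass on C>G subtypes),
  recording the labels.

All generators take a required seed, restore the RNG state on exit, and
the ground-truth object suffices to recompute every expectation.

## Problem sizes used by the test suite

The suite runs at desk scale, chosen so the 7-mer taxonomy is populated
for common subtypes while the whole suite completes in minutes: 200-kb
fixture cohorts for estimator tests; a 300-kb genome with 5000 de novos
and 100,000 background sites per replicate (20 replicates) for the
strategy-ranking check; a 1-Mb genome with 200 samples (~100 singletons
each) for the spike-recovery QC check; 50,000 sites × 100 replicates
for feature-effect coverage. The million-site background partition is
exercised directly on a synthetic site list.

## Known limitations

* Autosomal biallelic SNVs only; indels, multiallelic records and sex
  chromosomes are out of scope, as is ancestral-allele polarization
  (the reference allele is treated as ancestral, and a VCF REF that
  contradicts the genome is a hard error).
* The relative rates are not calibrated to per-generation units.
* The i.i.d. synthetic genome under-represents motif-count imbalance
  and linkage structure; parameter-recovery results on it bound what
  the estimators can do on ideal data, not what real data will give.
* The linear-in-rate validation link is faithful to the published model
  but, as discussed, is misspecified under rate-proportional sampling;
  rankings among near-equivalent strategies should be read with that in
  mind.
* Signature attribution (matching NMF signatures to biological
  processes) and contamination/relatedness QC are out of scope.
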