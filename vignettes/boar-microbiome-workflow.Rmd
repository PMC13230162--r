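---
title: "Partitioning breed, farm and age effects in boar gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning breed, farm and age effects in boar gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boarMicrobiome)
```

## The problem

Commercial boar stations house three breeds — Duroc, Landrace and Large
White — in strongly imbalanced numbers (the design this package defaults to
has nine breed-by-station groups of 34/113/338, 8/108/301 and 498/166/85
animals, 1,651 in total, aged 257–1,906 days). Shotgun metagenome profiling
of such a cohort yields a TPM-scale species abundance matrix, per-species
genome-coverage statistics, and sample metadata (breed, farm, operating
company, rearing batch, age). The scientific questions are: how much of the
variation in community composition is attributable to breed, age and
husbandry factors; which species are shared across breeds and farms; and
which species are consistently enriched in a breed or an age stage once the
other factors are controlled. All of these are confounded with the group
imbalance, which is why the package couples every comparison with a
resampling check.

This vignette explains the models behind each stage, the defaults and why
they are set where they are, and what the synthetic cohort generator can
and cannot establish about behaviour on real data.

## The cohort container

A cohort is a `CohortExperiment`, a `SummarizedExperiment` with taxa as
rows, samples as columns, and two assays: `tpm` (abundances closed to a
per-sample total of 10^6) and `coverage` (reads-per-base). Accessors
(`tpm()`, `coverage()`, `sampleData()`) return matrices with samples in
rows — the orientation of the on-disk TSV tables and of every analysis
function. `metadata()` carries the average read length (151 bp) and, for
simulated cohorts, the planted-truth table.

## Presence gating and filtering

Two presence rules operate at different points of the chain, and both are
strict inequalities because they gate detection:

* **coverage rule** — a species is retained in a sample only when its
  effective coverage (reads-per-base × read length) exceeds 1×. Exactly
  1.0 is absent. `gateByCoverage()` zeroes gated entries and re-closes
  each sample to 10^6.
* **abundance rule** — for set analysis, presence means relative abundance
  above 10^-5 (TPM > 10).

Prevalence cutoffs, by contrast, are inclusive: a taxon present in exactly
10% of a group passes the 10% set-analysis filter, and the enrichment
filter keeps taxa detected in at least 5% of samples *and* with mean
relative abundance at least 10^-5. The coverage rule is applied first
(table construction), the abundance rule afterwards (set analysis); the
two are not assumed equivalent, and alpha diversity is computed on the
full coverage-gated table rather than any prevalence-filtered one (a flag
on `buildGroupSets()`/`prevalenceFilter()` lets users choose otherwise).

## Diversity and ordination

Alpha diversity is observed richness (taxa with abundance > 0), Shannon
(natural log) and Simpson (1 − Σp²), via `vegan::diversity()`. Group
comparisons use two-sided Wilcoxon rank-sum tests — exact when the
combined sample is ≤ 20 without ties, normal approximation with tie
correction otherwise — BH-adjusted within each index family; fully tied
samples carry no evidence and return p = 1.

Beta diversity is Bray–Curtis, d(i,j) = Σ|xᵢ−xⱼ| / Σ(xᵢ+xⱼ). It is not a
metric, so ordination uses principal coordinates: Gower double-centring of
−½D², eigendecomposition, coordinates scaled by √λ. Negative eigenvalues
are reported but uncorrected (no Cailliez/Lingoes), proportions explained
are over the positive-eigenvalue sum, and each axis's sign is fixed so its
largest-magnitude loading is positive — a deterministic convention, since
eigenvectors are defined only up to sign.

## Distance-based variance partitioning

`permanova()` is implemented from first principles rather than delegated,
because multi-term partitioning with both sequential and marginal sums of
squares is the analytical core of the package. With G the Gower-centred
inner-product matrix and H_k the hat matrix of the dummy-coded design of
the first k terms,

* sequential SS of term k = tr(H_k G) − tr(H_{k−1} G) — order-dependent,
  and terms + residual = total exactly;
* marginal SS of term k = tr(H_full G) − tr(H_{−k} G);
* pseudo-F uses the full-model residual in both modes; R² = SS/SS_total.

Both modes are reported throughout because they differ for unbalanced
data, and the stratified analyses this package targets are unbalanced by
construction. Significance comes from freely permuting sample rows (no
blocks), with p = (1 + #{F* ≥ F}) / (1 + N) so p is never zero; the
comparison uses a 10^-8 relative tolerance so permutations that tie the
observed statistic exactly (relabelings of the same partition) are counted
despite floating-point noise. On Euclidean distances of a 1-D response the
sequential SS equal classical ANOVA sums of squares to 10^-8 — the
suite's primary correctness oracle, alongside agreement with
`vegan::adonis2` on random data.

Stratified fits (`permanovaByStratum()`) drop, within each stratum, every
level of a modelled factor observed fewer than `min_group_size = 10`
times before fitting — the rule under which a breed group of n = 8 is
excluded — and record skipped strata with reasons. Age enters these
models as the three-level stage factor (young ≤ 365 d, mid 366–1095 d,
aged > 1095 d; the year boundaries are whole days because no day/month
convention is standard), not as continuous days.

## Bootstrap robustness under imbalance

With groups of 8 to 498 animals, a significant test may simply reflect the
largest group. `bootstrapAlpha()` subsamples, within each farm, every
breed down to the smallest breed's size (without replacement — the
procedure equalises, it does not resample), recomputes the indices and
runs the omnibus non-parametric test (Kruskal–Wallis for ≥ 3 groups) per
iteration; `bootstrapBeta()` does the global analogue with equal-size
draws per breed-by-farm cell followed by a one-term PERMANOVA. Each
iteration's realised design is asserted balanced. The per-iteration
criterion is p < 0.05; the summary reports the stability fraction, the
median p and a 95% p-interval. No numeric cutoff on the stability
fraction defines "robust" in the source procedure, so the declare-stable
threshold is a reporting flag (default 0.95), not part of the test.

One calibration subtlety: iterations on a single cohort are dependent —
the smallest group is reused in every draw (with the 34/113/338 station
design, the smallest breed is drawn whole each time), so the per-cohort
fraction of significant iterations has near-unit variance under the null.
The package's null-calibration checks therefore estimate the *marginal*
per-iteration false-positive rate by pooling iterations across
independently simulated null cohorts (20 cohorts × 10 iterations); that
pooled rate is what should sit near 5%.

## Shared and specific taxa

`buildGroupSets()` applies the abundance presence rule then the 10%
prevalence rule within each group (breeds within a farm, or farms within
a breed); `intersectReport()` tallies exclusive intersections — taxa in
exactly each subset of groups, the bars of an UpSet plot — over all
2^k − 1 subsets, asserting that they tile the union. Because "shared
between two groups" is sometimes read inclusively, the report also emits
the inclusive pairwise overlap matrix. A brute-force set-algebra tally is
kept in the test suite as the oracle.

## Enrichment models and the consistency classifier

Per-taxon responses are ln(relative abundance + pseudocount), the
pseudocount being half the taxon's smallest nonzero relative abundance
(recorded per taxon) — the TSS + LOG convention of multivariable
microbiome association frameworks, re-implemented here as explicit OLS
fits so the covariate handling and the classifier are fully specified.
For each pair of levels of the primary factor (breed, or age stage), the
response is regressed on the contrast indicator plus dummy-coded
covariates restricted to the pair's samples; covariate levels absent from
the pair are dropped, aliased columns are removed by the rank-revealing
decomposition, and zero-variance responses are flagged with p = 1. BH
adjustment is applied across taxa *within each pairwise model* — the
family matching the "q < 0.05 in both models" rule; the family choice is
a documented decision since no explicit family is standard.

A taxon is labelled enriched in level L only when both pairwise models
involving L favour L in sign and both have q strictly below 0.05. Sign
logic makes labels mutually exclusive, and relabelling reference and
contrast flips coefficients but never labels. Default covariates are
company + farm + batch for breed, and farm + breed + batch for age stage
(breed is a covariate of the age models because age composition differs
across breeds in this design).

## The synthetic generator, and what passing tests show

`simulateCohort()` draws, per sample, log-scale taxon intensities =
baseline + breed + farm + stage + batch shifts + Gaussian noise
(`dispersion`, default 1.0 on the natural-log scale), exponentiates and
closes to 10^6. An additive log-normal model was chosen over a
Dirichlet-multinomial because the enrichment models are linear on log
abundances, making planted effects interpretable as target coefficients;
zero-inflation and phylogenetic correlation among taxa are deliberately
not modelled. Default baselines give two synthetic phyla
(Firmicutes-like, Bacteroidota-like) higher intensities, reproducing the
two-phylum dominance of the pig hindgut. Coverage is
`depth_factor` (default 3) × relative abundance × a per-sample lognormal
depth jitter (sdlog 0.3), placing typical taxa near the 1× gate so
presence calling is exercised on both sides. The default design is the
real nine-group station structure with ages uniform on 257–1,906 days and
four batches nested per farm; per-breed dispersions are not reported
anywhere, so the default is a testability choice, not a fidelity claim.
Determinism: one RNG stream per cohort seeded from the design, per-sample
sub-streams drawn from it, so equal seeds give byte-identical files.

Two benchmark conventions deserve note. First, planted-effect recovery
simulations give planted taxa a flat baseline: with heterogeneous
baselines, the planted mass differs across breeds, and compositional
closure then shifts *every* null taxon between breeds — a real property
of relative-abundance data (the package's models are not
closure-corrected; CLR/ILR transforms are out of scope), not an estimator
defect. Symmetric planted mass isolates the estimator's behaviour.
Second, passing on this generator demonstrates algorithmic correctness
and calibration under the stated model; it does not establish robustness
to zero-inflation, taxon-taxon correlation, or depth-dependent detection
beyond the simple coverage model.

## Numerical choices and problem sizes

* Strict `>` for both presence gates; inclusive `≥` for prevalence and
  the enrichment mean-abundance boundary.
* PCoA eigenvalue positivity cutoff at 10^-8 of the largest magnitude.
* Permutation-tie tolerance 10^-8 relative, p estimator (1+c)/(1+N).
* Confounded model terms report df 0 and are flagged, not silently
  dropped.
* The test suite and the verification script run on scaled-down cohorts —
  tens of samples per group, 30–530 taxa, 99–999 permutations, bootstrap
  blocks of 100–200 iterations — sizes chosen so the full property set
  (null calibration at 200 replicates, 50-replicate planted-effect runs)
  completes in well under a minute while keeping binomial error inside
  each test's tolerance. The pipeline defaults (999 permutations, 1,000
  iterations) are the study-scale settings.

## Worked example

```{r example, eval = FALSE}
design <- cohortDesign(seed = 1)            # the nine-station design
model <- effectModel(n_taxa = 300,
                     breed_effects = data.frame(taxon = 1:5,
                                                level = "Duroc",
                                                shift = 2))
cohort <- simulateCohort(design, model)
cfg <- runConfig(output_dir = "results", seed = 1,
                 permutations = 199, bootstrap_iterations = 100)
manifest <- runAll(cfg, cohort = cohort)
```

The manifest records the config hash, seed and per-stage counts; rerunning
with the same config and cohort reproduces every result file byte for
byte.

## Known limitations

Continuous covariates are not supported in the distance models (age is
always the stage factor); permutations are free, never restricted within
blocks; no dispersion homogeneity test (PERMDISP) accompanies the
location test; enrichment models are fixed-effects OLS without random
effects or zero-inflation; and Bray–Curtis/PCoA are the only beta
machinery — no phylogeny-aware distances.
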