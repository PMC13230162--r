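# boarMicrobiome

Variance partitioning and enrichment analysis for large, imbalanced
shotgun-metagenome surveys of commercial boar gut microbiota.

Boar stations house Duroc, Landrace and Large White breeding boars in very
unequal numbers (the package's default cohort design has nine
breed-by-station groups of 34/113/338, 8/108/301 and 498/166/85 animals —
1,651 in total — aged 257–1,906 days). Given a TPM-scale species abundance
table, per-species coverage statistics and sample metadata, the package
answers three questions while guarding against the imbalance:

1. **How much community variation do breed, age and husbandry explain?**
   A from-scratch PERMANOVA partitions Bray–Curtis variation among
   categorical terms: for term *k* with cumulative hat matrix *H_k* on the
   Gower-centred matrix *G*, sequential SS = tr(H_k G) − tr(H_{k−1} G)
   (marginal SS analogously against the full model), R² = SS/SS_total,
   pseudo-F on the full-model residual, and p from free row permutations
   with p = (1 + #{F\* ≥ F}) / (1 + N). Stratified models (per farm:
   `~ breed + age_stage + batch`; per age stage: `~ farm + breed + batch`)
   drop factor levels with fewer than 10 samples before fitting.
2. **Are diversity differences artefacts of group size?** Bootstrap
   subsampling equalises every group to the smallest group's size
   (without replacement), re-tests per iteration (Kruskal–Wallis /
   Wilcoxon for alpha diversity, one-term PERMANOVA for composition) and
   reports the fraction of iterations with p < 0.05.
3. **Which species are shared or consistently enriched?** Presence uses
   strict gates (effective coverage > 1×; relative abundance > 10⁻⁵) and
   inclusive prevalence cutoffs (≥ 10% for set analysis); UpSet-style
   exclusive intersections count shared/specific taxa. Enrichment fits,
   per taxon, OLS models of log relative abundance (pseudocount = half
   the minimum nonzero value) on each pair of breeds or age stages with
   company/farm/batch covariates, BH-adjusts within each pairwise model,
   and labels a taxon enriched in level L only when **both** models
   involving L agree in direction with q < 0.05.

A synthetic cohort generator (log-normal additive effects on the log
scale, compositional closure to 10⁶, coverage proportional to abundance)
reproduces the station design so the whole chain is testable without any
sequencing data; planted effects are carried as a truth table for
recovery benchmarking.

## Worked example

```r
library(boarMicrobiome)

design <- cohortDesign(seed = 1)                   # nine-station default
model  <- effectModel(n_taxa = 120,
                      breed_effects = data.frame(taxon = 1:5,
                                                 level = "Duroc",
                                                 shift = 2))
cohort <- simulateCohort(design, model)
cohort
#> CohortExperiment: 120 taxa x 1651 samples
#> samples per breed x farm:
#>             farm
#> breed         A1  A2  B1
#>   Duroc       34   8 498
#>   Landrace   113 108 166
#>   LargeWhite 338 301  85
#> age range: 257-1906 days; stages: young=106, mid=788, aged=757
#> planted effects: 5 records

gated <- gateByCoverage(cohort)          # presence gate at 1x, re-closed
ab <- tpm(gated); meta <- sampleData(gated)

sel <- meta$farm == "B1"
d <- brayCurtis(ab[sel, ])
permanova(d ~ breed + age_stage + batch, meta[sel, ],
          permutations = 199, seed = 1)
#> PERMANOVA (sequential SS, 199 permutations)
#>            Df   SumOfSqs       R2       F     p
#> breed       2   8.849280 0.076350 30.8200 0.005
#> age_stage   2   0.211257 0.001823  0.7358 0.840
#> batch       3   0.465728 0.004018  1.0810 0.320
#> Residual  741 106.373000 0.917800      NA    NA
#> Total     748 115.899000 1.000000      NA    NA
```

The five taxa planted with a +2 log-shift in Duroc drive a breed R² of
7.6% in station B1 (p = 0.005, the smallest value 199 permutations can
resolve is 0.005); age stage and batch explain under half a percent each
and are indistinguishable from noise. `runAll(runConfig(...), cohort)`
executes the full chain — gating, diversity, stratified PERMANOVA (both
SS modes), bootstraps, shared-taxa intersections, enrichment — writing
TSV results and a JSON manifest whose config hash and seed make reruns
byte-identical.

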