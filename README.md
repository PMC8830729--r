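# migragen

Genomics of partial migration in GPS-collared ungulates: an R package that
takes a cohort from raw telemetry and a SNP matrix to per-SNP association
with migratory behaviour and to ancestry–behaviour regressions, with a
synthetic-data generator so every stage is testable against known truth.

It is written for movement ecologists and conservation geneticists working
on populations where migrants and residents coexist (caribou being the
motivating system) and who want one reproducible pipeline instead of a
chain of disconnected tools.

## What it computes

**Movement phenotypes.** Tracks are thinned to one fix per day. Seasonal
ranges are 95% isopleths of kernel utilization distributions (reference
bandwidth h = ½(sₓ+s_y)n^(−1/6)), and the overlap index

    IO = 2·A₁₂ / (A₁ + A₂)  ∈ [0, 1]

separates residents (high IO) from migrants (low IO). Independently, each
animal-year's net squared displacement (NSD) series is fitted with five
movement models — migrant (bell curve with residence time ρ ≥ 30 days),
mixed-migrant, disperser, nomad, resident — and classified by AIC, with the
rNSD reference point chosen over the first 60 days of tracking. Migrants
get a distance (√δ km), a departure day (day 1 = 1 January), a centroid
distance and a latitudinal shift.

**Population structure.** Genotype QC (call rate ≥ 0.90, MAF > 0.05,
individual missingness ≤ 0.85, LD pruning 50/5/0.5, exact Hardy–Weinberg
p ≥ 0.001), PCA, maximum-likelihood admixture by EM with 5-fold
cross-validation over K, argmax cluster assignment, and Weir–Cockerham
F_ST with a bootstrap CI.

**Association.** Univariate linear mixed model per SNP with a centered
genomic relatedness matrix, per-SNP ML variance-ratio optimisation, Wald
χ² tests, Bonferroni correction, genomic inflation factor λ_GC, per-SNP
PVE with relative PVE normalised to 100% over the significant set, and
exon/intron/promoter(2 kb)/intergenic annotation.

**Ancestry models.** Linear (IO) and logistic (migrant/resident) regressions
on admixture proportions, plus ecotype-random-intercept variants and
Kruskal–Wallis / pairwise Wilcoxon ecotype contrasts.

## Worked example

Simulate a small cohort with admixture structure and migration phenotypes,
classify one migrant's track, and regress behaviour on ancestry:

```r
library(migragen)
cfg <- sim_config(n_individuals = 40, n_snps = 2000, seed = 7)
sim <- simulate_dataset(cfg)

tr  <- thin_daily(sim$tracks[[which(sim$truth$migrant == 1)[1]]])
sel <- select_reference_point(tr)
sel$scan
#> nsd_scan -- best model: mixed-migrant
#> mixed-migrant       migrant     disperser         nomad      resident
#>        4143.5        4153.0        4745.2        4887.4        4896.6

fit <- fit_admixture(sim$geno, K = 2, seed = 1, n_restarts = 2, max_iter = 500)
fst_between(sim$geno, assign_clusters(fit)$cluster, n_boot = 1000, seed = 1)
#> F_ST = 0.0689 (95% CI 0.0638-0.0740; Weir-Cockerham 1984, ratio of averages; 2000 loci)

q_north <- align_q(fit$Q, sim$Q)[, 1]
regress_migrant_on_q(sim$truth$migrant, q_north)
#>     model  response  beta     se statistic      p r_squared   aic  n
#>  logistic nsd_class 1.354 0.8501     1.593 0.1111   0.04877 55.89 40
```

The round-trip NSD shapes beat the stationary ones by ~750 AIC on this
migrant's track; the two admixture clusters recovered from 2,000 SNPs are
mildly differentiated (F_ST ≈ 0.07, as simulated); and northern ancestry
raises the odds of being a migrant (β̂ = 1.35 on the log-odds scale — the
cohort of 40 is deliberately too small for significance; the test suite
checks coverage at the study sizes).

The full pipeline — telemetry → movement → popgen → association → ancestry,
with TSV/JSON outputs and per-stage manifests — runs from one config:

```r
run_pipeline(pipeline_config(telemetry = "telemetry.csv",
                             vcf = "genotypes.vcf", out_dir = "out"))
```

A thin command-line wrapper lives at `inst/cli/migragen.R`
(`Rscript migragen.R simulate|all --config config.yaml`).

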