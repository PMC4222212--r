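# introquant

Tools for quantifying **unidirectional genetic introgression** — gene flow
from a domesticated source into wild conspecific populations — from a panel
of diagnostic biallelic SNPs. The motivating application is monitoring
introgression of escaped farm Atlantic salmon into wild rivers, but the
method is generic: it applies wherever a marker panel separates a
"domesticated" group from a "wild" group regardless of population of origin.

The central difficulty is that both groups are substructured: many farm
strains, many wild rivers, drift and natural migration everywhere. introquant
standardizes the analysis by:

1. **Center points.** Pooling equal subsamples of the reference populations
   for each group and letting them mate at random *in silico* (allele copies
   drawn from pooled frequencies) to create one Hardy–Weinberg reference
   population per group — a wild and a farm "center point" (default 100
   synthetic individuals each).
2. **One-by-one assignment.** Estimating, for every individual separately, a
   probability of membership in the wild center point, *P*(wild), with a
   two-cluster (K = 2) Bayesian admixture model run on the individual stacked
   with the two center points. Per sweep the Gibbs sampler draws allele-copy
   origins z, cluster allele frequencies p ~ Dirichlet(λ + counts), and
   individual admixture proportions q ~ Dirichlet(α + origin counts);
   *P*(wild) is the posterior mean membership in the wild-aligned cluster.
   Analyzing individuals one by one keeps every estimate independent of the
   sample composition. A fixed-frequency maximum-likelihood estimator of q
   (`ml_admixture`, the same likelihood with frequencies held at the
   center-point values) is available as a fast deterministic alternative and
   as an independent check on the sampler.
3. **Reference distributions.** Collecting *P*(wild) over the wild and farm
   reference individuals into calibration distributions (means, 5th/95th
   percentiles, per-population means).
4. **Tests.** One-sided tests of whether a contemporary sample's mean
   *P*(wild) has dropped, on logit-transformed values: against a
   population-specific historical sample when one exists, or against the
   grand mean of the wild references with an extra between-population
   variance component when none does — so introgression can be quantified
   *without* a historical reference for that river.
5. **Calibration.** The proportion of wild genome left in an admixed sample:

   wild genome left = (P̄_adm − Farm_ref) / (Wild_ref − Farm_ref)

   with a percentile bootstrap CI over individuals.

Gamete-level simulators (F1 hybrids, backcrosses BCW/BCF, second-generation
hybrids 2GH, composition scenarios) and a Balding–Nichols generator of
diverged wild/farm panels make the entire pipeline testable with no external
data.

## Worked example

Simulate a diverged panel (59 loci, Balding–Nichols F = 0.3) with three wild
and two farm reference populations, plant a contemporary "river" sample that
is in fact a cohort of F1 hybrids, and run the full pipeline:

```r
library(introquant)

panel <- simulate_reference_populations(
  n_loci = 59, fst = 0.3,
  pop_sizes = list(wild = c(40, 40, 40), farm = c(40, 40)),
  f_within = 0.02, seed = 11)
gm <- panel$genotypes

wild_parents <- subset_individuals(gm, populations(gm) == "wild_1")
farm_parents <- subset_individuals(gm, populations(gm) == "farm_1")
contemporary <- cross_populations(wild_parents, farm_parents, 30,
                                  pairing = "random", seed = 12,
                                  label = "river_now")

report <- run_pipeline(
  bind_individuals(gm, contemporary),
  roles = list(wild_ref = c("wild_1", "wild_2", "wild_3"),
               farm_ref = c("farm_1", "farm_2"),
               admixed  = "river_now"),
  settings = mcmc_settings(seed = 1),
  mode = "ml", historical = "wild_1", verbose = FALSE)
print(report)
```

```
introquant pipeline report
  wild reference:  mean P(wild) 0.966 (5th pct 0.869, n = 120)
  farm reference:  mean P(wild) 0.028 (95th pct 0.157, n = 80)
  admixed sample:  mean P(wild) 0.518 (n = 30)
introgression test (without_reference, one-sided level 0.05)
  contemporary mean logit P(wild) = 0.071 (n = 30)
  null mean = 5.118; critical value = 3.788 [P(wild) 0.978]
  p = 2.134e-10 -> REJECT: evidence of introgression
introgression test (with_reference, one-sided level 0.05)
  contemporary mean logit P(wild) = 0.071 (n = 30)
  null mean = 4.230; critical value = 3.400 [P(wild) 0.968]
  p = 8.465e-17 -> REJECT: evidence of introgression
wild genome left: 52.2% (95% CI 47.6% - 56.3%)
  mean P(wild) = 0.518 over 30 individuals; anchors wild 0.966 / farm 0.028
```

Reading the output: the wild and farm references separate cleanly (means
0.966 vs 0.028), the F1 cohort sits in between (0.518), both test modes
reject the no-introgression null, and the calibrated estimate of wild genome
left (52.2%, CI 47.6–56.3%) brackets the true value of 50% for
first-generation hybrids. `mode = "ml"` uses the fast maximum-likelihood
assignment; `mode = "mcmc"` runs the full sampler (50,000 burn-in /
100,000 sweeps by default — see `mcmc_settings()` for reduced desk-scale
settings).

A thin command-line wrapper over the same functions is installed at
`exec/introquant` (subcommands: `convert`, `centerpoint`, `assign`,
`refdist`, `fst-pcoa`, `test`, `estimate`, `simulate-panel`, `cross`,
`scenario`, `run`).

## Vignette

`vignettes/introgression-quantification.Rmd` documents the model, its
assumptions, the tunable parameters, the synthetic-data generators and the
numerical choices in detail.
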