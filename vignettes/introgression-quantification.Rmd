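---
title: "Quantifying domesticated-to-wild introgression with in silico center points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying domesticated-to-wild introgression with in silico center points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introquant)
```

## The problem

Domesticated populations that escape into the wild — farm Atlantic salmon
being the canonical case — interbreed with wild conspecifics and leave
domesticated alleles behind. Quantifying that *unidirectional* introgression
is hard because neither side is a single population: there are many farm
strains and many wild rivers, all drifting, and wild populations also
exchange migrants naturally. A naive joint clustering of everything is
sensitive to sample composition and confounds substructure with
introgression.

introquant implements a standardized workflow for this setting. It assumes a
panel of biallelic SNPs that is *collectively diagnostic*: wild and
domesticated groups differ in allele frequencies consistently across
populations of origin. Internally genotypes are A-allele dosages in
\{0, 1, 2\} with `NA` for missing, stored in a `genotype_matrix` with one
population label per individual.

## Center points

Rather than using every reference population as its own cluster anchor, the
workflow builds one synthetic anchor per group:

* `subsample_equal()` draws the same number of individuals from each
  reference population (by default the smallest population's size), so no
  single strain or river dominates the pooled allele frequencies;
* `synthesize_centerpoint()` computes pooled per-locus frequencies and draws
  each synthetic individual's two allele copies as independent Bernoulli
  variables at those frequencies.

The second step is "random mating in silico": it restores Hardy–Weinberg and
linkage equilibrium *by construction*, which matters because the assignment
model assumes HWE within clusters, and a raw pool of individuals from
structured populations is not a Hardy–Weinberg population. The center point
depends on the pool only through its allele frequencies — a property the test
suite asserts directly. The default of 100 synthetic individuals per center
point is large enough to represent the pooled frequencies while keeping the
per-individual MCMC cheap; missing genotypes are excluded from pooled
frequencies rather than imputed, and a locus with no data at all is an error.

## One-by-one assignment: P(wild)

`assign_individual()` stacks one query individual with the two center points
(201 individuals by default) and runs a two-cluster Bayesian admixture model
with no population priors. Per Gibbs sweep:

* each allele copy's cluster-of-origin z is drawn with probability
  proportional to (individual admixture q) x (cluster allele frequency);
* cluster frequencies are redrawn from Beta(lambda + A-count,
  lambda + B-count), with lambda = 1 by default;
* each individual's q is redrawn from Dirichlet(alpha + origin counts).

The two clusters are unlabeled during sampling; afterwards the cluster in
which the wild center-point individuals have the higher mean membership is
called "wild" (with 100 pure anchors per cluster this rule is effectively
deterministic). *P*(wild) is the query's posterior mean membership in the
wild-aligned cluster, with a batch-means Monte Carlo standard error.
Individuals are analyzed one by one so that each estimate is independent of
how many and which other samples were collected — `assign_batch()` just loops,
seeding each run from a hash of the individual id, so results are invariant
to query order and to adding or removing other queries.

Missing query genotypes drop out of the likelihood; an all-missing query is
an error, as is any locus-set mismatch between query and center points.

### The concentration parameter alpha

The admixture prior q ~ Dirichlet(alpha) has one shared alpha. By default
introquant **fixes alpha at 1** (a flat prior on q). Sampling alpha by
Metropolis under a Uniform(0, 10) prior is available
(`mcmc_settings(update_alpha = TRUE)`), but is not the default for a reason:
in this design every run contains 200 exactly pure synthetic individuals and
a single query, so the posterior of a shared alpha collapses towards zero.
A near-zero alpha makes the Dirichlet prior strongly bimodal and pushes
genuinely admixed queries towards 0 or 1 — an artifact of sharing one alpha
between 200 pure anchors and one possibly-admixed individual, not evidence
about the query. With alpha fixed at 1 the posterior mean of the query's
membership tracks the fixed-frequency maximum-likelihood estimate closely on
diagnostic panels, which is the behavior the rest of the pipeline relies on.

### The ML estimator

`ml_admixture()` maximizes the same per-allele-copy mixture likelihood with
cluster frequencies held at the center-point values, by golden-section
search on [0, 1] (tolerance 1e-8, endpoints checked explicitly). It is
deterministic, runs in microseconds, and serves two roles: a fast assignment
mode for large batches (`assign_batch(..., mode = "ml")`) and an independent
cross-check of the sampler — the test suite verifies it against exhaustive
likelihood grids and verifies MCMC-ML agreement on diagnostic panels.

Two caveats connect the estimators. The posterior mean and the ML maximizer
only agree closely when the posterior is narrow: on a weakly diagnostic
panel (say Balding-Nichols F = 0.3 across 59 loci) the per-individual
posterior standard deviation is around 0.08, the posterior is skewed, and
the two point estimates can differ by more than 0.05 even with arbitrarily
long chains. Likewise, per-individual recovery of a known admixture
proportion to within 0.05 requires a strongly diagnostic panel (near-fixed
frequency differences); at F = 0.3 the information bound alone puts the
per-individual error near 0.07 at intermediate q. Cohort *means* — what the
introgression estimate actually uses — are far better behaved, which is why
the F1-cohort checks run at F = 0.3 while the per-individual
agreement/recovery checks run at F = 0.8.

## Reference distributions and the visual check

`build_reference_distribution()` collects per-individual *P*(wild) values
into a summary: mean, 5th/95th percentiles (linear interpolation between
order statistics, R's type-7 quantile), per-population means, and
logit-transformed values. The logit transform ln(p/(1-p)) stabilizes
variance for proportions near the boundaries; values are clamped into
[epsilon, 1-epsilon] first, epsilon = 0.001 by default, matching the
3-decimal granularity of typical membership output.

`pairwise_fst_pcoa()` is the workflow's sanity check that the synthetic
center points actually sit inside their reference clusters: pairwise
Weir-Cockerham F_ST between populations (multi-locus ratio of variance
components a / (a + b + c); negative estimates floored at 0 for the distance
matrix) followed by classical metric scaling (`stats::cmdscale`), with
variance explained per axis relative to the positive eigenvalues. The
estimator is implemented from the variance-component formulas because no
installed package provides a genotype-matrix Weir-Cockerham estimator; it is
unit-tested against a fully hand-computed single-locus case and against
simulated panels of known divergence.

## Testing for introgression

All tests work on logit-transformed *P*(wild). Under the null hypothesis
that a contemporary sample is unchanged, it shares its population's mean,
and all wild populations are assumed to share a common within-population
variance `sigma2_within`, pooled across the wild reference populations. The
alternative is one-sided: introgression can only lower mean *P*(wild).

* **With a historical reference** for the same population: a two-sample
  z-test of the contemporary versus historical mean, variance
  `sigma2_within * (1/n_hist + 1/n_cont)`.
* **Without one**: the null mean is the grand mean of the wild reference
  population means, and the contemporary mean gets an additional
  between-population variance component: `sigma2_between + sigma2_within /
  n_cont`, where `sigma2_between` is the method-of-moments estimate
  (variance of population mean logits minus the average within-population
  contribution), floored at 0. This is what allows quantification without a
  river-specific historical sample, at the price of a wider acceptance
  region.

A z-test rather than a t-test is used because `sigma2_within` is pooled over
hundreds of reference individuals (large degrees of freedom). The
without-reference variant is mildly anti-conservative (measured type-I error
around 0.06 at the 0.05 level with 20 reference populations) because the
grand mean and `sigma2_between` are themselves estimated; the simulation
tests document this. `critical_value_curve()` inverts the test: for each
contemporary sample size n it reports the largest mean that still rejects,
back-transformed to the *P*(wild) scale. The curve is monotone in n and, in
without-reference mode, plateaus at
`inv_logit(grand_mean - z_0.95 * sqrt(sigma2_between))`: below that level of
introgression, no sample size suffices — the population-to-population
variability is the binding constraint.

## Calibration and the bootstrap

Because wild references average below 1 and farm references above 0, a raw
admixed mean understates the wild genome share. `wild_genome_proportion()`
rescales it linearly between the two anchors:
(P_adm - Farm_ref) / (Wild_ref - Farm_ref). Values outside [0, 1] are
possible under sampling noise and are returned with a warning rather than
truncated. `bootstrap_ci()` resamples individuals with replacement (1000
replicates by default) and reports the percentile interval of the calibrated
resample means — a plain percentile bootstrap, matching the resampling design
of the workflow; simulation puts its coverage within a few points of nominal
for cohorts of 30 or more.

## Hybrid simulators and synthetic panels

`cross_populations()` mates two parental pools at the gamete level: per
locus, one allele copy drawn uniformly from each parent, independently
across loci; a parent missing a locus transmits a missing allele. The
`all_pairs` pairing crosses every A-side population with every B-side
population (n offspring per population pair — the classical
every-river-times-every-strain design); `random` draws parent pairs from the
pooled sets. `build_cross_groups()` derives the six groups reachable after
two generations of interbreeding (pure wild, pure farm, F1 hybrids H,
backcrosses BCW/BCF, second-generation hybrids 2GH), whose pedigree-expected
wild-genome fractions (1, 0, 0.5, 0.75, 0.25, 0.5) anchor the recovery
tests. `scenario_spec()` + `resample_scenario()` compose these groups in
stated proportions and resample cohorts to get a calibrated estimate with a
percentile interval; `scenario_expected_wild_fraction()` gives the exact
composition-weighted expectation.

`simulate_reference_populations()` generates diverged wild/farm panels under
the Balding-Nichols model: per locus an ancestral frequency pi is uniform on
[0.05, 0.95], each group's frequency is Beta-distributed around pi with
variance F pi (1 - pi), optionally each population within a group re-draws
around the group frequency with a smaller `f_within`, and individuals are
Hardy-Weinberg draws. Balding-Nichols was chosen because one interpretable
parameter (F) controls divergence and the expected Weir-Cockerham F_ST
between the groups is approximately F — which the test suite checks.
`simulate_admixed_individual()` draws each allele copy from the wild
frequencies with probability q and the farm frequencies otherwise — exactly
the generative model behind the admixture likelihood, making it the
ground-truth generator for recovery tests.

### What the synthetic data does and does not emulate

The generator reproduces the *structure* of the problem — two diverged
groups, panel size 59, Hardy-Weinberg populations, known divergence — but
real diagnostic panels differ in ways that matter for absolute numbers:
loci are not exchangeable draws from one divergence distribution (real
panels are ascertained for diagnosticity), genotyping error and missingness
patterns are absent by default, and real wild populations are connected by
migration rather than independent draws. Passing tests on synthetic data
therefore validate the machinery and its statistical properties (unbiased
frequency preservation, HWE, recovery, coverage, type-I error), not the
specific reference means or percentile values any particular real panel
would produce.

## Numerical choices and problem sizes

* Default MCMC: 50,000 burn-in / 100,000 retained sweeps. The package's own
  tests and the acceptance script use reduced runs (500-5,000 burn-in,
  1,500-5,000 retained) — at 201 individuals x 59 loci a reduced run takes a
  few seconds, and the recovery and agreement tests confirm reduced-run
  accuracy at the cohort level.
* Label alignment by center-point mean memberships, post hoc; with
  100 anchors per cluster label switching is not observed. In the degenerate
  no-information case (identical center points) runs fall into one of two
  symmetric label modes; the tests check symmetry of the run distribution
  rather than a single slow-mixing chain.
* `ml_admixture` uses golden-section search to 1e-8 plus explicit endpoint
  checks, so boundary solutions (q = 0 or 1) are exact.
* Percentiles: type-7 linear interpolation; logit clamp epsilon 0.001;
  percentile bootstrap (not BCa) with 1,000 replicates; one-sided level 0.05.
* Equal subsampling and all simulators are seeded explicitly; every
  stochastic function takes a `seed` and restores the caller's RNG state.
* Half-missing genotypes in input files collapse to missing with a warning
  (the likelihood treats a genotype's two copies jointly); missing
  offspring alleles propagate rather than being imputed.

## Known limitations

* K is fixed at 2 and the frequency model is the independent (uncorrelated)
  one; correlated-frequency and linkage models are out of scope.
* The without-reference test treats the available wild references as a
  random sample of wild populations; if they are not (for example, all from
  one region), `sigma2_between` is misestimated.
* The calibration is linear between two scalar anchors; it corrects the
  mean, not the shape, of the admixed distribution.
* Per-individual classification of hybrids is intrinsically uncertain on
  realistic panels — F1 individuals span nearly the whole [0, 1] range —
  so conclusions should be drawn at the population level.
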