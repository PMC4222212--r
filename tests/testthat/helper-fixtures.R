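# Shared fixtures and independent oracles.

# Bare genotype values (attributes stripped) for content comparisons.
geno_data <- function(gm) {
  m <- unclass(gm)
  attributes(m) <- list(dim = dim(m))
  m
}

# Random genotype matrix with missing data, for round-trip properties.
random_genotype_matrix <- function(n, L, miss_rate = 0.1, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  g[matrix(runif(n * L) < miss_rate, n, L)] <- NA_integer_
  genotype_matrix(g, populations = sample(c("popA", "popB"), n, replace = TRUE))
}

# Fully diagnostic panel: wild fixed for A, farm fixed for B.
diagnostic_freqs <- function(L) {
  list(wild = structure(data.frame(locus_id = paste0("locus_", seq_len(L)),
                                   freq_A = rep(1, L), n_alleles = 2L * L),
                        class = c("allele_frequencies", "data.frame")),
       farm = structure(data.frame(locus_id = paste0("locus_", seq_len(L)),
                                   freq_A = rep(0, L), n_alleles = 2L * L),
                        class = c("allele_frequencies", "data.frame")))
}

diagnostic_parents <- function(L, n = 10) {
  list(wild = genotype_matrix(matrix(2L, n, L),
                              populations = rep("wild_pool", n),
                              individual_ids = paste0("w", seq_len(n)),
                              locus_ids = paste0("locus_", seq_len(L))),
       farm = genotype_matrix(matrix(0L, n, L),
                              populations = rep("farm_pool", n),
                              individual_ids = paste0("f", seq_len(n)),
                              locus_ids = paste0("locus_", seq_len(L))))
}

# Strongly diverged synthetic panel plus ready-made center points.
diverged_setup <- function(seed = 1, fst = 0.3, n_cp = 100, n_loci = 59) {
  panel <- simulate_reference_populations(
    n_loci = n_loci, fst = fst,
    pop_sizes = list(wild = 100L, farm = 100L), seed = seed)
  gm <- panel$genotypes
  wild <- subset_individuals(gm, populations(gm) == "wild_1")
  farm <- subset_individuals(gm, populations(gm) == "farm_1")
  wcp <- synthesize_centerpoint(wild, "wild", n_cp, seed = seed + 1)
  fcp <- synthesize_centerpoint(farm, "farm", n_cp, seed = seed + 2)
  list(panel = panel, wild = wild, farm = farm, wcp = wcp, fcp = fcp,
       wf = allele_frequencies(wcp), ff = allele_frequencies(fcp))
}

# Reduced sweep counts for desk-scale MCMC checks.
fast_settings <- function(seed = 1, burn_in = 1000, reps = 3000) {
  mcmc_settings(burn_in = burn_in, reps = reps, seed = seed)
}

# Exact Hardy-Weinberg test (conditional on allele counts): two-sided
# p-value summing probabilities of heterozygote counts no more likely than
# the observed one. Independent oracle, direct enumeration.
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  het_range <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  log_prob <- vapply(het_range, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(n_Aa, het_range)] * (1 + 1e-12)])
}

# Reference distribution straight from a vector of P(wild) values.
dist_from_values <- function(values, pops = "pop", role = "wild") {
  build_reference_distribution(
    data.frame(individual_id = paste0("i", seq_along(values)),
               population = rep_len(pops, length(values)),
               p_wild = values, stringsAsFactors = FALSE),
    role = role)
}
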