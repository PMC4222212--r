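test_that("crosses of fixed parents force heterozygous offspring", {
  p <- diagnostic_parents(L = 8, n = 4)
  off <- cross_populations(p$wild, p$farm, n_offspring_per_pair = 10,
                           pairing = "random", seed = 2, label = "F1")
  expect_identical(nrow(off), 10L)
  expect_true(all(unclass(off) == 1L))
})

test_that("all-pairs pairing yields offspring per population pair", {
  set.seed(12)
  g <- matrix(sample(0:2, 2 * 260 * 3, replace = TRUE), ncol = 3)
  wild <- genotype_matrix(g[1:260, ], populations = rep(paste0("w", 1:20), each = 13))
  farm <- genotype_matrix(g[261:520, ], populations = rep(paste0("f", 1:13), each = 20))
  off <- cross_populations(wild, farm, n_offspring_per_pair = 5, seed = 3,
                           label = "H")
  expect_identical(nrow(off), 1300L)  # 260 population pairs x 5
})

test_that("offspring alleles always exist in the contributing parents", {
  # parent pools fixed at dosage 2 and dosage 1: offspring in {1, 2}
  L <- 30
  a <- genotype_matrix(matrix(2L, 3, L), populations = rep("a", 3))
  b <- genotype_matrix(matrix(1L, 3, L), populations = rep("b", 3))
  off <- cross_populations(a, b, 50, pairing = "random", seed = 4)
  expect_true(all(unclass(off) %in% c(1L, 2L)))
  # B-side gamete is A with probability 1/2: exact binomial bounds
  n_A_from_b <- sum(unclass(off) == 2L)
  expect_gte(n_A_from_b, qbinom(0.0005, 50 * L, 0.5))
  expect_lte(n_A_from_b, qbinom(0.9995, 50 * L, 0.5))
})

test_that("missing parental loci propagate to offspring", {
  a <- genotype_matrix(matrix(c(2L, NA), 1, 2), populations = "a")
  b <- genotype_matrix(matrix(c(0L, 2L), 1, 2), populations = "b")
  off <- cross_populations(a, b, 5, pairing = "random", seed = 5)
  expect_true(all(unclass(off)[, 1] == 1L))
  expect_true(all(is.na(unclass(off)[, 2])))
})

test_that("cross groups have pedigree-expected dosages on a diagnostic panel", {
  p <- diagnostic_parents(L = 40, n = 10)
  groups <- build_cross_groups(p$wild, p$farm, n_per_group = 30, seed = 6)
  expect_identical(nrow(groups), 180L)
  expect_setequal(unique(populations(groups)),
                  c("pure_wild", "pure_farm", "H", "BCW", "BCF", "2GH"))
  g <- unclass(groups)
  pops <- populations(groups)
  expect_true(all(g[pops == "pure_wild", ] == 2L))
  expect_true(all(g[pops == "pure_farm", ] == 0L))
  expect_true(all(g[pops == "H", ] == 1L))
  bcw <- g[pops == "BCW", ]
  expect_true(all(bcw %in% c(1L, 2L)))   # one gamete always wild
  expect_equal(mean(bcw), 1.5, tolerance = 0.05)
  # mean dosage = 2 x wild-genome fraction per group
  fr <- cross_group_wild_fractions()
  for (grp in names(fr)) {
    expect_equal(mean(g[pops == grp, ]), 2 * fr[[grp]], tolerance = 0.08)
  }
})

test_that("scenario expectation is the composition-weighted pedigree mean", {
  props <- c(pure_wild = 0.706, H = 0.107, BCW = 0.167, BCF = 0.007,
             `2GH` = 0.009, pure_farm = 0.004)
  spec <- scenario_spec(props)
  expect_equal(scenario_expected_wild_fraction(spec), 0.891, tolerance = 5e-4)
  expect_equal(round(100 * scenario_expected_wild_fraction(spec)), 89)
  expect_equal(scenario_expected_wild_fraction(scenario_spec(c(pure_wild = 1))), 1)
  expect_equal(scenario_expected_wild_fraction(scenario_spec(c(H = 1))), 0.5)
  expect_warning(scenario_spec(c(pure_wild = 0.5, H = 0.4)), "renormalizing")
  expect_error(scenario_spec(c(nonsense = 1)), "named over")
})

test_that("degenerate scenario pools reproduce the expectation with zero width", {
  fr <- cross_group_wild_fractions()
  pools <- lapply(fr, function(x) rep(x, 5))  # each pool constant at pedigree value
  props <- c(pure_wild = 0.706, H = 0.107, BCW = 0.167, BCF = 0.007,
             `2GH` = 0.009, pure_farm = 0.004)
  spec <- scenario_spec(props, sample_size = 10000, n_reps = 50, seed = 9)
  est <- resample_scenario(pools, spec, wild_ref = 1, farm_ref = 0)
  expect_equal(est$mean, est$expected, tolerance = 0.005)
  # truly degenerate: single active group
  spec1 <- scenario_spec(c(H = 1), sample_size = 30, n_reps = 20, seed = 10)
  est1 <- resample_scenario(pools, spec1, wild_ref = 1, farm_ref = 0)
  expect_equal(est1$mean, 0.5)
  expect_equal(est1$ci_high - est1$ci_low, 0)
  expect_error(resample_scenario(list(H = numeric(0)), spec1, 1, 0), "H")
})

test_that("scenario resampling is unbiased and tightens with sample size", {
  set.seed(13)
  fr <- cross_group_wild_fractions()
  wild_ref <- 0.93; farm_ref <- 0.07
  # unbiased pools: P(wild) values with mean at the calibrated group position
  pools <- lapply(fr, function(x) {
    m <- farm_ref + x * (wild_ref - farm_ref)
    pmin(pmax(rnorm(200, m, 0.05), 0), 1)
  })
  props <- c(pure_wild = 0.706, H = 0.107, BCW = 0.167, BCF = 0.007,
             `2GH` = 0.009, pure_farm = 0.004)
  est30 <- resample_scenario(pools, scenario_spec(props, 30, 1000, seed = 14),
                             wild_ref, farm_ref)
  est100 <- resample_scenario(pools, scenario_spec(props, 100, 1000, seed = 14),
                              wild_ref, farm_ref)
  expect_lt(abs(est30$mean - est30$expected), 0.03)
  expect_lt(abs(est100$mean - est100$expected), 0.03)
  expect_gt(est30$ci_high - est30$ci_low, est100$ci_high - est100$ci_low)
})

test_that("Balding-Nichols generator honors its degenerate and deterministic cases", {
  p0 <- simulate_reference_populations(n_loci = 20, fst = 0, seed = 15)
  expect_identical(p0$wild_freq, p0$farm_freq)
  p1 <- simulate_reference_populations(n_loci = 20, fst = 0.3, seed = 16)
  p2 <- simulate_reference_populations(n_loci = 20, fst = 0.3, seed = 16)
  expect_identical(unclass(p1$genotypes), unclass(p2$genotypes))
  expect_identical(p1$wild_freq, p2$wild_freq)
  expect_true(all(p1$wild_freq > 0 & p1$wild_freq < 1))
})

test_that("admixed individuals have the generative dosage structure", {
  fq <- diagnostic_freqs(50)
  pure <- simulate_admixed_individual(1, fq$wild, fq$farm, seed = 17)
  expect_true(all(unclass(pure) == 2L))
  half <- simulate_admixed_individual(0.5, fq$wild, fq$farm, seed = 18)
  expect_equal(mean(unclass(half)), 1, tolerance = 0.3)
  expect_error(simulate_admixed_individual(1.2, fq$wild, fq$farm))
})

test_that("ML recovery of simulated admixture proportions is unbiased", {
  d <- diverged_setup(seed = 19, n_cp = 100)
  for (q in c(0.25, 0.75)) {
    qhat <- vapply(1:60, function(r) {
      ml_admixture(simulate_admixed_individual(q, d$wf, d$ff, seed = 1000 + r),
                   d$wf, d$ff)
    }, numeric(1))
    expect_lt(abs(mean(qhat) - q), 0.04)
  }
})
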