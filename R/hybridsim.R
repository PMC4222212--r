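#' Gamete-level crosses between two parental pools
#'
#' Generates offspring by sampling one gamete from each side: at every locus
#' one allele copy is drawn uniformly from the A-side parent's genotype and
#' one from the B-side parent's, independently across loci. A parent missing
#' a locus transmits a missing allele, so the offspring genotype is missing
#' there.
#'
#' Pairings:
#' \describe{
#'   \item{all_pairs}{every pair of population labels (A-side x B-side)
#'     contributes `n_offspring_per_pair` offspring, each from parents drawn
#'     uniformly at random within the paired populations (the classical
#'     "every wild population crossed with every farm population" design).}
#'   \item{random}{`n_offspring_per_pair` offspring in total, each from a
#'     random parent pair drawn from the two whole pools.}
#' }
#'
#' @param parents_a,parents_b [genotype_matrix()] objects on a shared locus
#'   set.
#' @param n_offspring_per_pair offspring per population pair (all_pairs) or
#'   in total (random).
#' @param pairing `"all_pairs"` or `"random"`.
#' @param seed integer seed.
#' @param label population label given to the offspring (default `"cross"`).
#' @return a [genotype_matrix()] of offspring.
#' @export
cross_populations <- function(parents_a, parents_b, n_offspring_per_pair = 5L,
                              pairing = c("all_pairs", "random"), seed = 1L,
                              label = "cross") {
  pairing <- match.arg(pairing)
  if (nrow(parents_a) == 0L || nrow(parents_b) == 0L) {
    stop("both parental pools must be non-empty")
  }
  if (!identical(locus_ids(parents_a), locus_ids(parents_b))) {
    stop("parental pools must share an identical locus set")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ga <- unclass(parents_a); gb <- unclass(parents_b)
  if (pairing == "all_pairs") {
    pa <- populations(parents_a); pb <- populations(parents_b)
    pairs <- expand.grid(a = unique(pa), b = unique(pb),
                         stringsAsFactors = FALSE)
    pick <- function(idx) idx[sample.int(length(idx), n_offspring_per_pair,
                                         replace = TRUE)]
    rows_a <- unlist(lapply(pairs$a, function(p) pick(which(pa == p))))
    rows_b <- unlist(lapply(pairs$b, function(p) pick(which(pb == p))))
  } else {
    rows_a <- sample.int(nrow(ga), n_offspring_per_pair, replace = TRUE)
    rows_b <- sample.int(nrow(gb), n_offspring_per_pair, replace = TRUE)
  }
  n_off <- length(rows_a)
  L <- ncol(ga)
  # gamete from dosage g: allele A with probability g/2 (uniform copy choice)
  da <- ga[rows_a, , drop = FALSE]; db <- gb[rows_b, , drop = FALSE]
  na_mask <- is.na(da) | is.na(db)
  pa_ <- da / 2; pa_[is.na(pa_)] <- 0.5
  pb_ <- db / 2; pb_[is.na(pb_)] <- 0.5
  gam_a <- matrix(stats::rbinom(n_off * L, 1L, pa_), nrow = n_off)
  gam_b <- matrix(stats::rbinom(n_off * L, 1L, pb_), nrow = n_off)
  off <- gam_a + gam_b
  off[na_mask] <- NA_integer_
  genotype_matrix(off, populations = rep(label, n_off),
                  individual_ids = paste0(label, "_", seq_len(n_off)),
                  locus_ids = locus_ids(parents_a))
}

#' Build the six cross groups of a two-generation interbreeding design
#'
#' From a wild and a farm parental pool, generates the groups reachable
#' after two generations of interbreeding: pure wild, pure farm,
#' first-generation hybrids (H = wild x farm), backcrosses to wild
#' (BCW = H x wild) and to farm (BCF = H x farm), and second-generation
#' hybrids (2GH = H x H). Pure groups are bred within their own pool so all
#' six groups are one in silico generation removed from the parents.
#' Pedigree-expected wild-genome fractions: pure_wild 1, H 0.5, BCW 0.75,
#' BCF 0.25, 2GH 0.5, pure_farm 0.
#'
#' @param wild,farm parental [genotype_matrix()] pools on a shared locus set.
#' @param n_per_group offspring per group (default 30).
#' @param seed integer seed.
#' @return a [genotype_matrix()] of `6 * n_per_group` offspring with the
#'   group name as population label.
#' @export
build_cross_groups <- function(wild, farm, n_per_group = 30L, seed = 1L) {
  cross <- function(a, b, lab, s) {
    cross_populations(a, b, n_offspring_per_pair = n_per_group,
                      pairing = "random", seed = s, label = lab)
  }
  h_parents <- cross(wild, farm, "H_parent", seed + 10L)  # extra H for 2nd gen
  bind_individuals(
    cross(wild, wild, "pure_wild", seed + 1L),
    cross(wild, farm, "H", seed + 2L),
    cross(h_parents, wild, "BCW", seed + 3L),
    cross(h_parents, farm, "BCF", seed + 4L),
    cross(h_parents, h_parents, "2GH", seed + 5L),
    cross(farm, farm, "pure_farm", seed + 6L)
  )
}

#' Expected wild-genome fractions of the cross groups
#'
#' @return named numeric vector of pedigree expectations.
#' @export
cross_group_wild_fractions <- function() {
  c(pure_wild = 1, H = 0.5, BCW = 0.75, BCF = 0.25, `2GH` = 0.5, pure_farm = 0)
}

#' Specify an introgression scenario
#'
#' A scenario is a composition of the six cross groups in a spawning
#' population (proportions summing to 1) together with the resampling
#' design. Per-group expected wild-genome fractions are fixed by pedigree
#' (see [cross_group_wild_fractions()]).
#'
#' @param proportions named numeric vector over (a subset of) the group
#'   names `pure_wild, H, BCW, BCF, 2GH, pure_farm`; must be non-negative
#'   and sum to 1 (renormalized with a warning if off by more than 1e-9).
#' @param sample_size individuals per resampled replicate (default 30).
#' @param n_reps resampling replicates (default 1000).
#' @param seed integer seed.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(proportions, sample_size = 30L, n_reps = 1000L,
                          seed = 1L) {
  groups <- names(cross_group_wild_fractions())
  if (is.null(names(proportions)) || !all(names(proportions) %in% groups)) {
    stop("proportions must be named over: ", paste(groups, collapse = ", "))
  }
  if (any(proportions < 0)) stop("proportions must be non-negative")
  s <- sum(proportions)
  if (abs(s - 1) > 1e-9) {
    warning("proportions sum to ", format(s), "; renormalizing")
    proportions <- proportions / s
  }
  structure(list(proportions = proportions,
                 wild_fractions = cross_group_wild_fractions()[names(proportions)],
                 sample_size = as.integer(sample_size),
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Expected wild-genome fraction of a scenario
#'
#' The composition-weighted mean of the pedigree wild-genome fractions:
#' `sum_g proportion(g) * wild_fraction(g)`.
#'
#' @param spec a [scenario_spec()].
#' @return the expected proportion of wild genome.
#' @export
scenario_expected_wild_fraction <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  sum(spec$proportions * spec$wild_fractions)
}

#' Resample a scenario's calibrated wild-genome estimate
#'
#' Per replicate, draws `sample_size` individuals with group membership
#' multinomial in the scenario proportions, samples a P(wild) value with
#' replacement from that group's pool, and applies the calibration of
#' [wild_genome_proportion()] to the replicate mean. Reports the mean over
#' replicates and the central percentile interval.
#'
#' @param group_pwild named list of per-group P(wild) vectors (every group
#'   with positive proportion needs a non-empty pool).
#' @param spec a [scenario_spec()].
#' @param wild_ref,farm_ref calibration anchors.
#' @param level central coverage of the interval (default 0.95).
#' @return a `scenario_estimate` list: `mean`, `ci_low`, `ci_high`,
#'   `replicates` (the per-replicate estimates), `expected` (the pedigree
#'   expectation of the scenario).
#' @export
resample_scenario <- function(group_pwild, spec, wild_ref, farm_ref,
                              level = 0.95) {
  stopifnot(inherits(spec, "scenario_spec"))
  active <- names(spec$proportions)[spec$proportions > 0]
  missing_pool <- active[!vapply(active, function(g) {
    length(group_pwild[[g]]) > 0
  }, logical(1))]
  if (length(missing_pool)) {
    stop("no P(wild) pool for group(s): ", paste(missing_pool, collapse = ", "))
  }
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  est <- vapply(seq_len(spec$n_reps), function(r) {
    counts <- stats::rmultinom(1, spec$sample_size, spec$proportions)[, 1]
    vals <- unlist(lapply(names(counts)[counts > 0], function(g) {
      sample(group_pwild[[g]], counts[[g]], replace = TRUE)
    }))
    suppressWarnings(wild_genome_proportion(mean(vals), wild_ref, farm_ref))
  }, numeric(1))
  qs <- stats::quantile(est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(mean = mean(est), ci_low = qs[1], ci_high = qs[2],
                 replicates = est,
                 expected = scenario_expected_wild_fraction(spec),
                 level = level),
            class = "scenario_estimate")
}

#' @export
print.scenario_estimate <- function(x, ...) {
  cat(sprintf("scenario estimate: %.1f%% wild genome left (%.0f%% CI %.1f%% - %.1f%%)\n",
              100 * x$mean, 100 * x$level, 100 * x$ci_low, 100 * x$ci_high))
  cat(sprintf("  pedigree expectation: %.1f%%\n", 100 * x$expected))
  invisible(x)
}

#' Simulate diverged wild and farm reference populations
#'
#' Balding-Nichols generator for a synthetic diagnostic panel: per locus an
#' ancestral frequency pi is drawn (uniform on `ancestral_range`), the wild
#' and farm group frequencies are independent draws from
#' `Beta(pi (1-F)/F, (1-pi)(1-F)/F)` (so their variance around pi is
#' `F pi (1-pi)`), and optionally each population within a group re-draws
#' around its group frequency with a smaller within-group `f_within`.
#' Individuals are Hardy-Weinberg draws from their population frequency.
#'
#' @param n_loci panel size (default 59).
#' @param fst between-group Balding-Nichols F in \[0, 1); `F = 0` makes the
#'   two groups share pi exactly.
#' @param pop_sizes named list with elements `wild` and `farm`, each a vector
#'   of population sizes (one population per element).
#' @param f_within Balding-Nichols F of populations around their group
#'   frequency (default 0: populations within a group share the group
#'   frequency).
#' @param ancestral_range range of the uniform ancestral frequency
#'   distribution (default `c(0.05, 0.95)`).
#' @param seed integer seed.
#' @return a `synthetic_panel` list: `genotypes` (a [genotype_matrix()] with
#'   populations labeled `wild_1, ..., farm_1, ...`), `wild_freq`,
#'   `farm_freq` (true group frequencies), `pop_freq` (per-population
#'   frequencies), `spec` (the call parameters).
#' @export
simulate_reference_populations <- function(n_loci = 59L, fst = 0.3,
                                           pop_sizes = list(wild = 100L,
                                                            farm = 100L),
                                           f_within = 0,
                                           ancestral_range = c(0.05, 0.95),
                                           seed = 1L) {
  stopifnot(fst >= 0, fst < 1, f_within >= 0, f_within < 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rbn <- function(p, f) {
    if (f == 0) return(p)
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  pi0 <- stats::runif(n_loci, ancestral_range[1], ancestral_range[2])
  wild_freq <- rbn(pi0, fst)
  farm_freq <- rbn(pi0, fst)

  draw_group <- function(group, group_freq) {
    sizes <- pop_sizes[[group]]
    labs <- paste0(group, "_", seq_along(sizes))
    pf <- list()
    mats <- lapply(seq_along(sizes), function(j) {
      f <- rbn(group_freq, f_within)
      pf[[labs[j]]] <<- f
      n <- sizes[j]
      matrix(stats::rbinom(n * n_loci, 2L, rep(f, each = n)), nrow = n)
    })
    list(geno = do.call(rbind, mats),
         pops = rep(labs, times = sizes), pop_freq = pf)
  }
  w <- draw_group("wild", wild_freq)
  f <- draw_group("farm", farm_freq)
  geno <- rbind(w$geno, f$geno)
  gm <- genotype_matrix(
    geno, populations = c(w$pops, f$pops),
    individual_ids = paste0("ind_", seq_len(nrow(geno))),
    locus_ids = paste0("locus_", seq_len(n_loci)))
  structure(list(genotypes = gm,
                 wild_freq = wild_freq, farm_freq = farm_freq,
                 pop_freq = c(w$pop_freq, f$pop_freq),
                 spec = list(n_loci = as.integer(n_loci), fst = fst,
                             pop_sizes = pop_sizes, f_within = f_within,
                             ancestral_range = ancestral_range,
                             seed = as.integer(seed))),
            class = "synthetic_panel")
}

#' Simulate one admixed individual with known admixture proportion
#'
#' Each of the two allele copies at every locus is, independently, a wild
#' draw (Bernoulli of the wild frequency) with probability `q` and a farm
#' draw otherwise — the generative model behind the admixture likelihood,
#' used for parameter-recovery checks.
#'
#' @param q true admixture proportion in \[0, 1\].
#' @param wild_freqs,farm_freqs [allele_frequencies()] objects or plain
#'   per-locus frequency vectors on the same locus set.
#' @param seed integer seed.
#' @param id individual id (default `"admixed_1"`).
#' @return a one-individual [genotype_matrix()] labeled `"admixed"`.
#' @export
simulate_admixed_individual <- function(q, wild_freqs, farm_freqs, seed = 1L,
                                        id = "admixed_1") {
  stopifnot(q >= 0, q <= 1)
  if (inherits(wild_freqs, "allele_frequencies")) {
    loci <- wild_freqs$locus_id
    pw <- wild_freqs$freq_A
  } else {
    pw <- as.numeric(wild_freqs)
    loci <- paste0("locus_", seq_along(pw))
  }
  pf <- if (inherits(farm_freqs, "allele_frequencies")) farm_freqs$freq_A
        else as.numeric(farm_freqs)
  stopifnot(length(pw) == length(pf))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  L <- length(pw)
  copy <- function() {
    origin_wild <- stats::runif(L) < q
    stats::rbinom(L, 1L, ifelse(origin_wild, pw, pf))
  }
  g <- copy() + copy()
  genotype_matrix(matrix(g, nrow = 1), populations = "admixed",
                  individual_ids = id, locus_ids = loci)
}
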