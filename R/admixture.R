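#' MCMC settings for the two-cluster admixture model
#'
#' Bundles and validates the sampler settings. Defaults follow common
#' practice for individual-by-individual assignment against two reference
#' center points: 50,000 burn-in sweeps and 100,000 retained sweeps, a
#' symmetric Dirichlet(1) prior on cluster allele frequencies, and a single
#' admixture concentration alpha shared by both clusters.
#'
#' By default alpha is held fixed at `alpha_init` (a flat Dirichlet(1) prior
#' on each individual's admixture proportions). It can instead be sampled by
#' a Metropolis random walk under a Uniform(0, alpha_max) prior
#' (`update_alpha = TRUE`); note that with two large, exactly pure anchor
#' populations in every run, the posterior of a shared alpha collapses
#' towards zero, which turns the prior on the query's admixture proportion
#' strongly bimodal and pushes genuinely admixed individuals towards 0 or 1
#' — a known pathology of the shared-alpha admixture model on reference-
#' anchored data, and the reason the fixed-alpha variant is the default.
#'
#' @param burn_in discarded sweeps (default 50000).
#' @param reps retained sweeps (default 100000).
#' @param lambda Dirichlet prior parameter for allele frequencies (> 0).
#' @param alpha_init initial (or fixed) alpha, in (0, alpha_max).
#' @param alpha_proposal_sd Metropolis step standard deviation (used only
#'   when `update_alpha = TRUE`).
#' @param alpha_max upper bound of the uniform prior on alpha.
#' @param update_alpha sample alpha by Metropolis instead of holding it
#'   fixed (default FALSE).
#' @param seed integer seed.
#' @return a validated `mcmc_settings` list (K is fixed at 2).
#' @export
mcmc_settings <- function(burn_in = 50000L, reps = 100000L, lambda = 1,
                          alpha_init = 1, alpha_proposal_sd = 0.05,
                          alpha_max = 10, update_alpha = FALSE, seed = 1L) {
  stopifnot(burn_in >= 0, reps >= 1, lambda > 0,
            alpha_init > 0, alpha_init < alpha_max, alpha_proposal_sd > 0,
            is.logical(update_alpha))
  structure(list(K = 2L, burn_in = as.integer(burn_in), reps = as.integer(reps),
                 lambda = lambda, alpha_init = alpha_init,
                 alpha_proposal_sd = alpha_proposal_sd, alpha_max = alpha_max,
                 update_alpha = isTRUE(update_alpha),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Assign one individual to the wild and farm center points
#'
#' Runs the two-cluster Bayesian admixture model on the query individual
#' stacked with both center points (no population priors, K = 2). Per sweep
#' the sampler draws allele-copy origins, cluster allele frequencies
#' (Dirichlet/Beta with parameter `lambda`), individual admixture
#' proportions, and the shared concentration alpha (Metropolis). The two
#' unlabeled clusters are aligned afterwards by comparing the mean posterior
#' memberships of the wild versus farm center-point individuals: the cluster
#' in which the wild center point sits is called "wild". `p_wild` is the
#' query's posterior mean membership in that cluster.
#'
#' Analyzing individuals one by one, rather than all of them jointly, keeps
#' each estimate independent of the composition of the rest of the sample.
#'
#' @param query a [genotype_matrix()] with exactly one individual (missing
#'   genotypes drop out of the likelihood; an all-missing query is an error).
#' @param wild_cp,farm_cp center points from [synthesize_centerpoint()] (any
#'   [genotype_matrix()] on the same locus set is accepted).
#' @param settings an [mcmc_settings()] object.
#' @return an `admixture_result`: list with `individual_id`, `population`,
#'   `p_wild`, `p_wild_se` (batch-means Monte Carlo standard error),
#'   `alpha_mean`, `label_alignment`, and the settings used.
#' @export
assign_individual <- function(query, wild_cp, farm_cp,
                              settings = mcmc_settings()) {
  stopifnot(inherits(settings, "mcmc_settings"))
  if (nrow(query) != 1L) stop("query must contain exactly one individual")
  if (!identical(locus_ids(query), locus_ids(wild_cp)) ||
      !identical(locus_ids(query), locus_ids(farm_cp))) {
    stop("query and center points must share an identical locus set")
  }
  if (all(is.na(unclass(query)))) {
    stop("query individual '", individual_ids(query), "' has no genotypes")
  }
  n_w <- nrow(wild_cp); n_f <- nrow(farm_cp)
  stacked <- rbind(unclass(wild_cp), unclass(farm_cp), unclass(query))
  storage.mode(stacked) <- "integer"

  old <- local_seed(settings$seed)
  on.exit(restore_seed(old))
  fit <- .admixture_gibbs(stacked, settings$burn_in, settings$reps,
                          settings$lambda, settings$alpha_init,
                          settings$alpha_proposal_sd, settings$alpha_max,
                          update_alpha = isTRUE(settings$update_alpha))

  wild_rows <- seq_len(n_w)
  farm_rows <- n_w + seq_len(n_f)
  qrow <- n_w + n_f + 1L
  wild_mean_c1 <- mean(fit$q_mean[wild_rows, 1L])
  farm_mean_c1 <- mean(fit$q_mean[farm_rows, 1L])
  wild_cluster <- if (wild_mean_c1 >= farm_mean_c1) 1L else 2L

  p_wild <- fit$q_mean[qrow, wild_cluster]
  bm <- fit$batch_mean_cluster1[, qrow]
  if (wild_cluster == 2L) bm <- 1 - bm
  se <- if (length(bm) > 1L) stats::sd(bm) / sqrt(length(bm)) else NA_real_

  structure(list(
    individual_id = individual_ids(query),
    population = populations(query),
    p_wild = p_wild,
    p_wild_se = se,
    alpha_mean = fit$alpha_mean,
    label_alignment = list(
      wild_cluster = wild_cluster,
      wild_cp_mean = if (wild_cluster == 1L) wild_mean_c1 else 1 - wild_mean_c1,
      farm_cp_mean = if (wild_cluster == 1L) farm_mean_c1 else 1 - farm_mean_c1
    ),
    settings = settings,
    mode = "mcmc"
  ), class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: %s (%s)\n", x$individual_id, x$population))
  cat(sprintf("  P(wild) = %.4f (MC se %.4f, mode %s)\n",
              x$p_wild, x$p_wild_se, x$mode))
  invisible(x)
}

#' Assign a batch of individuals, one by one
#'
#' Each query is an independent single-individual run against the two center
#' points. The run for an individual is seeded by `settings$seed` combined
#' with a deterministic hash of the individual's id, so adding, removing or
#' permuting queries never changes any other individual's estimate (see
#' [derive_seed()]).
#'
#' @param queries a [genotype_matrix()] of query individuals.
#' @param wild_cp,farm_cp center points (shared locus set).
#' @param settings an [mcmc_settings()] object; `derive_seed(settings$seed,
#'   id)` seeds each individual's run.
#' @param mode `"mcmc"` (full Bayesian run per individual) or `"ml"`
#'   (fixed-frequency maximum likelihood against the center-point allele
#'   frequencies; fast, no Monte Carlo error).
#' @return an `admixture_results` data frame: `individual_id`, `population`,
#'   `p_wild`, `p_wild_se`, `mode`, one row per query in input order.
#' @export
assign_batch <- function(queries, wild_cp, farm_cp,
                         settings = mcmc_settings(), mode = c("mcmc", "ml")) {
  mode <- match.arg(mode)
  n <- nrow(queries)
  if (n == 0L) stop("no query individuals")
  if (mode == "ml") {
    wf <- allele_frequencies(wild_cp)
    ff <- allele_frequencies(farm_cp)
    p <- vapply(seq_len(n), function(i) {
      ml_admixture(subset_individuals(queries, i), wf, ff)
    }, numeric(1))
    se <- rep(NA_real_, n)
  } else {
    ids <- individual_ids(queries)
    res <- lapply(seq_len(n), function(i) {
      s <- settings
      s$seed <- derive_seed(settings$seed, ids[i])
      assign_individual(subset_individuals(queries, i), wild_cp, farm_cp, s)
    })
    p <- vapply(res, `[[`, numeric(1), "p_wild")
    se <- vapply(res, `[[`, numeric(1), "p_wild_se")
  }
  structure(data.frame(individual_id = individual_ids(queries),
                       population = populations(queries),
                       p_wild = p, p_wild_se = se, mode = mode,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("admixture_results", "data.frame"))
}

#' Derive a per-individual seed from a base seed and an id
#'
#' A polynomial string hash of the id folded into the base seed (kept within
#' the 32-bit integer range). Seeding each individual's run by identity
#' rather than by position keeps batch results invariant to query order and
#' to adding or removing other queries.
#'
#' @param base integer base seed.
#' @param id character id.
#' @return an integer seed.
#' @export
derive_seed <- function(base, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 268435456
  as.integer((as.double(base) + h) %% 2147483647)
}

#' Fixed-frequency maximum-likelihood admixture proportion
#'
#' Estimates an individual's admixture proportion q (membership in the wild
#' cluster) with the cluster allele frequencies held fixed at the supplied
#' center-point values, by maximizing the per-allele-copy mixture
#' log-likelihood
#' \deqn{\ell(q) = \sum_l [ g_l \log(q p^w_l + (1-q) p^f_l)
#'       + (2-g_l) \log(q(1-p^w_l) + (1-q)(1-p^f_l)) ]}
#' over q in \[0, 1\] (golden-section search refined to 1e-8, with the two
#' endpoints checked explicitly). Missing loci drop out. This is the same
#' admixture likelihood the Gibbs sampler targets, with the frequency
#' uncertainty removed, and serves as a fast deterministic estimator and an
#' independent check on the MCMC.
#'
#' @param query a one-individual [genotype_matrix()].
#' @param wild_freqs,farm_freqs [allele_frequencies()] on the query's locus
#'   set.
#' @return the estimate `q_hat` in \[0, 1\].
#' @export
ml_admixture <- function(query, wild_freqs, farm_freqs) {
  if (nrow(query) != 1L) stop("query must contain exactly one individual")
  g <- as.integer(unclass(query)[1L, ])
  pw <- wild_freqs$freq_A[match(locus_ids(query), wild_freqs$locus_id)]
  pf <- farm_freqs$freq_A[match(locus_ids(query), farm_freqs$locus_id)]
  keep <- !is.na(g) & !is.na(pw) & !is.na(pf)
  if (!any(keep)) stop("no loci with both a genotype and defined frequencies")
  g <- g[keep]; pw <- pw[keep]; pf <- pf[keep]

  loglik <- function(q) {
    pa <- q * pw + (1 - q) * pf
    sum(g * log(pmax(pa, 1e-300)) + (2 - g) * log(pmax(1 - pa, 1e-300)))
  }
  opt <- stats::optimize(loglik, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-8)
  cand <- c(0, opt$maximum, 1)
  cand[which.max(vapply(cand, loglik, numeric(1)))]
}
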