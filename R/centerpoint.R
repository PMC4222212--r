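#' Equal subsampling across reference populations
#'
#' Draws the same number of individuals, without replacement, from each
#' listed population. Pooling equal subsamples before synthesizing a center
#' point prevents large reference populations from dominating the pooled
#' allele frequencies; the number is typically the smallest reference sample
#' size (`n_per_pop = NULL`).
#'
#' @param matrix a [genotype_matrix()].
#' @param populations population labels to subsample from.
#' @param n_per_pop individuals per population; `NULL` uses the smallest of
#'   the listed populations.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [genotype_matrix()] with `n_per_pop` individuals per population.
#' @export
subsample_equal <- function(matrix, populations, n_per_pop = NULL, seed = 1L) {
  pops <- attr(matrix, "populations")
  populations <- as.character(populations)
  missing_pops <- setdiff(populations, pops)
  if (length(missing_pops)) {
    stop("populations not present in the genotype matrix: ",
         paste(missing_pops, collapse = ", "))
  }
  sizes <- vapply(populations, function(p) sum(pops == p), integer(1))
  if (is.null(n_per_pop)) n_per_pop <- min(sizes)
  too_small <- sizes < n_per_pop
  if (any(too_small)) {
    p <- populations[which(too_small)[1]]
    stop("population '", p, "' has ", sizes[[p]],
         " individuals, fewer than n_per_pop = ", n_per_pop)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  keep <- unlist(lapply(populations, function(p) {
    idx <- which(pops == p)
    sort(sample(idx, n_per_pop, replace = FALSE))
  }))
  subset_individuals(matrix, keep)
}

#' Synthesize a Hardy-Weinberg center point by in silico random mating
#'
#' Builds a single analytical reference population (a "center point") for one
#' group (wild or farm) from a pooled genotype sample. For every synthetic
#' offspring and locus, each of the two allele copies is an independent
#' Bernoulli draw with the pooled A-allele frequency, which restores
#' Hardy-Weinberg and linkage equilibrium by construction: the center point
#' depends on the pooled sample only through its allele frequencies.
#'
#' @param pooled a [genotype_matrix()] with at least one non-missing genotype
#'   at every locus (e.g. the output of [subsample_equal()]).
#' @param role `"wild"` or `"farm"`; used as the population label of all
#'   synthetic individuals.
#' @param n_offspring number of synthetic individuals (default 100).
#' @param seed integer seed.
#' @return a `center_point` object: a [genotype_matrix()] of the synthetic
#'   individuals with attributes `role` and `provenance` (source populations,
#'   pooled frequencies, seed).
#' @export
synthesize_centerpoint <- function(pooled, role = c("wild", "farm"),
                                   n_offspring = 100L, seed = 1L) {
  role <- match.arg(role)
  freqs <- allele_frequencies(pooled)
  empty <- freqs$n_alleles == 0L
  if (any(empty)) {
    stop("no non-missing alleles at loci: ",
         paste(freqs$locus_id[empty], collapse = ", "))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  L <- nrow(freqs)
  geno <- matrix(stats::rbinom(n_offspring * L, size = 2L,
                               prob = rep(freqs$freq_A, each = n_offspring)),
                 nrow = n_offspring, ncol = L)
  gm <- genotype_matrix(
    geno,
    populations = rep(role, n_offspring),
    individual_ids = if (n_offspring) paste0(role, "_cp_", seq_len(n_offspring))
                     else character(0),
    locus_ids = freqs$locus_id
  )
  structure(gm,
            role = role,
            provenance = list(
              source_populations = unique(populations(pooled)),
              n_pooled = nrow(pooled),
              pooled_freq_A = stats::setNames(freqs$freq_A, freqs$locus_id),
              n_offspring = n_offspring,
              seed = seed
            ),
            class = c("center_point", class(gm)))
}

#' @export
print.center_point <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("center_point (%s): %d synthetic individuals x %d loci\n",
              attr(x, "role"), nrow(x), ncol(x)))
  cat("pooled from:", paste(prov$source_populations, collapse = ", "),
      sprintf("(%d individuals, seed %d)\n", prov$n_pooled, prov$seed))
  invisible(x)
}

#' @rdname synthesize_centerpoint
#' @param x a `center_point`.
#' @export
centerpoint_role <- function(x) attr(x, "role")

# Seed handling: set the RNG deterministically inside a function without
# clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
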