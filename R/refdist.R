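#' Logit transform with clamping
#'
#' `logit_clamped(p) = log(p / (1 - p))` after clamping `p` into
#' `[epsilon, 1 - epsilon]`, so membership estimates of exactly 0 or 1 map to
#' finite values. `inv_logit` is the plain inverse.
#'
#' @param p proportions in \[0, 1\].
#' @param epsilon clamp width (default 0.001, matching the typical 3-decimal
#'   granularity of membership output).
#' @return numeric vector.
#' @export
logit_clamped <- function(p, epsilon = 0.001) {
  p <- pmin(pmax(p, epsilon), 1 - epsilon)
  log(p / (1 - p))
}

#' @rdname logit_clamped
#' @param x logit-scale values.
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Build a P(wild) reference (or query) distribution
#'
#' Collects per-individual P(wild) estimates into a summarized distribution:
#' overall mean, 5th and 95th percentiles (linear interpolation between the
#' closest order statistics), per-population means, and logit-transformed
#' values (clamped so they stay finite).
#'
#' @param results an `admixture_results` data frame from [assign_batch()],
#'   a list of `admixture_result` objects, or a numeric vector of P(wild)
#'   values.
#' @param labels population label per value; defaults to the labels carried
#'   by `results` (a single label is recycled).
#' @param role `"wild"`, `"farm"` or `"admixed"`.
#' @param epsilon clamp for the logit transform.
#' @return a `reference_distribution`: list with `values` (data frame of
#'   `individual_id`, `population`, `p_wild`, `logit_p_wild`), `role`,
#'   `mean`, `percentile_5`, `percentile_95`, `per_population_means`,
#'   `epsilon`, `n`.
#' @export
build_reference_distribution <- function(results, labels = NULL,
                                         role = c("wild", "farm", "admixed"),
                                         epsilon = 0.001) {
  role <- match.arg(role)
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1), "admixture_result"))) {
    results <- data.frame(
      individual_id = vapply(results, `[[`, character(1), "individual_id"),
      population = vapply(results, `[[`, character(1), "population"),
      p_wild = vapply(results, `[[`, numeric(1), "p_wild"),
      stringsAsFactors = FALSE)
  }
  if (is.data.frame(results)) {
    values <- results$p_wild
    ids <- results$individual_id
    if (is.null(labels)) labels <- results$population
  } else {
    values <- as.numeric(results)
    ids <- names(values)
    if (is.null(ids)) ids <- paste0("ind_", seq_along(values))
  }
  if (length(values) == 0L) stop("no P(wild) values supplied")
  if (is.null(labels)) labels <- "unlabeled"
  labels <- rep_len(as.character(labels), length(values))
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("P(wild) values must lie in [0, 1]")
  }

  lv <- logit_clamped(values, epsilon)
  qs <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  per_pop <- vapply(split(values, labels), mean, numeric(1))
  structure(list(
    values = data.frame(individual_id = ids, population = labels,
                        p_wild = values, logit_p_wild = lv,
                        row.names = NULL, stringsAsFactors = FALSE),
    role = role,
    mean = mean(values),
    percentile_5 = qs[1],
    percentile_95 = qs[2],
    per_population_means = per_pop[unique(labels)],
    epsilon = epsilon,
    n = length(values)
  ), class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("reference_distribution (%s): %d individuals, %d population(s)\n",
              x$role, x$n, length(x$per_population_means)))
  cat(sprintf("  mean P(wild) = %.3f; 5th pct = %.3f; 95th pct = %.3f\n",
              x$mean, x$percentile_5, x$percentile_95))
  invisible(x)
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Multi-locus F_ST (theta) between two populations from the 1984
#' variance-component estimator: per locus and allele the among-population
#' (a), among-individuals-within-population (b) and within-individual (c)
#' components are formed from sample sizes, allele frequencies and observed
#' heterozygosities, and theta is the ratio of sums over loci,
#' `sum(a) / sum(a + b + c)`. Loci with data in fewer than two individuals
#' per population are skipped.
#'
#' @param matrix a [genotype_matrix()].
#' @param pop_a,pop_b population labels present in `matrix`.
#' @return the multi-locus estimate (can be slightly negative when the true
#'   differentiation is near zero).
#' @export
wc_fst <- function(matrix, pop_a, pop_b) {
  pops <- populations(matrix)
  ga <- unclass(matrix)[pops == pop_a, , drop = FALSE]
  gb <- unclass(matrix)[pops == pop_b, , drop = FALSE]
  if (nrow(ga) < 2L || nrow(gb) < 2L) {
    stop("each population needs at least 2 individuals (",
         pop_a, ": ", nrow(ga), ", ", pop_b, ": ", nrow(gb), ")")
  }
  r <- 2
  num <- 0; den <- 0
  for (l in seq_len(ncol(ga))) {
    xa <- ga[, l]; xb <- gb[, l]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 2L || n2 < 2L) next
    p1 <- sum(xa) / (2 * n1); p2 <- sum(xb) / (2 * n2)
    h1 <- mean(xa == 1L); h2 <- mean(xb == 1L)
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise F_ST matrix and principal coordinate analysis
#'
#' The workflow's visual sanity check: pairwise Weir-Cockerham F_ST between
#' all listed populations (optionally with the synthetic center points
#' appended, to confirm they land inside their reference clusters), followed
#' by classical metric scaling of the F_ST distance matrix. Negative F_ST
#' estimates are floored at 0 for the distance matrix.
#'
#' @param matrix a [genotype_matrix()].
#' @param populations labels to include; default all labels in `matrix`,
#'   each with at least 2 individuals.
#' @param centerpoints optional list of center points to append.
#' @param n_axes number of ordination axes to return (default 2, capped by
#'   what the data support).
#' @return a `fst_pcoa` list: `fst` (symmetric matrix, zero diagonal),
#'   `coordinates` (populations x axes), `variance_explained` (share of the
#'   positive eigenvalue total per axis).
#' @export
pairwise_fst_pcoa <- function(matrix, populations = NULL, centerpoints = NULL,
                              n_axes = 2L) {
  if (!is.null(centerpoints)) {
    for (cp in centerpoints) matrix <- bind_individuals(matrix, cp)
  }
  pops <- attr(matrix, "populations")
  if (is.null(populations)) populations <- unique(pops)
  sizes <- vapply(populations, function(p) sum(pops == p), integer(1))
  if (any(sizes < 2L)) {
    stop("populations with fewer than 2 individuals: ",
         paste(populations[sizes < 2L], collapse = ", "))
  }
  if (length(populations) < 2L) stop("need at least 2 populations")
  k <- length(populations)
  fst <- matrix(0, k, k, dimnames = list(populations, populations))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      f <- wc_fst(matrix, populations[i], populations[j])
      fst[i, j] <- fst[j, i] <- f
    }
  }
  d <- pmax(fst, 0)
  n_axes <- min(n_axes, k - 1L)
  mds <- stats::cmdscale(stats::as.dist(d), k = n_axes, eig = TRUE)
  pos <- mds$eig[mds$eig > 1e-12]
  coords <- mds$points
  ve <- if (length(pos)) mds$eig[seq_len(ncol(coords))] / sum(pos)
        else rep(0, ncol(coords))
  colnames(coords) <- paste0("axis_", seq_len(ncol(coords)))
  structure(list(fst = fst, coordinates = coords,
                 variance_explained = pmax(ve, 0)),
            class = "fst_pcoa")
}
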