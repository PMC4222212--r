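#' Diploid biallelic genotype matrix with population labels
#'
#' The central data container of the package: an integer matrix of A-allele
#' dosages (0, 1 or 2 copies of the A allele; `NA` for missing) with one row
#' per individual and one column per locus, carrying unique individual ids,
#' unique locus ids and one population label per individual.
#'
#' The A allele at each locus is an arbitrary but fixed reference allele
#' (for files, the first allele label encountered at that locus). Encoding
#' genotypes as a single dosage makes admixture likelihoods and gamete
#' sampling binomial in one number.
#'
#' @param genotypes integer matrix (individuals x loci) with values in
#'   `{0, 1, 2, NA}`. Row and column names, if present, seed the ids.
#' @param populations character vector of population labels, one per row.
#' @param individual_ids unique ids, one per row; defaults to rownames or
#'   `ind_1 ...`.
#' @param locus_ids unique ids, one per column; defaults to colnames or
#'   `locus_1 ...`.
#' @return An object of class `genotype_matrix`: the integer matrix with
#'   ids as dimnames and the labels in `attr(, "populations")`.
#' @examples
#' g <- genotype_matrix(rbind(c(2, 1), c(0, 0)), populations = c("p1", "p2"))
#' allele_frequencies(g)
#' @export
genotype_matrix <- function(genotypes, populations,
                            individual_ids = NULL, locus_ids = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    stop("genotype values must be 0, 1, 2 or NA; found ",
         paste(unique(genotypes[bad]), collapse = ", "))
  }
  n <- nrow(genotypes)
  populations <- as.character(populations)
  if (length(populations) != n) {
    stop("need one population label per individual: ", length(populations),
         " labels for ", n, " individuals")
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(genotypes)
    if (is.null(individual_ids)) {
      individual_ids <- if (n) paste0("ind_", seq_len(n)) else character(0)
    }
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(genotypes)
    if (is.null(locus_ids)) {
      locus_ids <- if (ncol(genotypes)) paste0("locus_", seq_len(ncol(genotypes)))
                   else character(0)
    }
  }
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  if (length(individual_ids) != n || length(locus_ids) != ncol(genotypes)) {
    stop("id lengths do not match matrix dimensions")
  }
  dimnames(genotypes) <- list(individual_ids, locus_ids)
  structure(genotypes, populations = populations, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n", nrow(x), ncol(x)))
  pops <- table(populations(x))
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)), collapse = ", "),
      "\n")
  miss <- mean(is.na(unclass(x)))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
populations <- function(x) attr(x, "populations")

#' @rdname genotype_matrix
#' @export
individual_ids <- function(x) rownames(x)

#' @rdname genotype_matrix
#' @export
locus_ids <- function(x) colnames(x)

#' Subset a genotype matrix by individuals (keeps labels aligned)
#'
#' @param x a `genotype_matrix`.
#' @param individuals logical, integer or character selector of rows.
#' @return a `genotype_matrix` with the selected individuals.
#' @export
subset_individuals <- function(x, individuals) {
  idx <- seq_len(nrow(x))
  names(idx) <- rownames(x)
  keep <- if (is.character(individuals)) idx[individuals] else idx[individuals]
  if (anyNA(keep)) stop("unknown individual ids in selector")
  genotype_matrix(unclass(x)[keep, , drop = FALSE],
                  populations = populations(x)[keep])
}

#' Stack genotype matrices over the same locus set
#'
#' @param ... `genotype_matrix` objects sharing an identical locus set.
#' @return a `genotype_matrix` with all individuals.
#' @export
bind_individuals <- function(...) {
  mats <- list(...)
  loci <- locus_ids(mats[[1]])
  for (m in mats) {
    if (!identical(locus_ids(m), loci)) stop("locus sets differ between matrices")
  }
  ids <- unlist(lapply(mats, individual_ids))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_dup")
  }
  genotype_matrix(do.call(rbind, lapply(mats, unclass)),
                  populations = unlist(lapply(mats, populations)),
                  individual_ids = ids, locus_ids = loci)
}

#' Per-locus allele frequencies
#'
#' Computes the frequency of the A allele at each locus from non-missing
#' genotypes: `freq_A(l) = sum(dosage at l) / n_alleles(l)` where
#' `n_alleles` counts non-missing allele copies (2 per genotype). Loci with
#' no data get `n_alleles = 0` and `freq_A = NA`.
#'
#' @param matrix a `genotype_matrix`.
#' @param subset optional individual selector (see [subset_individuals()]);
#'   must select at least one individual.
#' @return an `allele_frequencies` object: data frame with columns
#'   `locus_id`, `freq_A`, `n_alleles`.
#' @export
allele_frequencies <- function(matrix, subset = NULL) {
  if (!is.null(subset)) matrix <- subset_individuals(matrix, subset)
  if (nrow(matrix) == 0L) stop("cannot compute allele frequencies of an empty subset")
  g <- unclass(matrix)
  n_alleles <- 2L * colSums(!is.na(g))
  counts <- colSums(g, na.rm = TRUE)
  freq <- ifelse(n_alleles > 0, counts / n_alleles, NA_real_)
  structure(
    data.frame(locus_id = colnames(g), freq_A = freq, n_alleles = n_alleles,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("allele_frequencies", "data.frame")
  )
}
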