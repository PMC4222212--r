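#' Read a STRUCTURE-style genotype file
#'
#' One row per individual: an id column, a population column, then 2L allele
#' columns (two adjacent columns per locus). Missing allele copies are coded
#' `-9`. Allele labels at each locus are mapped to the internal A/B coding:
#' for files using the standard `1`/`2` coding A is always allele `1` (this
#' makes write-then-read an exact identity, including loci fixed for allele
#' `2`); for any other labeling A is the first non-missing allele label
#' encountered in file order, so the encoding is deterministic for a given
#' file. A two-row dialect (each individual on two consecutive rows, one
#' allele copy per row) is accepted via `dialect = "two_row"`.
#'
#' Half-missing genotypes (exactly one allele copy `-9`) are collapsed to
#' missing, with a warning.
#'
#' @param path path to the text file (whitespace-separated).
#' @param dialect `"one_row"` (default) or `"two_row"`.
#' @param locus_ids optional locus names; a first header line with L names is
#'   auto-detected otherwise, else loci are named `locus_1 ...`.
#' @param missing_code allele code for missing data (default `"-9"`).
#' @return a [genotype_matrix()].
#' @export
read_structure_file <- function(path, dialect = c("one_row", "two_row"),
                                locus_ids = NULL, missing_code = "-9") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(genotype_matrix(matrix(integer(0), 0, 0), populations = character(0)))
  }
  tok <- strsplit(trimws(lines), "[ \t]+")
  header_offset <- 0L
  # header detection: first line shorter than the rest and with no id column
  if (length(tok) > 1L && length(tok[[1]]) < length(tok[[2]]) &&
      is.null(locus_ids)) {
    locus_ids <- tok[[1]]
    header_offset <- 1L
    tok <- tok[-1L]
  }
  ncols <- lengths(tok)
  if (length(unique(ncols)) != 1L) {
    # the first data row fixes the layout; flag the first row that deviates
    bad <- which(ncols != ncols[1])[1]
    stop("row ", bad + header_offset, " has ", ncols[bad],
         " columns where ", ncols[1], " were expected")
  }
  nc <- ncols[1]
  if (nc < 3L) stop("need at least id, population and one allele column")
  body <- do.call(rbind, tok)

  if (dialect == "one_row") {
    if ((nc - 2L) %% 2L != 0L) {
      stop("one-row dialect needs an even number of allele columns; row 1 has ",
           nc - 2L)
    }
    L <- (nc - 2L) %/% 2L
    ids <- body[, 1]
    pops <- body[, 2]
    a1 <- body[, 2L + 2L * seq_len(L) - 1L, drop = FALSE]
    a2 <- body[, 2L + 2L * seq_len(L), drop = FALSE]
  } else {
    if (nrow(body) %% 2L != 0L) stop("two-row dialect needs an even row count")
    odd <- seq(1L, nrow(body), by = 2L)
    even <- odd + 1L
    if (!all(body[odd, 1] == body[even, 1])) {
      stop("two-row dialect: consecutive rows must share the individual id")
    }
    L <- nc - 2L
    ids <- body[odd, 1]
    pops <- body[odd, 2]
    a1 <- body[odd, -(1:2), drop = FALSE]
    a2 <- body[even, -(1:2), drop = FALSE]
  }
  if (is.null(locus_ids)) locus_ids <- paste0("locus_", seq_len(L))
  if (length(locus_ids) != L) {
    stop("locus id count (", length(locus_ids), ") does not match loci (", L, ")")
  }

  geno <- matrix(NA_integer_, nrow = length(ids), ncol = L)
  half_missing <- 0L
  for (l in seq_len(L)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    m1 <- x1 == missing_code; m2 <- x2 == missing_code
    half <- xor(m1, m2)
    half_missing <- half_missing + sum(half)
    obs <- as.vector(rbind(x1, x2))         # file order: row by row, copy 1 then 2
    obs <- obs[obs != missing_code]
    labs <- unique(obs)
    if (length(labs) > 2L) {
      stop("locus ", locus_ids[l], " has ", length(labs),
           " distinct alleles; only biallelic markers are supported")
    }
    A <- if (length(labs) == 0L) NA_character_
         else if (all(labs %in% c("1", "2"))) "1"
         else labs[1]
    full <- !(m1 | m2 | half)
    geno[full, l] <- (x1[full] == A) + (x2[full] == A)
  }
  if (half_missing > 0L) {
    warning(half_missing, " half-missing genotype(s) treated as missing")
  }
  genotype_matrix(geno, populations = pops, individual_ids = ids,
                  locus_ids = locus_ids)
}

#' Write a genotype matrix as a STRUCTURE-style file
#'
#' One row per individual with alleles coded `1` (A) / `2` (B) and missing
#' genotypes as `-9 -9`; a header line with the locus ids is written first.
#' Reading the file back with [read_structure_file()] reproduces the input
#' matrix (A = allele `1` is always the first label encountered unless a
#' locus is fixed for B).
#'
#' @param matrix a [genotype_matrix()].
#' @param path output path.
#' @param header write the locus-id header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(matrix, path, header = TRUE) {
  g <- unclass(matrix)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(g) == 0L) return(invisible(path))  # degenerate: empty body, no header
  if (header && ncol(g) > 0L) writeLines(paste(colnames(g), collapse = " "), con)
  a1 <- ifelse(is.na(g), "-9", ifelse(g >= 1L, "1", "2"))
  a2 <- ifelse(is.na(g), "-9", ifelse(g == 2L, "1", "2"))
  inter <- matrix("", nrow(g), 2L * ncol(g))
  inter[, seq(1L, 2L * ncol(g), by = 2L)] <- a1
  inter[, seq(2L, 2L * ncol(g), by = 2L)] <- a2
  rows <- paste(rownames(g), populations(matrix),
                apply(inter, 1L, paste, collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Read / write the CSV dosage dialect
#'
#' A diff-friendly alternative format: header `id,population,<locus ids...>`,
#' one row per individual, genotypes as A-allele dosages 0/1/2 with `NA` for
#' missing.
#'
#' @param path file path.
#' @return `read_genotype_csv` returns a [genotype_matrix()];
#'   `write_genotype_csv` returns `path` invisibly.
#' @export
read_genotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || !identical(names(df)[1:2], c("id", "population"))) {
    stop("CSV dialect requires leading columns 'id' and 'population'")
  }
  geno <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(geno) <- "integer"
  genotype_matrix(geno, populations = df$population, individual_ids = df$id,
                  locus_ids = names(df)[-(1:2)])
}

#' @rdname read_genotype_csv
#' @param matrix a [genotype_matrix()].
#' @export
write_genotype_csv <- function(matrix, path) {
  df <- data.frame(id = individual_ids(matrix),
                   population = populations(matrix),
                   unclass(matrix), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
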