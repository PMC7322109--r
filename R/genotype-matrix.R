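#' Diploid genotype matrix
#'
#' Individuals x loci table of co-dominant marker calls. Each call is an
#' unordered pair of allele labels (PCR fragment sizes in bp, positive
#' integers) or missing. Internally stored as two integer matrices with the
#' smaller allele first, so `231/235` and `235/231` compare equal; `NA` in
#' both matrices marks a missing call.
#'
#' @param individuals Character vector of unique individual ids (rows).
#' @param loci Character vector of unique marker names (columns).
#' @param allele1,allele2 Integer matrices (`length(individuals)` x
#'   `length(loci)`) of allele labels; entries are swapped where needed so
#'   `allele1 <= allele2`. `NA` must appear in both or neither.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(individuals, loci, allele1, allele2) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  if (anyDuplicated(individuals)) stopf("duplicate individual ids")
  if (anyDuplicated(loci)) stopf("duplicate locus names")
  a1 <- matrix(as.integer(allele1), nrow = length(individuals))
  a2 <- matrix(as.integer(allele2), nrow = length(individuals))
  if (!all(dim(a1) == c(length(individuals), length(loci))) ||
      !all(dim(a2) == dim(a1)))
    stopf("allele matrices must be individuals x loci")
  if (any(xor(is.na(a1), is.na(a2))))
    stopf("half-missing calls are not allowed")
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0L) || any(a2[ok] <= 0L))
    stopf("allele labels must be positive integers")
  swap <- ok & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(list(individuals = individuals, loci = loci,
                 allele1 = a1, allele2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d loci, %.1f%% missing>\n",
              length(x$individuals), length(x$loci),
              100 * mean(is.na(x$allele1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$individuals), length(x$loci))

parse_call <- function(cell) {
  # "a/b" -> c(a, b); "a" -> c(a, a); "NA"/"" -> c(NA, NA)
  cell <- trimws(cell)
  if (is.na(cell) || cell == "" || cell == "NA") return(c(NA_integer_, NA_integer_))
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  if (length(parts) != 2L || any(!grepl("^[0-9]+$", parts)))
    stopf("malformed genotype call '%s'", cell)
  as.integer(parts)
}

#' Read a genotype CSV
#'
#' Expects a header row of locus names, a first column of individual ids, and
#' cells of the form `a/b` (allele sizes in bp), `a` (homozygote shorthand,
#' expanded to `a/a`) or `NA` for missing.
#'
#' @param path Path to the CSV file.
#' @return A [genotype_matrix()].
#' @export
read_genotype_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character"),
    error = function(e) stopf("genotype CSV format error: %s", conditionMessage(e)))
  if (ncol(df) < 2L) stopf("genotype CSV needs an id column plus loci")
  inds <- df[[1]]
  loci <- colnames(df)[-1]
  n <- length(inds); L <- length(loci)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) for (i in seq_len(n)) {
    call <- tryCatch(parse_call(df[i, j + 1L]), error = function(e)
      stopf("individual '%s', locus '%s': %s", inds[i], loci[j], conditionMessage(e)))
    a1[i, j] <- call[1]; a2[i, j] <- call[2]
  }
  genotype_matrix(inds, loci, a1, a2)
}

#' Write a genotype CSV
#'
#' Inverse of [read_genotype_csv()]; heterozygotes are written `a/b` with the
#' smaller allele first, homozygotes `a/a`, missing calls `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_csv <- function(gm, path) {
  cells <- matrix(ifelse(is.na(gm$allele1), "NA",
                         paste0(gm$allele1, "/", gm$allele2)),
                  nrow = length(gm$individuals))
  df <- data.frame(individual = gm$individuals, cells, check.names = FALSE)
  colnames(df) <- c("individual", gm$loci)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
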