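#' Sequence records
#'
#' A `seq_record` is one FASTA/FASTQ entry: an identifier, an optional free-text
#' description, the residues (uppercase, alphabet `A`, `C`, `G`, `T`, `N`), and
#' per-base Phred quality scores when the record came from FASTQ. Coordinates
#' reported against records anywhere in this package are 1-based inclusive.
#'
#' @param id Non-empty identifier token (no whitespace).
#' @param residues Sequence string; lower case is accepted and uppercased.
#' @param description Free text after the first whitespace of the header.
#' @param qualities Optional integer vector of Phred scores, one per base.
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("s1", "ACGTACGT")
#' @export
seq_record <- function(id, residues, description = "", qualities = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stopf("record id must be a single non-empty token")
  residues <- toupper(residues)
  if (nchar(residues) < 1L) stopf("record '%s': empty sequence", id)
  bad <- regexpr("[^ACGTN]", residues)
  if (bad > 0)
    stopf("record '%s': illegal residue '%s' at position %d",
          id, substr(residues, bad, bad), bad)
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(residues) || any(qualities < 0L))
      stopf("record '%s': qualities must be non-negative, one per base", id)
  }
  structure(list(id = id, description = description,
                 residues = residues, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s: %d bp%s>\n", x$id, nchar(x$residues),
              if (is.null(x$qualities)) "" else ", with qualities"))
  invisible(x)
}

record_lengths <- function(records) vapply(records, function(r) nchar(r$residues), integer(1))

#' Read a FASTA file
#'
#' Reads plain or gzip-compressed FASTA (compression detected by the `.gz`
#' suffix). Multi-line sequence bodies are concatenated, residues are
#' uppercased, and any character outside `A/C/G/T/N` (including IUPAC
#' ambiguity codes) is rejected with the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stopf("FASTA format error in %s: %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) stopf("no records in %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  mapply(function(i, d, s) seq_record(i, s, description = d),
         ids, desc, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTA
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for the sequence body.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(length(records) >= 1L)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A list of [seq_record()] objects carrying qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stopf("FASTQ format error in %s: %s",
                              path, conditionMessage(e)))
  if (length(set) == 0L) stopf("no records in %s", path)
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  mapply(function(i, d, s, q)
    seq_record(i, s, description = d,
               qualities = as.integer(charToRaw(q)) - 33L),
    ids, desc, as.character(set), quals, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to FASTQ (Phred+33)
#'
#' @inheritParams write_fasta
#' @export
write_fastq <- function(records, path) {
  stopifnot(length(records) >= 1L)
  lines <- unlist(lapply(records, function(r) {
    if (is.null(r$qualities)) stopf("record '%s' has no qualities", r$id)
    c(paste0("@", if (nzchar(r$description)) paste(r$id, r$description) else r$id),
      r$residues, "+",
      rawToChar(as.raw(r$qualities + 33L)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Summarise base qualities of a read set
#'
#' Computes the standard sequencing-report quantities: Q20/Q30 are the
#' percentages of bases with Phred score at least 20/30, GC content is
#' `100 * (G + C) / (A + C + G + T)` (N excluded), and the error rate is the
#' mean per-base error probability `100 * mean(10^(-Q/10))`.
#'
#' @param records List of [seq_record()] objects, all carrying qualities.
#' @return A one-row `data.frame` with columns `n_reads`, `n_bases`,
#'   `q20_pct`, `q30_pct`, `gc_pct`, `error_rate_pct`.
#' @export
quality_summary <- function(records) {
  if (length(records) == 0L) stopf("no reads")
  has_q <- vapply(records, function(r) !is.null(r$qualities), logical(1))
  if (!all(has_q))
    stopf("record '%s' has no qualities", records[[which(!has_q)[1]]]$id)
  q <- unlist(lapply(records, `[[`, "qualities"), use.names = FALSE)
  n_bases <- length(q)
  data.frame(
    n_reads = length(records),
    n_bases = n_bases,
    q20_pct = 100 * sum(q >= 20L) / n_bases,
    q30_pct = 100 * sum(q >= 30L) / n_bases,
    gc_pct = gc_pct_of(vapply(records, `[[`, character(1), "residues")),
    error_rate_pct = 100 * mean(10^(-q / 10))
  )
}
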