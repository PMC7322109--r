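# shared internal helpers

.DNA <- c("A", "C", "G", "T")

# reverse complement of plain character strings (vectorised)
rc <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# TRUE if motif is not a whole-number power of a shorter string
is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p <= 1L) return(TRUE)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L &&
        motif == strrep(substr(motif, 1L, q), p %/% q)) {
      return(FALSE)
    }
  }
  TRUE
}

# GC percentage of character sequences, N excluded from both counts
gc_pct_of <- function(seqs) {
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  gc <- sum(chars == "G" | chars == "C")
  at <- sum(chars == "A" | chars == "T")
  if (gc + at == 0) stop("no unambiguous bases to compute GC content from")
  100 * gc / (gc + at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
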