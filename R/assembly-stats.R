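#' Nx length of an assembly
#'
#' Sorts the contig/scaffold lengths in decreasing order and returns the
#' length at which the cumulative sum first reaches `x` percent of the total
#' assembly length (N50, N90, ...).
#'
#' @param lengths Vector of sequence lengths in bp, all >= 1.
#' @param x Percentage in (0, 100).
#' @return The Nx length in bp.
#' @export
nx_length <- function(lengths, x) {
  if (!length(lengths)) stopf("no lengths")
  stopifnot(all(lengths >= 1), x > 0, x < 100)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= x / 100 * sum(s))[1]]
}

#' Pooled GC content of records passing a length filter
#'
#' GC percentage `100 * (G + C) / (A + C + G + T)` pooled over all records of
#' length >= `min_len`; `N` bases are excluded from numerator and denominator.
#' The default filter of 500 bp follows the convention of computing assembly
#' GC content on contigs of at least 500 bp.
#'
#' @param records List of [seq_record()] objects.
#' @param min_len Minimum record length in bp (inclusive boundary).
#' @return GC percentage.
#' @export
gc_content <- function(records, min_len = 500) {
  lens <- record_lengths(records)
  keep <- lens >= min_len
  if (!any(keep)) stopf("no record passes the %d bp length filter", min_len)
  gc_pct_of(vapply(records[keep], `[[`, character(1), "residues"))
}

#' Assembly summary statistics
#'
#' Total length and sequence count, the count of sequences longer than 2 kb,
#' maximum length, N50 and N90, and the pooled GC content over records of
#' length >= `gc_min_len`.
#'
#' @param records List of [seq_record()] objects.
#' @param gc_min_len Length filter for the GC computation.
#' @return A one-row `data.frame` with columns `total_length_bp`,
#'   `total_number`, `number_gt_2kb`, `max_length_bp`, `n50_bp`, `n90_bp`,
#'   `gc_pct`.
#' @export
summarize_assembly <- function(records, gc_min_len = 500) {
  if (!length(records)) stopf("no records")
  lens <- record_lengths(records)
  data.frame(
    total_length_bp = sum(lens),
    total_number = length(lens),
    number_gt_2kb = sum(lens > 2000L),
    max_length_bp = max(lens),
    n50_bp = nx_length(lens, 50),
    n90_bp = nx_length(lens, 90),
    gc_pct = if (any(lens >= gc_min_len)) gc_content(records, gc_min_len) else NA_real_
  )
}
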