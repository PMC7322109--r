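# Independent oracles used across the suite. These deliberately re-derive
# results through different mechanisms than the package implementation
# (regex scanning, stats::hclust, nested-loop enumeration).

# Regex-based perfect-SSR scanner: PCRE backreference repetition gives
# leftmost maximal whole-unit runs per period; the same primitivity,
# threshold and smaller-period-wins rules as the miner contract are then
# applied on top.
oracle_find_ssrs <- function(records,
                             min_repeats = default_min_repeats(),
                             min_scaffold_len = 1000) {
  out <- list()
  for (rec in records) {
    s <- rec$residues
    if (nchar(s) < min_scaffold_len) next
    cand <- NULL
    for (p in 1:6) {
      need <- min_repeats[[as.character(p)]]
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, need - 1L)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      for (i in seq_along(m)) {
        motif <- substr(s, m[i], m[i] + p - 1L)
        primitive <- TRUE
        for (q in seq_len(p - 1L)) {
          if (p %% q == 0L && motif == strrep(substr(motif, 1L, q), p %/% q))
            primitive <- FALSE
        }
        if (!primitive) next
        cand <- rbind(cand, data.frame(
          start = as.integer(m[i]), end = as.integer(m[i] + lens[i] - 1L),
          period = p, motif = motif, repeats = lens[i] %/% p))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(cand$period, cand$start), , drop = FALSE]
    kept <- rep(FALSE, nrow(cand))
    occ <- NULL
    for (i in seq_len(nrow(cand))) {
      if (is.null(occ) || !any(cand$start[i] <= occ$end & cand$end[i] >= occ$start)) {
        kept[i] <- TRUE
        occ <- rbind(occ, cand[i, c("start", "end")])
      }
    }
    cand <- cand[kept, , drop = FALSE]
    cand$scaffold_id <- rec$id
    out[[length(out) + 1L]] <- cand
  }
  if (!length(out)) {
    return(data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      motif = character(0), repeats = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold_id, res$start),
             c("scaffold_id", "start", "end", "period", "motif", "repeats")]
  rownames(res) <- NULL
  res
}

# Brute-force primer-pair enumerator: plain loops over every window with the
# constraint checks spelt out one by one, then every admissible pairing.
oracle_windows <- function(s, from, to, cs, strand) {
  rows <- list()
  for (start in from:to) {
    for (len in cs$primer_len[1]:cs$primer_len[2]) {
      end <- start + len - 1L
      if (end > nchar(s)) next
      w <- substr(s, start, end)
      if (grepl("N", w)) next
      p <- if (strand == "fwd") w else
        paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]), collapse = "")
      gc <- 100 * sum(strsplit(p, "")[[1]] %in% c("G", "C")) / len
      if (gc < cs$gc[1] || gc > cs$gc[2]) next
      tm <- melting_temp(p)
      if (tm < cs$tm[1] || tm > cs$tm[2]) next
      rows[[length(rows) + 1L]] <- data.frame(start = start, end = end,
                                              len = len, seq = p,
                                              gc = gc, tm = tm)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

oracle_design <- function(record, locus, cs = primer_constraints()) {
  s <- record$residues
  L <- nchar(s)
  if (locus$start < 2L || locus$end >= L) return(NULL)
  fwd <- oracle_windows(s, 1L, locus$start - 1L, cs, "fwd")
  rev_ <- oracle_windows(s, locus$end + 1L, L, cs, "rev")
  if (is.null(fwd)) return(NULL)
  fwd <- fwd[fwd$end < locus$start, , drop = FALSE]
  if (is.null(rev_)) return(NULL)
  rev_ <- rev_[rev_$start > locus$end, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev_))) {
    prod <- rev_$end[j] - fwd$start[i] + 1L
    if (prod < cs$product_len[1] || prod > cs$product_len[2]) next
    score <- abs(prod - cs$opt_product) +
      abs(fwd$len[i] - cs$opt_len) + abs(rev_$len[j] - cs$opt_len) +
      abs(fwd$gc[i] - cs$opt_gc) + abs(rev_$gc[j] - cs$opt_gc) +
      abs(fwd$tm[i] - cs$opt_tm) + abs(rev_$tm[j] - cs$opt_tm)
    rows[[length(rows) + 1L]] <- data.frame(
      fwd_seq = fwd$seq[i], rev_seq = rev_$seq[j],
      fwd_start = fwd$start[i], rev_end = rev_$end[j],
      product_len = prod, score = score)
  }
  if (!length(rows)) return(NULL)
  res <- do.call(rbind, rows)
  res[order(res$score, res$fwd_start, res$product_len), , drop = FALSE]
}

# i.i.d. random scaffold record at a given GC fraction
random_record <- function(id, len, gc = 0.37) {
  seq_record(id, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                       collapse = ""))
}

# cophenetic distances (1 - GSC scale) from the stats::hclust oracle
oracle_upgma_cophenetic <- function(sim) {
  hc <- stats::hclust(stats::as.dist(1 - unclass(sim)), method = "average")
  as.matrix(stats::cophenetic(hc))
}
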