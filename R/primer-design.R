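# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K), 1 M NaCl reference.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Oligo melting temperature
#'
#' `wallace` is the 2/4 rule `2*(A+T) + 4*(G+C)` degrees C, useful for
#' hand-checkable arithmetic. `nearest_neighbor` (the default used in primer
#' scoring) applies the SantaLucia 1998 unified duplex parameters with the
#' salt entropy correction `dS += 0.368 * (n-1) * ln[Na+]` at `na_mM`
#' millimolar monovalent cation and a non-self-complementary oligo
#' concentration term `R * ln(C/4)`:
#' `Tm = 1000*dH / (dS + R*ln(C/4)) - 273.15`.
#'
#' @param seq Primer sequence(s), `A/C/G/T` only, length >= 8.
#' @param method `"nearest_neighbor"` or `"wallace"`.
#' @param na_mM Monovalent salt concentration in mM.
#' @param oligo_uM Oligo concentration in micromolar.
#' @return Melting temperature(s) in degrees Celsius.
#' @export
melting_temp <- function(seq, method = c("nearest_neighbor", "wallace"),
                         na_mM = 50, oligo_uM = 0.25) {
  method <- match.arg(method)
  seq <- toupper(seq)
  vapply(seq, function(s) {
    if (grepl("[^ACGT]", s)) stopf("primer contains a non-ACGT base: %s", s)
    n <- nchar(s)
    if (n < 8L) stopf("primer too short for a melting temperature (%d < 8)", n)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (method == "wallace")
      return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
    steps <- paste0(ch[-n], ch[-1])
    ends <- ifelse(ch[c(1L, n)] %in% c("G", "C"), "GC", "AT")
    dH <- sum(NN_DH[steps]) + sum(NN_INIT_DH[ends])
    dS <- sum(NN_DS[steps]) + sum(NN_INIT_DS[ends]) +
      0.368 * (n - 1) * log(na_mM / 1000)
    1000 * dH / (dS + 1.987 * log(oligo_uM * 1e-6 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer design constraint envelope
#'
#' The default bounds are the standard SSR-marker screening envelope:
#' product 100-300 bp, primer 18-27 bases, GC 40-70%, Tm 57-63 degrees C,
#' with scoring optima 200 bp / 20 bases / 50% / 60 degrees C.
#'
#' @param product_len,primer_len,gc,tm Length-2 numeric ranges (min, max).
#' @param opt_product,opt_len,opt_gc,opt_tm Scoring optima, inside the ranges.
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(product_len = c(100, 300),
                               primer_len = c(18, 27),
                               gc = c(40, 70),
                               tm = c(57, 63),
                               opt_product = 200, opt_len = 20,
                               opt_gc = 50, opt_tm = 60) {
  cs <- list(product_len = product_len, primer_len = primer_len,
             gc = gc, tm = tm,
             opt_product = opt_product, opt_len = opt_len,
             opt_gc = opt_gc, opt_tm = opt_tm)
  for (rng in cs[1:4]) stopifnot(length(rng) == 2L, rng[1] <= rng[2])
  stopifnot(opt_product >= product_len[1], opt_product <= product_len[2],
            opt_len >= primer_len[1], opt_len <= primer_len[2],
            opt_gc >= gc[1], opt_gc <= gc[2],
            opt_tm >= tm[1], opt_tm <= tm[2])
  structure(cs, class = "primer_constraints")
}

# All windows of lengths in the constraint range with start in [lo, hi] that
# satisfy the per-primer GC and Tm constraints; seq is given as the primer
# would read (reverse complement of the template window for "rev"). GC% and
# the nearest-neighbor Tm of a primer equal those of its template window
# because the unified duplex parameters are reverse-complement symmetric, so
# both orientations are scored from cumulative sums over the template.
primer_windows <- function(template, lo, hi, cs, orientation,
                           na_mM = 50, oligo_uM = 0.25) {
  L <- nchar(template)
  lo <- max(1L, lo); hi <- min(hi, L)
  if (hi < lo) return(NULL)
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  cum0 <- function(x) c(0, cumsum(x))
  cN <- cum0(ch == "N")
  cGC <- cum0(ch == "G" | ch == "C")
  steps <- paste0(ch[-L], ch[-1])
  dh <- unname(NN_DH[steps]); ds <- unname(NN_DS[steps])
  dh[is.na(dh)] <- 0; ds[is.na(ds)] <- 0   # N-containing steps; those windows drop out
  cdh <- cum0(dh); cds <- cum0(ds)
  grid <- expand.grid(start = lo:hi, len = seq(cs$primer_len[1], cs$primer_len[2]))
  grid$end <- grid$start + grid$len - 1L
  grid <- grid[grid$end <= L, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid <- grid[cN[grid$end + 1L] - cN[grid$start] == 0, , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  gc <- 100 * (cGC[grid$end + 1L] - cGC[grid$start]) / grid$len
  keep <- gc >= cs$gc[1] & gc <= cs$gc[2]
  grid <- grid[keep, , drop = FALSE]; gc <- gc[keep]
  if (!nrow(grid)) return(NULL)
  end_gc <- ifelse(ch[grid$start] %in% c("G", "C"), "GC", "AT")
  other_gc <- ifelse(ch[grid$end] %in% c("G", "C"), "GC", "AT")
  dH <- cdh[grid$end] - cdh[grid$start] +
    NN_INIT_DH[end_gc] + NN_INIT_DH[other_gc]
  dS <- cds[grid$end] - cds[grid$start] +
    NN_INIT_DS[end_gc] + NN_INIT_DS[other_gc] +
    0.368 * (grid$len - 1) * log(na_mM / 1000)
  tm <- unname(1000 * dH / (dS + 1.987 * log(oligo_uM * 1e-6 / 4)) - 273.15)
  keep <- tm >= cs$tm[1] & tm <= cs$tm[2]
  if (!any(keep)) return(NULL)
  grid <- grid[keep, , drop = FALSE]
  win <- substring(template, grid$start, grid$end)
  data.frame(start = grid$start, end = grid$end, len = grid$len,
             seq = if (orientation == "fwd") win else rc(win),
             gc = gc[keep], tm = tm[keep])
}

#' Design primer pairs flanking an SSR locus
#'
#' Exhaustively enumerates every (forward window, reverse window) pair on the
#' template such that the forward primer lies entirely upstream of the locus,
#' the reverse primer entirely downstream, the product spans the locus, and
#' every constraint of `constraints` holds. Candidates are scored by the
#' unweighted L1 deviation from the optima (product length, both primer
#' lengths, GC percentages and Tm values); the best `max_returned` pairs are
#' returned, ties broken by leftmost forward start, then shortest product.
#'
#' @param record The [seq_record()] the locus lies on.
#' @param locus One row of the [find_ssrs()] table (or any list with `start`
#'   and `end` 1-based template coordinates).
#' @param constraints A [primer_constraints()].
#' @param max_returned Number of pairs to return.
#' @return A `data.frame` of primer pairs (zero rows when no pair satisfies
#'   the constraints): `locus_id`, `fwd_seq`, `rev_seq`, `fwd_start`,
#'   `rev_end` (1-based template coordinates), `product_len`, `fwd_tm`,
#'   `rev_tm`, `fwd_gc`, `rev_gc`, `score`.
#' @export
design_for_locus <- function(record, locus, constraints = primer_constraints(),
                             max_returned = 1L) {
  cs <- constraints
  s <- record$residues
  L <- nchar(s)
  empty <- data.frame(locus_id = character(0), fwd_seq = character(0),
                      rev_seq = character(0), fwd_start = integer(0),
                      rev_end = integer(0), product_len = integer(0),
                      fwd_tm = numeric(0), rev_tm = numeric(0),
                      fwd_gc = numeric(0), rev_gc = numeric(0),
                      score = numeric(0))
  if (locus$start < 1L || locus$end > L) stopf("locus does not lie on the record")
  locus_id <- if (!is.null(locus$scaffold_id))
    sprintf("%s:%d-%d", locus$scaffold_id, locus$start, locus$end)
  else sprintf("%s:%d-%d", record$id, locus$start, locus$end)
  max_prod <- cs$product_len[2]
  fwd <- primer_windows(s, locus$start - max_prod + 1L, locus$start - 1L, cs, "fwd")
  if (!is.null(fwd)) fwd <- fwd[fwd$end < locus$start, , drop = FALSE]
  rev <- primer_windows(s, locus$end + 1L, min(L, locus$end + max_prod), cs, "rev")
  if (!is.null(rev)) rev <- rev[rev$start > locus$end, , drop = FALSE]
  if (is.null(fwd) || is.null(rev) || !nrow(fwd) || !nrow(rev)) return(empty)
  pairs <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  prod_len <- rev$end[pairs$r] - fwd$start[pairs$f] + 1L
  keep <- prod_len >= cs$product_len[1] & prod_len <= cs$product_len[2]
  if (!any(keep)) return(empty)
  pairs <- pairs[keep, , drop = FALSE]
  prod_len <- prod_len[keep]
  f <- fwd[pairs$f, ]; r <- rev[pairs$r, ]
  score <- abs(prod_len - cs$opt_product) +
    abs(f$len - cs$opt_len) + abs(r$len - cs$opt_len) +
    abs(f$gc - cs$opt_gc) + abs(r$gc - cs$opt_gc) +
    abs(f$tm - cs$opt_tm) + abs(r$tm - cs$opt_tm)
  out <- data.frame(locus_id = locus_id, fwd_seq = f$seq, rev_seq = r$seq,
                    fwd_start = f$start, rev_end = r$end,
                    product_len = prod_len,
                    fwd_tm = f$tm, rev_tm = r$tm,
                    fwd_gc = f$gc, rev_gc = r$gc, score = score)
  out <- out[order(out$score, out$fwd_start, out$product_len), , drop = FALSE]
  out <- utils::head(out, max_returned)
  rownames(out) <- NULL
  out
}

#' Collapse redundant primer pairs across loci
#'
#' Pairs with an identical (forward sequence, reverse sequence) combination
#' amplify the same product family; only the first by input order is kept.
#'
#' @param pairs `data.frame` of primer pairs from [design_for_locus()],
#'   possibly concatenated across loci.
#' @return The deduplicated `data.frame`.
#' @export
dedupe_pairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  keep <- !duplicated(paste(pairs$fwd_seq, pairs$rev_seq, sep = "|"))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
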