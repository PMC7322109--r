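#' Canonical class of an SSR motif
#'
#' Repeat units that are cyclic rotations of each other, or rotations of each
#' other's reverse complement, describe the same microsatellite; survey
#' tables therefore group motifs into canonical classes such as `A/T`,
#' `AT/AT` or `AAT/ATT`. The class representative `X` is the
#' lexicographically smallest string among all rotations of the motif and all
#' rotations of its reverse complement; the class is formatted `X/Y` with
#' `Y = reverse complement of X`.
#'
#' @param motif Character vector of primitive repeat units over `A/C/G/T`,
#'   length 1-6.
#' @return Character vector of class labels `"X/Y"`.
#' @export
canonical_class <- function(motif) {
  vapply(toupper(motif), function(m) {
    p <- nchar(m)
    if (p < 1L || p > 6L || grepl("[^ACGT]", m))
      stopf("motif must be 1-6 bases over A/C/G/T, got '%s'", m)
    if (!is_primitive(m))
      stopf("motif '%s' is not primitive", m)
    rots <- function(s) {
      i <- seq_len(p)
      vapply(i, function(j) paste0(substr(s, j, p), substr(s, 1, j - 1L)),
             character(1))
    }
    x <- min(c(rots(m), rots(rc(m))))
    paste0(x, "/", rc(x))
  }, character(1), USE.NAMES = FALSE)
}

ssr_type_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Default MISA-style minimum repeat numbers
#'
#' Minimum repeat counts per motif length (period 1-6): 10 for
#' mononucleotides, 6 for dinucleotides and 5 for tri- to hexanucleotides.
#'
#' @return Named integer vector, names `"1"`..`"6"`.
#' @export
default_min_repeats <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

# candidate perfect-repeat runs of one period in one sequence
find_runs_one_period <- function(s, p, min_rep) {
  L <- nchar(s)
  if (L < p * min_rep) return(NULL)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  eq <- ch[seq_len(L - p)] == ch[(p + 1L):L] & ch[seq_len(L - p)] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= p * (min_rep - 1L)  # stretch len = run + p
  if (!any(keep)) return(NULL)
  out <- lapply(which(keep), function(i) {
    st <- starts[i]
    stretch_len <- r$lengths[i] + p
    n_units <- stretch_len %/% p
    if (n_units < min_rep) return(NULL)
    motif <- substr(s, st, st + p - 1L)
    if (!is_primitive(motif)) return(NULL)  # reported at its smaller period
    data.frame(start = st, end = st + p * n_units - 1L,
               period = p, motif = motif, repeats = n_units)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out)) do.call(rbind, out) else NULL
}

#' Mine perfect SSRs from scaffolds
#'
#' MISA-style detection of perfect microsatellites: a locus is a maximal run
#' of a primitive motif of period 1-6 repeated at least `min_repeats[period]`
#' times. Maximality is in whole units: a trailing or leading partial unit
#' neither extends the repeat count nor the reported coordinates. Runs are
#' broken at `N`; records shorter than `min_scaffold_len` are skipped
#' entirely; a run reportable at several periods is reported once at its
#' smallest qualifying period, and of two overlapping candidate loci the one
#' with the smaller period wins. Coordinates are 1-based inclusive.
#'
#' @param records List of [seq_record()] objects.
#' @param min_repeats Named vector of minimum repeat counts per period, as
#'   [default_min_repeats()].
#' @param min_scaffold_len Minimum record length to scan (>= , in bp).
#' @return A `data.frame` with columns `scaffold_id`, `start`, `end`,
#'   `period`, `motif`, `class` (canonical class), `repeats`, `type`
#'   (`mono`..`hexa`), sorted by scaffold then start. Zero rows when nothing
#'   is found.
#' @export
find_ssrs <- function(records, min_repeats = default_min_repeats(),
                      min_scaffold_len = 1000) {
  stopifnot(all(min_repeats >= 2))
  empty <- data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      motif = character(0), class = character(0),
                      repeats = integer(0), type = character(0))
  per_record <- lapply(records, function(rec) {
    if (nchar(rec$residues) < min_scaffold_len) return(NULL)
    cands <- lapply(1:6, function(p)
      find_runs_one_period(rec$residues, p, min_repeats[[as.character(p)]]))
    cands <- cands[!vapply(cands, is.null, logical(1))]
    if (!length(cands)) return(NULL)
    cand <- do.call(rbind, cands)
    # smaller periods take precedence when candidate loci overlap
    cand <- cand[order(cand$period, cand$start), , drop = FALSE]
    kept <- logical(nrow(cand))
    occupied_start <- integer(0); occupied_end <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!any(cand$start[i] <= occupied_end & cand$end[i] >= occupied_start)) {
        kept[i] <- TRUE
        occupied_start <- c(occupied_start, cand$start[i])
        occupied_end <- c(occupied_end, cand$end[i])
      }
    }
    cand <- cand[kept, , drop = FALSE]
    cand$scaffold_id <- rec$id
    cand
  })
  per_record <- per_record[!vapply(per_record, is.null, logical(1))]
  if (!length(per_record)) return(empty)
  loci <- do.call(rbind, per_record)
  loci$class <- canonical_class(loci$motif)
  loci$type <- ssr_type_names[loci$period]
  loci <- loci[order(loci$scaffold_id, loci$start),
               c("scaffold_id", "start", "end", "period", "motif",
                 "class", "repeats", "type")]
  rownames(loci) <- NULL
  loci
}

repeat_bins <- c("5", "6", "7", "8", "9", "10", "11-20", ">20")

bin_repeat_count <- function(n) {
  ifelse(n <= 10, as.character(n), ifelse(n <= 20, "11-20", ">20"))
}

#' Percentage breakdown of an SSR motif distribution
#'
#' Given per-class locus counts, computes each class's share of its period
#' total and each period's share of the grand total. Totals default to the
#' sums of the supplied counts, but explicit period or grand totals can be
#' given to reproduce the arithmetic of an externally tabulated distribution
#' whose printed subtotals differ from the row sums.
#'
#' @param class_counts `data.frame` with columns `class`, `type` (one of
#'   `mono`..`hexa`) and `count`.
#' @param period_totals Optional named vector of per-type totals.
#' @param grand_total Optional grand total.
#' @return A list with `classes` (class, type, count, pct_of_period) and
#'   `periods` (type, count, pct_of_total), percentages rounded to 2 dp.
#' @export
ssr_percentages <- function(class_counts, period_totals = NULL,
                            grand_total = NULL) {
  stopifnot(all(c("class", "type", "count") %in% names(class_counts)))
  derived <- tapply(class_counts$count, class_counts$type, sum)
  if (is.null(period_totals)) period_totals <- derived
  if (is.null(grand_total)) grand_total <- sum(class_counts$count)
  cls <- class_counts[, c("class", "type", "count")]
  cls$pct_of_period <- round(100 * cls$count /
                               as.numeric(period_totals[as.character(cls$type)]), 2)
  types <- intersect(ssr_type_names, unique(as.character(class_counts$type)))
  per <- data.frame(type = types,
                    count = as.numeric(period_totals[types]),
                    pct_of_total = round(100 * as.numeric(period_totals[types]) /
                                           grand_total, 2))
  rownames(per) <- NULL
  list(classes = cls, periods = per)
}

#' Summarise mined SSR loci
#'
#' Builds the survey-style motif distribution (per canonical class, binned by
#' repeat count into 5, 6, 7, 8, 9, 10, 11-20 and >20) with percentage
#' columns, and the mean inter-SSR distance
#' `total_scanned_length / n_loci / 1000` kb (2 dp).
#'
#' @param loci `data.frame` from [find_ssrs()].
#' @param total_scanned_length Total length in bp of the scaffolds scanned.
#' @return A list of class `ssr_summary` with elements `distribution` (class
#'   x repeat-count-bin counts plus `total`), `percentages` (see
#'   [ssr_percentages()]), `n_loci`, `total_scanned_length` and
#'   `mean_distance_kb` (`NA` when no loci were found).
#' @export
summarize_ssrs <- function(loci, total_scanned_length) {
  stopifnot(total_scanned_length > 0)
  n <- nrow(loci)
  if (n == 0L) {
    dist <- matrix(0L, 0, length(repeat_bins) + 1L,
                   dimnames = list(NULL, c(repeat_bins, "total")))
    return(structure(list(distribution = as.data.frame(dist),
                          percentages = NULL, n_loci = 0L,
                          total_scanned_length = total_scanned_length,
                          mean_distance_kb = NA_real_),
                     class = "ssr_summary"))
  }
  lev <- repeat_bins
  if (any(loci$repeats < 5))   # only reachable with thresholds below the MISA defaults
    lev <- c(as.character(sort(unique(loci$repeats[loci$repeats < 5]))), lev)
  bins <- factor(bin_repeat_count(loci$repeats), levels = lev)
  keys <- paste(loci$type, loci$class, sep = ":")
  ord <- order(match(loci$type, ssr_type_names), loci$class)
  keys_u <- unique(keys[ord])
  tab <- table(factor(keys, levels = keys_u), bins)
  dist <- as.data.frame.matrix(tab)
  dist$total <- rowSums(dist)
  info <- do.call(rbind, strsplit(keys_u, ":", fixed = TRUE))
  dist <- cbind(data.frame(type = info[, 1], class = info[, 2]), dist)
  rownames(dist) <- NULL
  pct <- ssr_percentages(data.frame(class = dist$class, type = dist$type,
                                    count = dist$total))
  structure(list(distribution = dist, percentages = pct, n_loci = n,
                 total_scanned_length = total_scanned_length,
                 mean_distance_kb = round(total_scanned_length / n / 1000, 2)),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf("<ssr_summary: %d loci over %.2f Mb, mean distance %s kb>\n",
              x$n_loci, x$total_scanned_length / 1e6,
              if (is.na(x$mean_distance_kb)) "-" else
                format(x$mean_distance_kb)))
  invisible(x)
}
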