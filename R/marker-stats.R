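resolve_subset <- function(gm, individuals) {
  if (is.null(individuals)) return(seq_along(gm$individuals))
  idx <- match(individuals, gm$individuals)
  if (anyNA(idx)) stopf("unknown individual(s): %s",
                        paste(individuals[is.na(idx)], collapse = ", "))
  idx
}

#' Allele frequencies at a locus
#'
#' Each non-missing diploid call contributes two allele observations;
#' frequencies sum to 1 over the observed alleles.
#'
#' @param gm A [genotype_matrix()].
#' @param locus Locus name.
#' @param individuals Optional character vector restricting the sample (e.g.
#'   one species); default all individuals.
#' @return Named numeric vector of allele frequencies.
#' @export
allele_frequencies <- function(gm, locus, individuals = NULL) {
  j <- match(locus, gm$loci)
  if (is.na(j)) stopf("unknown locus '%s'", locus)
  idx <- resolve_subset(gm, individuals)
  alleles <- c(gm$allele1[idx, j], gm$allele2[idx, j])
  alleles <- alleles[!is.na(alleles)]
  if (!length(alleles)) stopf("locus '%s' untyped in subset", locus)
  tab <- table(alleles)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Botstein polymorphism class of a PIC value
#'
#' `low` for PIC < 0.25, `high` for PIC > 0.5, `moderate` in between
#' (boundary values 0.25 and 0.5 are assigned to `moderate`).
#'
#' @param pic Numeric vector of PIC values.
#' @return Character vector `"low"/"moderate"/"high"`.
#' @export
botstein_class <- function(pic) {
  ifelse(pic < 0.25, "low", ifelse(pic > 0.5, "high", "moderate"))
}

#' Per-locus diversity statistics
#'
#' Computes, over the (optionally subset) typed individuals at one locus:
#' the allele count Na; observed heterozygosity Ho (fraction of typed
#' individuals that are heterozygous); expected heterozygosity
#' `He = 1 - sum(fi^2)` both as-is (`he_biased`) and with the small-sample
#' correction `2n/(2n-1)` (`he_unbiased`, the value population-genetics
#' software conventionally reports); the polymorphism information content
#' `PIC = 1 - sum(fi^2)` (the gene-diversity form); and the Botstein class.
#'
#' @inheritParams allele_frequencies
#' @return A one-row `data.frame`: `locus`, `n_typed`, `na`, `ho`,
#'   `he_biased`, `he_unbiased`, `pic`, `botstein`.
#' @export
locus_stats <- function(gm, locus, individuals = NULL) {
  j <- match(locus, gm$loci)
  if (is.na(j)) stopf("unknown locus '%s'", locus)
  idx <- resolve_subset(gm, individuals)
  a1 <- gm$allele1[idx, j]; a2 <- gm$allele2[idx, j]
  typed <- !is.na(a1)
  n <- sum(typed)
  if (n == 0L) stopf("locus '%s' untyped in subset", locus)
  f <- allele_frequencies(gm, locus, individuals)
  he <- 1 - sum(f^2)
  data.frame(locus = locus, n_typed = n,
             na = length(f),
             ho = sum(a1[typed] != a2[typed]) / n,
             he_biased = he,
             he_unbiased = 2 * n / (2 * n - 1) * he,
             pic = he,
             botstein = botstein_class(he))
}

#' Per-locus statistics for many loci
#'
#' Applies [locus_stats()] across loci; loci untyped in the subset are
#' reported as `NA` rows (printed as dashes in survey tables).
#'
#' @inheritParams allele_frequencies
#' @param loci Character vector of loci; default all.
#' @return A `data.frame`, one row per locus.
#' @export
locus_stats_table <- function(gm, loci = NULL, individuals = NULL) {
  loci <- loci %||% gm$loci
  do.call(rbind, lapply(loci, function(l) {
    tryCatch(locus_stats(gm, l, individuals), error = function(e)
      data.frame(locus = l, n_typed = 0L, na = NA_integer_, ho = NA_real_,
                 he_biased = NA_real_, he_unbiased = NA_real_,
                 pic = NA_real_, botstein = NA_character_))
  }))
}

#' Panel summary of marker diversity
#'
#' Totals and unweighted means over loci of the per-locus statistics, plus
#' the tally of Botstein polymorphism classes. Accepts either the output of
#' [locus_stats_table()] or any `data.frame` with columns `na`, `pic`, `ho`
#' and `he` (or `he_unbiased`), so a printed marker table can be summarised
#' directly.
#'
#' @param stats Per-locus statistics table; `NA` rows (untyped loci) are
#'   dropped.
#' @return A list: `n_loci`, `total_alleles`, `mean_na`, `mean_ho`,
#'   `mean_he`, `mean_pic`, `range_na`, `range_pic`, and `class_counts`
#'   (named vector low/moderate/high).
#' @export
summarize_panel <- function(stats) {
  he_col <- if ("he" %in% names(stats)) "he" else "he_unbiased"
  stopifnot(all(c("na", "pic", "ho", he_col) %in% names(stats)))
  stats <- stats[!is.na(stats$na), , drop = FALSE]
  if (!nrow(stats)) stopf("no typed loci to summarise")
  cls <- if ("botstein" %in% names(stats)) stats$botstein else botstein_class(stats$pic)
  list(n_loci = nrow(stats),
       total_alleles = sum(stats$na),
       mean_na = mean(stats$na),
       mean_ho = mean(stats$ho),
       mean_he = mean(stats[[he_col]]),
       mean_pic = mean(stats$pic),
       range_na = range(stats$na),
       range_pic = range(stats$pic),
       class_counts = c(low = sum(cls == "low"),
                        moderate = sum(cls == "moderate"),
                        high = sum(cls == "high")))
}
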