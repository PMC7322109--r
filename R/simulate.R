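#' Scaffold simulation spec
#'
#' Describes a synthetic genome fragment set: i.i.d. background residues at a
#' target GC fraction with perfect SSRs planted at known positions, emulating
#' the length-filtered scaffold sets that genome-survey SSR mining runs on.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param length_range Length-2 vector (min, max) scaffold length in bp.
#' @param gc_target Background GC fraction in (0, 1).
#' @param planted_ssrs `data.frame` with columns `motif` (primitive, 1-6 bp),
#'   `repeats`, `scaffold` (index) and `start` (1-based); may have zero rows.
#'   Planted loci must not overlap and must keep >= 50 bp clear of scaffold
#'   ends.
#' @param seed Integer RNG seed; the generator is a pure function of the
#'   spec, seed included.
#' @return A list of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_scaffolds, length_range, gc_target = 0.37,
                            planted_ssrs = NULL, seed = 1L) {
  stopifnot(n_scaffolds >= 1, length(length_range) == 2L,
            length_range[1] >= 120, length_range[1] <= length_range[2],
            gc_target > 0, gc_target < 1)
  if (is.null(planted_ssrs))
    planted_ssrs <- data.frame(motif = character(0), repeats = integer(0),
                               scaffold = integer(0), start = integer(0))
  stopifnot(all(c("motif", "repeats", "scaffold", "start") %in% names(planted_ssrs)))
  if (nrow(planted_ssrs)) {
    planted_ssrs$motif <- toupper(planted_ssrs$motif)
    ok <- vapply(planted_ssrs$motif, is_primitive, logical(1))
    if (!all(ok)) stopf("planted motif '%s' is not primitive",
                        planted_ssrs$motif[!ok][1])
    stopifnot(all(planted_ssrs$scaffold >= 1),
              all(planted_ssrs$scaffold <= n_scaffolds),
              all(planted_ssrs$repeats >= 2),
              all(planted_ssrs$start > 50))
    len <- nchar(planted_ssrs$motif) * planted_ssrs$repeats
    planted_ssrs$end <- planted_ssrs$start + len - 1L
    if (any(planted_ssrs$end > length_range[1] - 50))
      stopf("planted SSR runs within 50 bp of a scaffold end")
    for (sc in unique(planted_ssrs$scaffold)) {
      rows <- planted_ssrs[planted_ssrs$scaffold == sc, ]
      rows <- rows[order(rows$start), ]
      if (nrow(rows) > 1L &&
          any(rows$start[-1] <= rows$end[-nrow(rows)]))
        stopf("planted SSRs overlap on scaffold %d", sc)
    }
  }
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 length_range = as.integer(length_range),
                 gc_target = gc_target, planted_ssrs = planted_ssrs,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

#' Simulate scaffolds with planted SSRs
#'
#' Background residues are drawn i.i.d. with `P(G) + P(C) = gc_target`; the
#' planted SSR strings are then substituted in exactly. Each scaffold is
#' redrawn (rejection sampling) until mining it with the default MISA
#' thresholds returns exactly the planted loci that pass those thresholds,
#' so the background can neither create unplanned loci nor extend a planted
#' run. The truth table carries 1-based coordinates.
#'
#' @param spec A [genome_sim_spec()].
#' @return A list: `records` (list of [seq_record()]) and `truth`
#'   (`data.frame` in the [find_ssrs()] column layout).
#' @export
simulate_scaffolds <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  thr <- default_min_repeats()
  probs <- c((1 - spec$gc_target) / 2, spec$gc_target / 2,
             spec$gc_target / 2, (1 - spec$gc_target) / 2)
  withr::with_seed(spec$seed, {
    lens <- if (spec$length_range[1] == spec$length_range[2])
      rep(spec$length_range[1], spec$n_scaffolds)
    else sample(spec$length_range[1]:spec$length_range[2],
                spec$n_scaffolds, replace = TRUE)
    records <- vector("list", spec$n_scaffolds)
    truth_rows <- vector("list", spec$n_scaffolds)
    for (i in seq_len(spec$n_scaffolds)) {
      id <- sprintf("scaffold_%03d", i)
      planted <- spec$planted_ssrs[spec$planted_ssrs$scaffold == i, , drop = FALSE]
      expected <- NULL
      if (nrow(planted)) {
        planted <- planted[order(planted$start), , drop = FALSE]
        qual <- planted$repeats >= thr[as.character(nchar(planted$motif))]
        expected <- planted[qual, , drop = FALSE]
      }
      for (attempt in 1:200) {
        s <- paste(sample(.DNA, lens[i], replace = TRUE, prob = probs),
                   collapse = "")
        if (nrow(planted)) for (r in seq_len(nrow(planted))) {
          ins <- strrep(planted$motif[r], planted$repeats[r])
          substr(s, planted$start[r], planted$start[r] + nchar(ins) - 1L) <- ins
        }
        rec <- seq_record(id, s)
        mined <- find_ssrs(list(rec), min_repeats = thr, min_scaffold_len = 1)
        want_n <- if (is.null(expected)) 0L else nrow(expected)
        ok <- nrow(mined) == want_n &&
          (want_n == 0L ||
             (all(mined$start == expected$start) &&
                all(mined$end == expected$end) &&
                all(mined$motif == expected$motif) &&
                all(mined$repeats == expected$repeats)))
        if (ok && want_n > 0L) {
          # also require exact mirrored recovery on the reverse strand, so no
          # partial repeat unit leaks into a flank in either direction
          rcrec <- seq_record(id, rc(s))
          rmined <- find_ssrs(list(rcrec), min_repeats = thr, min_scaffold_len = 1)
          ok <- nrow(rmined) == want_n &&
            all(sort(lens[i] - rmined$end + 1L) == sort(expected$start)) &&
            all(sort(lens[i] - rmined$start + 1L) == sort(expected$end)) &&
            all(rmined$repeats[order(-rmined$start)] == expected$repeats)
        }
        if (ok) break
        if (attempt == 200L)
          stopf("could not draw a clean background for scaffold %d", i)
      }
      records[[i]] <- rec
      if (!is.null(expected) && nrow(expected)) {
        truth_rows[[i]] <- data.frame(
          scaffold_id = id, start = expected$start, end = expected$end,
          period = nchar(expected$motif), motif = expected$motif,
          class = canonical_class(expected$motif),
          repeats = expected$repeats,
          type = ssr_type_names[nchar(expected$motif)])
      }
    }
  })
  truth_rows <- truth_rows[!vapply(truth_rows, is.null, logical(1))]
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(scaffold_id = character(0), start = integer(0),
               end = integer(0), period = integer(0), motif = character(0),
               class = character(0), repeats = integer(0), type = character(0))
  truth <- truth[order(truth$scaffold_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' k-mer spectrum simulation spec
#'
#' Mixture model for a diploid genome-survey k-mer histogram: erroneous
#' k-mers concentrated at depths 1-2; a heterozygous component of
#' `2 * G_unique * f_het` distinct k-mers at Poisson(coverage/2) depth, with
#' `f_het = 1 - (1 - het_rate)^k` linking the per-base rate to the k-mer
#' level; a homozygous unique component at Poisson(coverage); and repeat
#' families of copy number 2, 4 and 8 (equal genome mass) at
#' Poisson(copies * coverage), sized to put `repeat_fraction` of the genome
#' in multi-copy sequence. Defaults mirror a heterozygous, repeat-rich
#' survey at 44x coverage with 17-mers.
#'
#' @param genome_size Genome size in bp (= number of k-mer loci).
#' @param coverage k-mer coverage (the homozygous peak depth, lambda).
#' @param het_rate Per-base heterozygosity in `[0, 1)`.
#' @param repeat_fraction Fraction of the genome in multi-copy families.
#' @param error_kmer_mass Erroneous fraction of all k-mer observations.
#' @param k Odd k-mer length (15, 17, 19 or 21).
#' @param seed Integer RNG seed.
#' @return A list of class `spectrum_sim_spec`.
#' @export
spectrum_sim_spec <- function(genome_size = 1e7, coverage = 44,
                              het_rate = 0.017, repeat_fraction = 0.5,
                              error_kmer_mass = 0.05, k = 17L, seed = 1L) {
  stopifnot(genome_size >= 1e4, coverage > 0,
            het_rate >= 0, het_rate < 1,
            repeat_fraction >= 0, repeat_fraction < 1,
            error_kmer_mass >= 0, error_kmer_mass < 1,
            k %in% c(15L, 17L, 19L, 21L))
  structure(list(genome_size = genome_size, coverage = coverage,
                 het_rate = het_rate, repeat_fraction = repeat_fraction,
                 error_kmer_mass = error_kmer_mass, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "spectrum_sim_spec")
}

# multinomial draw of a depth histogram for one mixture component
component_counts <- function(n_kmers, lambda, dmax) {
  n_kmers <- round(n_kmers)
  if (n_kmers < 1) return(numeric(dmax))
  p <- stats::dpois(0:dmax, lambda)
  p[dmax + 1L] <- p[dmax + 1L] + max(0, 1 - sum(p))
  draw <- stats::rmultinom(1, n_kmers, p)[, 1]
  draw[-1L]  # depth-0 k-mers are never observed
}

#' Simulate a k-mer depth histogram
#'
#' Draws the mixture described by [spectrum_sim_spec()]. Total k-mer
#' observations concentrate around
#' `coverage * genome_size / (1 - error_kmer_mass)` and the genomic mass is
#' conserved component-wise, so the survey estimators can be validated
#' against the spec's ground truth.
#'
#' @param spec A [spectrum_sim_spec()].
#' @return A [kmer_histogram()].
#' @export
simulate_kmer_histogram <- function(spec) {
  stopifnot(inherits(spec, "spectrum_sim_spec"))
  G <- spec$genome_size; lam <- spec$coverage
  f_het <- 1 - (1 - spec$het_rate)^spec$k
  g_unique <- G * (1 - spec$repeat_fraction)
  copies <- c(2, 4, 8)
  dmax <- max(stats::qpois(1 - 1e-12, max(copies) * lam) + 20L, 50L)
  withr::with_seed(spec$seed, {
    y <- component_counts(2 * g_unique * f_het, lam / 2, dmax) +
      component_counts(g_unique * (1 - f_het), lam, dmax)
    for (m in copies) {
      y <- y + component_counts(G * spec$repeat_fraction / 3 / m, m * lam, dmax)
    }
    if (spec$error_kmer_mass > 0) {
      err_obs <- spec$error_kmer_mass / (1 - spec$error_kmer_mass) * lam * G
      y[1] <- y[1] + round(0.8 * err_obs)
      y[2] <- y[2] + round(0.1 * err_obs)  # depth-2 k-mers carry 2 obs each
    }
  })
  kmer_histogram(spec$k, seq_len(dmax), y)
}

#' Two-population genotype simulation spec
#'
#' Balding-Nichols style divergence model for diploid microsatellite panels:
#' per locus an ancestral allele-frequency vector is drawn (flat Dirichlet
#' over 2-7 alleles by default); each population's frequencies are a
#' Dirichlet perturbation with concentration `(1 - divergence) / divergence`,
#' so `divergence` acts like Fst (0 = identical populations, 1 = free
#' drift); individuals are Hardy-Weinberg draws and calls are masked missing
#' at `missing_rate`. Defaults mirror a two-species screening panel of
#' 10 + 5 individuals at 36 loci.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Integer vector of individuals per population (each >= 2).
#' @param n_loci Number of marker loci.
#' @param alleles_per_locus Length-2 range of allele counts per locus.
#' @param divergence Fst-like mixing parameter in `[0, 1]`.
#' @param missing_rate Fraction of calls masked missing.
#' @param seed Integer RNG seed.
#' @return A list of class `pop_sim_spec`.
#' @export
pop_sim_spec <- function(n_pops = 2L, n_per_pop = c(10L, 5L), n_loci = 36L,
                         alleles_per_locus = c(2L, 7L), divergence = 0.8,
                         missing_rate = 0.02, seed = 1L) {
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  stopifnot(n_pops >= 1, all(n_per_pop >= 2), n_loci >= 1,
            length(alleles_per_locus) == 2L, alleles_per_locus[1] >= 1,
            alleles_per_locus[1] <= alleles_per_locus[2],
            divergence >= 0, divergence <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_pops = as.integer(n_pops), n_per_pop = n_per_pop,
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 divergence = divergence, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "pop_sim_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1  # degenerate underflow guard
  x / sum(x)
}

#' Simulate a two-population diploid genotype panel
#'
#' @param spec A [pop_sim_spec()].
#' @return A list: `genotypes` (a [genotype_matrix()]), `populations` (named
#'   character vector individual -> population), and `truth` (list per locus
#'   of the ancestral and per-population allele-frequency vectors, names =
#'   allele sizes in bp).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "pop_sim_spec"))
  n <- sum(spec$n_per_pop)
  pops <- rep(paste0("P", seq_len(spec$n_pops)), spec$n_per_pop)
  inds <- sprintf("%s_%02d", pops, unlist(lapply(spec$n_per_pop, seq_len)))
  loci <- sprintf("L%02d", seq_len(spec$n_loci))
  a1 <- a2 <- matrix(NA_integer_, n, spec$n_loci)
  truth <- vector("list", spec$n_loci)
  names(truth) <- loci
  d <- spec$divergence
  withr::with_seed(spec$seed, {
    for (j in seq_len(spec$n_loci)) {
      n_all <- if (spec$alleles_per_locus[1] == spec$alleles_per_locus[2])
        spec$alleles_per_locus[1]
      else sample(spec$alleles_per_locus[1]:spec$alleles_per_locus[2], 1L)
      sizes <- sample(100:280, 1L) + 2L * (seq_len(n_all) - 1L)
      p0 <- rdirichlet1(rep(1, n_all))
      pop_freqs <- lapply(seq_len(spec$n_pops), function(pp) {
        if (d == 0) p0
        else if (d == 1) { out <- numeric(n_all); out[sample.int(n_all, 1, prob = p0)] <- 1; out }
        else rdirichlet1(p0 * (1 - d) / d)
      })
      names(pop_freqs) <- paste0("P", seq_len(spec$n_pops))
      for (i in seq_len(n)) {
        p <- pop_freqs[[pops[i]]]
        g <- sort(sample(sizes, 2L, replace = TRUE, prob = p))
        a1[i, j] <- g[1]; a2[i, j] <- g[2]
      }
      truth[[j]] <- c(list(ancestral = stats::setNames(p0, sizes)),
                      lapply(pop_freqs, stats::setNames, sizes))
    }
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(n * spec$n_loci) < spec$missing_rate,
                     n, spec$n_loci)
      a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
    }
  })
  list(genotypes = genotype_matrix(inds, loci, a1, a2),
       populations = stats::setNames(pops, inds),
       truth = truth)
}
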