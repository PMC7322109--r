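#' k-mer depth histogram
#'
#' The spectrum behind survey-based genome profiling: `count[i]` distinct
#' k-mers were each observed exactly `depth[i]` times in the read set. The
#' total number of k-mer observations ("k-mer number" in survey reports) is
#' `sum(depth * count)`.
#'
#' @param k Odd k-mer length the histogram was built with.
#' @param depth Integer vector of depths (multiplicities), >= 1, strictly
#'   increasing.
#' @param count Integer-valued vector of distinct-k-mer counts, >= 0.
#' @return An object of class `kmer_histogram`.
#' @export
kmer_histogram <- function(k, depth, count) {
  depth <- as.integer(depth)
  count <- as.numeric(count)  # counts can exceed .Machine$integer.max
  if (length(depth) != length(count)) stopf("depth and count lengths differ")
  if (any(depth < 1L)) stopf("depths must be >= 1")
  if (is.unsorted(depth, strictly = TRUE)) stopf("duplicate or unsorted depth")
  if (any(count < 0)) stopf("negative distinct-k-mer count")
  keep <- count > 0
  structure(list(k = as.integer(k), depth = depth[keep], count = count[keep]),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram k=%d: %d depths, %.3g observations>\n",
              x$k, length(x$depth), total_observations(x)))
  invisible(x)
}

#' Total number of k-mer observations in a histogram
#'
#' @param hist A [kmer_histogram()].
#' @return `sum(depth * count)`.
#' @export
total_observations <- function(hist) sum(hist$depth * hist$count)

#' Read / write a k-mer histogram TSV
#'
#' The interchange format is two tab-separated integer columns,
#' `depth<TAB>distinct-k-mer count`, with depths strictly increasing.
#' Comment lines starting with `#` are ignored on read and a `# k=<k>`
#' comment is emitted on write so the k-mer length round-trips.
#'
#' @param path Path to the TSV file.
#' @param k k-mer length to attach when the file carries no `# k=` comment.
#' @return [read_kmer_histogram()]: a [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  kline <- grep("^#\\s*k=", lines, value = TRUE)
  if (length(kline)) k <- as.integer(sub("^#\\s*k=", "", kline[1]))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stopf("empty k-mer histogram: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stopf("histogram rows must be depth<TAB>count")
  depth <- as.numeric(vapply(parts, `[`, character(1), 1))
  count <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(depth) || anyNA(count)) stopf("non-numeric histogram entry")
  if (anyDuplicated(depth)) stopf("duplicate depth row")
  if (any(count < 0)) stopf("negative count")
  o <- order(depth)
  kmer_histogram(k, depth[o], count[o])
}

#' @rdname read_kmer_histogram
#' @param hist A [kmer_histogram()].
#' @export
write_kmer_histogram <- function(hist, path) {
  writeLines(c(sprintf("# k=%d", hist$k),
               sprintf("%d\t%s", hist$depth,
                       format(hist$count, scientific = FALSE, trim = TRUE))),
             path)
  invisible(path)
}

# dense count vector over 1..max(depth); depths absent from the support are 0
dense_counts <- function(hist) {
  y <- numeric(max(hist$depth))
  y[hist$depth] <- hist$count
  y
}

#' Count k-mers in sequence records
#'
#' Tallies every length-`k` window that contains no `N` and returns the depth
#' histogram of distinct k-mer multiplicities. With `canonical = TRUE` a k-mer
#' and its reverse complement are merged under the lexicographically smaller
#' of the two forms, as read-based counters do.
#'
#' @param records List of [seq_record()] objects.
#' @param k k-mer length.
#' @param canonical Merge reverse-complement pairs?
#' @return A [kmer_histogram()].
#' @export
count_kmers <- function(records, k, canonical = FALSE) {
  stopifnot(k >= 1L, length(records) >= 1L)
  kmers <- unlist(lapply(records, function(r) {
    L <- nchar(r$residues)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    w <- substring(r$residues, starts, starts + k - 1L)
    w[!grepl("N", w, fixed = TRUE)]
  }), use.names = FALSE)
  if (!length(kmers)) stopf("no k-mers: every window is shorter than k or contains N")
  if (canonical) kmers <- pmin(kmers, rc(kmers))
  mult <- table(kmers)
  tab <- table(as.integer(mult))
  kmer_histogram(k, as.integer(names(tab)), as.numeric(tab))
}

#' Locate the error/genomic valley of a k-mer spectrum
#'
#' Sequencing errors pile up distinct k-mers at depth 1-2; the genuine genomic
#' component peaks near the coverage. Scanning the histogram support upward
#' from depth 1, the first local minimum separates the two: all mass at depths
#' below the returned cutoff is classified as erroneous.
#'
#' @param hist A [kmer_histogram()].
#' @return The cutoff depth (first local minimum; the first support depth when
#'   the spectrum rises immediately, i.e. no error component).
#' @export
find_error_cutoff <- function(hist) {
  d <- hist$depth; y <- hist$count
  n <- length(d)
  if (n < 2L) return(d[1] %||% stopf("empty histogram"))
  if (y[1] < y[2]) return(d[1])
  for (i in 2:(n - 1L)) {
    if (y[i] < y[i + 1L] && y[i] <= y[i - 1L]) return(d[i])
  }
  stopf("spectrum uninformative: no valley between the error and genomic components")
}

# local maxima of a numeric vector (plateau-tolerant on the right)
local_maxima <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (i == n) -Inf else y[i + 1L]
    y[i] > left && y[i] >= right
  }, logical(1)))
}

#' Estimate the homozygous peak depth of a k-mer spectrum
#'
#' Finds all local maxima at depths >= `error_cutoff` (after light 3-point
#' smoothing) with height at least 10% of the tallest. In heterozygous
#' genomes the tallest maximum can sit at half the true coverage (k-mers
#' spanning heterozygous sites), so if a maximum exists at about twice the
#' depth of the tallest one and is of comparable height (>= 70% of it), that
#' doubled depth is returned as the homozygous peak. The height guard keeps
#' the 2x-depth echo of two-copy repeat families, which is always much
#' smaller than the main peak, from being mistaken for it. Supply
#' `peak_depth` to override the heuristic entirely.
#'
#' @param hist A [kmer_histogram()].
#' @param error_cutoff Depth from [find_error_cutoff()].
#' @param peak_depth Optional explicit peak depth; returned as-is.
#' @return The estimated k-mer depth of the homozygous peak.
#' @export
estimate_peak_depth <- function(hist, error_cutoff, peak_depth = NULL) {
  if (!is.null(peak_depth)) return(as.integer(peak_depth))
  y <- dense_counts(hist)
  dmax <- length(y)
  if (error_cutoff > dmax) stopf("spectrum uninformative: cutoff beyond support")
  d <- error_cutoff:dmax
  y <- y[d]
  n <- length(y)
  ys <- if (n >= 3L) {
    vapply(seq_len(n), function(i)
      mean(y[max(1L, i - 1L):min(n, i + 1L)]), numeric(1))
  } else y
  cand <- local_maxima(ys)
  cand <- cand[cand > 1L | n == 1L]          # a rise right at the cutoff is the valley edge
  if (length(cand)) cand <- cand[ys[cand] >= 0.10 * max(ys[cand])]
  if (!length(cand)) {
    if (n == 1L) return(d[1])
    stopf("spectrum uninformative: no local maximum above the error cutoff")
  }
  t_i <- cand[which.max(ys[cand])]
  t_d <- d[t_i]
  q_i <- cand[abs(d[cand] - 2L * t_d) <= pmax(2, 0.1 * d[cand]) & d[cand] > t_d]
  if (length(q_i)) {
    q_i <- q_i[which.max(ys[q_i])]
    if (ys[q_i] >= 0.7 * ys[t_i]) return(d[q_i])
  }
  t_d
}

#' Estimate genome size from a k-mer spectrum
#'
#' Applies the survey formula `genome size = k-mer number / k-mer depth`. The
#' revised size removes the erroneous observations below the error cutoff
#' from the numerator first.
#'
#' @param hist A [kmer_histogram()].
#' @param peak_depth Homozygous peak depth (k-mer depth).
#' @param error_cutoff Depth below which mass is erroneous.
#' @return A list with `genome_size_bp` and `revised_genome_size_bp`.
#' @export
estimate_genome_size <- function(hist, peak_depth, error_cutoff = 1L) {
  stopifnot(peak_depth >= 1)
  total <- total_observations(hist)
  if (total <= 0) stopf("histogram has no observations")
  err <- sum(hist$depth[hist$depth < error_cutoff] *
               hist$count[hist$depth < error_cutoff])
  list(genome_size_bp = total / peak_depth,
       revised_genome_size_bp = (total - err) / peak_depth)
}

#' Estimate per-base heterozygosity from a k-mer spectrum
#'
#' Fits, by least squares over depths `[error_cutoff, 2*peak]`, a mixture of
#' Poisson-shaped components at half coverage (heterozygous k-mers), at
#' coverage (homozygous unique k-mers) and at twice coverage (the shoulder of
#' two-copy repeat families, included so it cannot leak into the half-depth
#' weight). Each heterozygous site disrupts k-mers on both haplotypes, so the
#' half-depth component carries twice the distinct k-mers per heterozygous
#' locus: with fitted weights `a` (half depth) and `b` (full depth), the
#' heterozygous fraction of k-mer loci is `f = a / (a + 2b)` and the per-base
#' rate inverts the independence approximation `f = 1 - (1 - r)^k`:
#' `r = 1 - (1 - f)^(1/k)`. Returns 0 when the half-depth weight is not
#' significantly positive.
#'
#' @param hist A [kmer_histogram()].
#' @param peak_depth Homozygous peak depth.
#' @param error_cutoff Depth from [find_error_cutoff()].
#' @param k k-mer length; defaults to the histogram's.
#' @return Estimated per-base heterozygosity (fraction), or `NA` with a
#'   warning if the fit fails.
#' @export
estimate_heterozygosity <- function(hist, peak_depth, error_cutoff = 1L, k = hist$k) {
  y <- dense_counts(hist)
  d <- error_cutoff:min(length(y), 2L * peak_depth)
  if (length(d) < 5L) stopf("window too narrow for a mixture fit")
  yy <- y[d]
  X <- cbind(het = stats::dpois(d, peak_depth / 2),
             hom = stats::dpois(d, peak_depth),
             rep2 = stats::dpois(d, 2 * peak_depth))
  fit <- tryCatch(stats::lm(yy ~ 0 + X), error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    warning("heterozygosity not estimable: mixture fit failed")
    return(NA_real_)
  }
  cf <- stats::coef(fit)
  a <- cf[["Xhet"]]; b <- max(cf[["Xhom"]], 0)
  tval <- tryCatch(summary(fit)$coefficients["Xhet", "t value"],
                   error = function(e) 0)
  if (!is.finite(a) || a <= 0 || !is.finite(tval) || tval < 2) return(0)
  f <- a / (a + 2 * b)
  f <- min(max(f, 0), 1 - 1e-12)
  1 - (1 - f)^(1 / k)
}

#' Estimate the repeat fraction of a genome from its k-mer spectrum
#'
#' Observations at depths beyond `multiplier * peak_depth` come from
#' multi-copy sequence (the "fat tail"). The repeat fraction is that tail
#' mass over all non-erroneous observations.
#'
#' @param hist A [kmer_histogram()].
#' @param peak_depth Homozygous peak depth.
#' @param error_cutoff Depth from [find_error_cutoff()].
#' @param multiplier Tail threshold in units of the peak depth.
#' @return Fraction in `[0, 1]`.
#' @export
estimate_repeat_fraction <- function(hist, peak_depth, error_cutoff = 1L,
                                     multiplier = 2) {
  obs <- hist$depth * hist$count
  total <- sum(obs)
  err <- sum(obs[hist$depth < error_cutoff])
  rep_obs <- sum(obs[hist$depth > multiplier * peak_depth])
  rep_obs / (total - err)
}

#' Full genome profile from a k-mer spectrum
#'
#' Convenience wrapper running [find_error_cutoff()], [estimate_peak_depth()],
#' [estimate_genome_size()], [estimate_heterozygosity()] and
#' [estimate_repeat_fraction()] in sequence, mirroring the columns of a
#' survey report (k, k-mer number, depth, genome size, revised size,
#' heterozygosity, repeat fraction).
#'
#' @param hist A [kmer_histogram()].
#' @param peak_depth Optional explicit peak depth override.
#' @param repeat_multiplier Tail threshold for the repeat fraction.
#' @return A list of class `genome_profile`.
#' @export
profile_genome <- function(hist, peak_depth = NULL, repeat_multiplier = 2) {
  cutoff <- find_error_cutoff(hist)
  peak <- estimate_peak_depth(hist, cutoff, peak_depth = peak_depth)
  size <- estimate_genome_size(hist, peak, cutoff)
  structure(list(
    k = hist$k,
    kmer_number = total_observations(hist),
    peak_depth = peak,
    error_cutoff = cutoff,
    genome_size_bp = size$genome_size_bp,
    revised_genome_size_bp = size$revised_genome_size_bp,
    het_rate = estimate_heterozygosity(hist, peak, cutoff),
    repeat_fraction = estimate_repeat_fraction(hist, peak, cutoff,
                                               multiplier = repeat_multiplier)
  ), class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "Genome profile (k=%d)\n",
    "  k-mer number:        %.0f\n",
    "  k-mer depth (peak):  %d\n",
    "  genome size:         %.2f Mb\n",
    "  revised genome size: %.2f Mb\n",
    "  heterozygosity:      %s\n",
    "  repeat fraction:     %.2f%%\n"),
    x$k, x$kmer_number, x$peak_depth,
    x$genome_size_bp / 1e6, x$revised_genome_size_bp / 1e6,
    if (is.na(x$het_rate)) "not estimable" else sprintf("%.2f%%", 100 * x$het_rate),
    100 * x$repeat_fraction))
  invisible(x)
}
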