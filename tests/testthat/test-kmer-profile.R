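test_that("k-mer counting matches hand tallies and an independent window count", {
  r <- list(seq_record("s", "ACGT"))
  h <- count_kmers(r, 2)
  expect_equal(h$depth, 1L)
  expect_equal(h$count, 3)

  h2 <- count_kmers(list(seq_record("s", "AAAA")), 2)
  expect_equal(h2$depth, 3L)
  expect_equal(h2$count, 1)

  # canonical counting merges reverse-complement pairs: AC + GT are one k-mer
  h3 <- count_kmers(list(seq_record("s", "ACGT")), 2, canonical = TRUE)
  expect_equal(sum(h3$count), 2)  # {AC(=GT) x2, CG x1} -> depths {1,2}
  expect_equal(total_observations(h3), 3)

  # windows containing N are skipped; total observations equal an
  # independently computed count of N-free windows
  set.seed(11)
  ch <- sample(c("A", "C", "G", "T"), 5000, TRUE)
  ch[sample(5000, 40)] <- "N"
  s <- paste(ch, collapse = "")
  k <- 17
  h4 <- count_kmers(list(seq_record("s", s)), k)
  n_free <- sum(vapply(seq_len(5000 - k + 1), function(i)
    !any(ch[i:(i + k - 1)] == "N"), logical(1)))
  expect_equal(total_observations(h4), n_free)

  expect_error(count_kmers(list(seq_record("s", "ACG")), 10), "no k-mers")
})

test_that("error cutoff is the first valley of the spectrum", {
  h <- kmer_histogram(17, c(1, 2, 3, 10, 11, 12), c(1000, 100, 5, 50, 80, 50))
  expect_equal(find_error_cutoff(h), 3L)

  # no error component: histogram rises from its first support depth
  h2 <- kmer_histogram(17, 1:5, c(10, 50, 90, 50, 10))
  expect_equal(find_error_cutoff(h2), 1L)

  # monotonically decreasing spectrum carries no genomic peak
  h3 <- kmer_histogram(17, 1:5, c(100, 50, 20, 5, 1))
  expect_error(find_error_cutoff(h3), "uninformative")
})

test_that("peak detection resolves the half-depth heterozygous peak", {
  # single clear peak
  h1 <- kmer_histogram(17, 25:35, c(1, 3, 8, 15, 25, 30, 25, 15, 8, 3, 1))
  expect_equal(estimate_peak_depth(h1, 1L), 30L)

  # a taller peak at 22 plus a comparable peak at 44 (a heterozygous mixture
  # with f_het = 0.28): the doubled depth is the homozygous coverage
  d <- 1:60
  y <- round(1e5 * (2 * 0.28 * dpois(d, 22) + (1 - 0.28) * dpois(d, 44)))
  h2 <- kmer_histogram(17, d, y)
  # the doubled depth (up to the +-1 plateau discretisation of a Poisson
  # mode) is chosen over the taller half-depth peak
  p2 <- estimate_peak_depth(h2, find_error_cutoff(h2))
  expect_lte(abs(p2 - 44L), 1L)

  # a small 2x echo (two-copy repeat families) must NOT displace the peak
  y3 <- round(1e5 * (dpois(d, 22) + 0.15 * dpois(d, 44)))
  h3 <- kmer_histogram(17, d, y3)
  expect_equal(estimate_peak_depth(h3, find_error_cutoff(h3)), 22L)

  # explicit override wins
  expect_equal(estimate_peak_depth(h2, 1L, peak_depth = 44), 44L)
})

test_that("genome size is total observations over peak depth", {
  # the survey formula at the published scale: 176134142868 17-mers at depth 44
  h <- kmer_histogram(17, 44, 176134142868 / 44)
  gs <- estimate_genome_size(h, 44)
  expect_equal(round(gs$genome_size_bp / 1e6, 2), 4003.05)

  h2 <- kmer_histogram(17, 10, 100)
  gs2 <- estimate_genome_size(h2, 10)
  expect_equal(gs2$genome_size_bp, 100)
  expect_equal(gs2$revised_genome_size_bp, 100)

  # algebraic identity on arbitrary histograms
  set.seed(5)
  for (i in 1:10) {
    dep <- sort(sample(1:200, 20))
    cnt <- sample(0:1000, 20, TRUE)
    h3 <- kmer_histogram(17, dep, cnt)
    peak <- sample(1:60, 1)
    expect_equal(estimate_genome_size(h3, peak)$genome_size_bp,
                 sum(h3$depth * h3$count) / peak)
  }
})

test_that("rescaling the histogram leaves peak, het and repeats invariant", {
  sp <- spectrum_sim_spec(genome_size = 2e6, coverage = 44, het_rate = 0.017,
                          repeat_fraction = 0.3, seed = 21)
  h <- simulate_kmer_histogram(sp)
  h10 <- kmer_histogram(h$k, h$depth, h$count * 10)
  cut <- find_error_cutoff(h)
  expect_equal(find_error_cutoff(h10), cut)
  peak <- estimate_peak_depth(h, cut)
  expect_equal(estimate_peak_depth(h10, cut), peak)
  expect_equal(estimate_heterozygosity(h10, peak, cut),
               estimate_heterozygosity(h, peak, cut), tolerance = 1e-10)
  expect_equal(estimate_repeat_fraction(h10, peak, cut),
               estimate_repeat_fraction(h, peak, cut), tolerance = 1e-12)
  expect_equal(estimate_genome_size(h10, peak, cut)$genome_size_bp,
               10 * estimate_genome_size(h, peak, cut)$genome_size_bp)
})

test_that("heterozygosity inversion matches the closed form", {
  # a mixture with known half-depth weight w: r = 1 - (1 - w)^(1/k)
  expect_equal(1 - (1 - 0.25)^(1 / 17), 0.01678, tolerance = 1e-4)
  # construct a noise-free mixture with f_het = 0.25 and check the estimator
  d <- 3:88
  f <- 0.25
  y <- 1e6 * (2 * f * dpois(d, 22) + (1 - f) * dpois(d, 44))
  h <- kmer_histogram(17, d, round(y))
  expect_equal(estimate_heterozygosity(h, 44, 3), 1 - (1 - f)^(1 / 17),
               tolerance = 2e-3)
})

test_that("null heterozygosity is reported as zero", {
  sp <- spectrum_sim_spec(genome_size = 2e6, coverage = 44, het_rate = 0,
                          repeat_fraction = 0, seed = 33)
  h <- simulate_kmer_histogram(sp)
  cut <- find_error_cutoff(h)
  peak <- estimate_peak_depth(h, cut)
  expect_lt(estimate_heterozygosity(h, peak, cut), 0.001)
})

test_that("repeat fraction measures the fat tail", {
  # unimodal spectrum, no tail
  d <- 1:88
  h <- kmer_histogram(17, d, round(1e6 * dpois(d, 44)))
  expect_lt(estimate_repeat_fraction(h, 44, 1), 0.01)
  # all mass far beyond the peak
  h2 <- kmer_histogram(17, c(44, 440), c(1, 1e6))
  expect_gt(estimate_repeat_fraction(h2, 44, 1), 0.99)
})

test_that("cutoff of a simulated error-laden spectrum sits in the valley", {
  sp <- spectrum_sim_spec(genome_size = 2e6, coverage = 44, het_rate = 0.017,
                          repeat_fraction = 0, error_kmer_mass = 0.2, seed = 8)
  h <- simulate_kmer_histogram(sp)
  cut <- find_error_cutoff(h)
  expect_gt(cut, 1)
  expect_lt(cut, 44 / 4)
})
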