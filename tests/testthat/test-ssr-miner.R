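pad_record <- function(core, left = 600, right = 600, seed = 1) {
  # embed a core string in clean background with no accidental SSRs
  set.seed(seed)
  repeat {
    s <- paste0(paste(sample(c("A", "C", "G", "T"), left, TRUE), collapse = ""),
                core,
                paste(sample(c("A", "C", "G", "T"), right, TRUE), collapse = ""))
    rec <- seq_record("pad", s)
    hits <- find_ssrs(list(rec), min_scaffold_len = 1)
    core_hits <- hits[hits$start >= left - 10 & hits$end <= left + nchar(core) + 10, ]
    if (nrow(hits) == nrow(core_hits)) return(list(rec = rec, offset = left))
  }
}

test_that("a planted (AG)10 is reported with MISA thresholds and coordinates", {
  p <- pad_record(strrep("AG", 10))
  loci <- find_ssrs(list(p$rec))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$period, 2)
  expect_equal(loci$motif, "AG")
  expect_equal(loci$repeats, 10)
  expect_equal(loci$class, "AG/CT")
  expect_equal(loci$start, p$offset + 1)
  expect_equal(loci$end, p$offset + 20)
})

test_that("mononucleotide threshold boundary: 9 repeats fail, 10 pass", {
  p9 <- pad_record(paste0("C", strrep("A", 9), "C"), seed = 2)
  expect_equal(nrow(find_ssrs(list(p9$rec))), 0)
  p10 <- pad_record(paste0("C", strrep("A", 10), "C"), seed = 3)
  loci <- find_ssrs(list(p10$rec))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$type, "mono")
  expect_equal(loci$repeats, 10)
})

test_that("partial-unit flanks do not extend the repeat count", {
  # (AG)6 followed by a lone A: still 6 whole units
  p <- pad_record(paste0("TT", strrep("AG", 6), "ATT"), seed = 5)
  loci <- find_ssrs(list(p$rec))
  expect_equal(loci$repeats, 6)
  expect_equal(loci$end - loci$start + 1, 12)
})

test_that("scaffolds below the length filter are skipped entirely", {
  flank <- "GATCACGTGGTCAAGCTTGACCATGGATCC"  # no runs near any threshold
  short <- seq_record("short", paste0(flank, strrep("AT", 12), flank))
  expect_equal(nrow(find_ssrs(list(short))), 0)               # < 1000 bp
  expect_equal(nrow(find_ssrs(list(short), min_scaffold_len = 50)), 1)
})

test_that("runs are broken at N", {
  p <- pad_record(paste0(strrep("A", 6), "N", strrep("A", 6)), seed = 6)
  expect_equal(nrow(find_ssrs(list(p$rec), min_scaffold_len = 1)), 0)
})

test_that("canonical classes match published groupings and are invariant", {
  expect_equal(canonical_class("TAT"), "AAT/ATT")
  expect_equal(canonical_class("T"), "A/T")
  expect_equal(canonical_class("AT"), "AT/AT")
  expect_equal(canonical_class("CG"), "CG/CG")
  expect_equal(canonical_class("GAA"), "AAG/CTT")
  expect_error(canonical_class("ATAT"), "primitive")
  expect_error(canonical_class("AXT"), "A/C/G/T")

  # exhaustive: all primitive motifs of period <= 3; the class is unchanged
  # under rotation and reverse complement of its argument
  bases <- c("A", "C", "G", "T")
  motifs <- c(bases,
              apply(expand.grid(bases, bases), 1, paste, collapse = ""),
              apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""))
  prim <- Filter(function(m) {
    p <- nchar(m)
    !any(vapply(seq_len(p - 1), function(q)
      p %% q == 0 && m == strrep(substr(m, 1, q), p / q), logical(1)))
  }, motifs)
  rot1 <- function(m) paste0(substr(m, 2, nchar(m)), substr(m, 1, 1))
  rcmp <- function(m) paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1]]),
                            collapse = "")
  for (m in prim) {
    cl <- canonical_class(m)
    expect_equal(canonical_class(rot1(m)), cl)
    expect_equal(canonical_class(rcmp(m)), cl)
    # the representative itself maps to its own class
    expect_equal(canonical_class(strsplit(cl, "/")[[1]][1]), cl)
  }
})

test_that("miner agrees with the regex oracle on random scaffolds", {
  set.seed(31)
  recs <- lapply(1:12, function(i) random_record(sprintf("r%02d", i), 5000))
  mined <- find_ssrs(recs)
  oracle <- oracle_find_ssrs(recs)
  expect_equal(mined[, names(oracle)], oracle)
})

test_that("mining is strand-consistent", {
  sim <- simulate_scaffolds(genome_sim_spec(
    6, c(3000, 3000), 0.37,
    data.frame(motif = c("A", "AG", "AAT", "AT", "ACG", "AATC"),
               repeats = c(11, 7, 6, 9, 5, 5),
               scaffold = 1:6, start = 1000L),
    seed = 17))
  fwd <- find_ssrs(sim$records)
  rev_recs <- lapply(sim$records, function(r)
    seq_record(r$id, paste(rev(strsplit(chartr("ACGTN", "TGCAN", r$residues),
                                        "")[[1]]), collapse = "")))
  bwd <- find_ssrs(rev_recs)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(sort(bwd$class), sort(fwd$class))
  # mirrored coordinates
  lens <- vapply(sim$records, function(r) nchar(r$residues), integer(1))
  names(lens) <- vapply(sim$records, `[[`, character(1), "id")
  key_f <- sort(paste(fwd$scaffold_id, fwd$start, fwd$end))
  key_b <- sort(paste(bwd$scaffold_id,
                      lens[bwd$scaffold_id] - bwd$end + 1,
                      lens[bwd$scaffold_id] - bwd$start + 1))
  expect_equal(key_b, key_f)
})

test_that("reported loci never overlap within a scaffold", {
  set.seed(77)
  recs <- lapply(1:10, function(i) random_record(sprintf("q%02d", i), 4000, gc = 0.2))
  loci <- find_ssrs(recs, min_repeats = c(`1` = 6L, `2` = 3L, `3` = 3L,
                                          `4` = 3L, `5` = 3L, `6` = 3L))
  expect_gt(nrow(loci), 0)  # low thresholds at AT-rich GC guarantee hits
  for (sc in unique(loci$scaffold_id)) {
    l <- loci[loci$scaffold_id == sc, ]
    l <- l[order(l$start), ]
    if (nrow(l) > 1) expect_true(all(l$start[-1] > l$end[-nrow(l)]))
  }
})

test_that("SSR summaries reproduce the survey spacing and tally the truth", {
  empty <- summarize_ssrs(find_ssrs(list()), 1000)
  expect_true(is.na(empty$mean_distance_kb))
  expect_equal(empty$n_loci, 0)

  sim <- simulate_scaffolds(genome_sim_spec(
    8, c(3000, 3000), 0.37,
    data.frame(motif = rep(c("A", "AG", "AAT", "AT"), 2),
               repeats = rep(c(12, 8, 6, 7), 2),
               scaffold = 1:8, start = 1500L),
    seed = 23))
  loci <- find_ssrs(sim$records)
  sm <- summarize_ssrs(loci, sum(vapply(sim$records, function(r)
    nchar(r$residues), integer(1))))
  expect_equal(sm$n_loci, nrow(sim$truth))
  expect_equal(sum(sm$distribution$total), nrow(sim$truth))
  # distribution equals a direct tally of the truth table
  truth_tally <- table(sim$truth$class)
  got <- setNames(sm$distribution$total, sm$distribution$class)
  expect_equal(unname(got[names(truth_tally)]), as.numeric(truth_tally))
  # mean distance definition, 2 dp
  expect_equal(sm$mean_distance_kb,
               round(sm$total_scanned_length / nrow(loci) / 1000, 2))
})

test_that("percentage routine reproduces printed survey arithmetic", {
  # spacing: 86.51 Mb scanned, 27153 loci -> 3.19 kb
  loci_stub <- data.frame(scaffold_id = "s", start = 1, end = 2, period = 1,
                          motif = "A", class = "A/T", repeats = 10,
                          type = "mono")
  sm <- summarize_ssrs(loci_stub[rep(1, 3), ], 86.51e6)
  expect_equal(sm$total_scanned_length / sm$n_loci, 86.51e6 / 3)

  counts <- data.frame(class = c("A/T", "C/G", "AT/AT", "AG/CT"),
                       type = c("mono", "mono", "di", "di"),
                       count = c(75, 25, 30, 10))
  pct <- ssr_percentages(counts)
  expect_equal(pct$classes$pct_of_period, c(75, 25, 75, 25))
  expect_equal(pct$periods$pct_of_total, c(71.43, 28.57))
  # explicit totals override the derived sums
  pct2 <- ssr_percentages(counts, period_totals = c(mono = 200, di = 50),
                          grand_total = 250)
  expect_equal(pct2$classes$pct_of_period, c(37.5, 12.5, 60, 20))
  expect_equal(pct2$periods$pct_of_total, c(80, 20))
})
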