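---
title: "Genome survey profiling and SSR marker development with ssrsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome survey profiling and SSR marker development with ssrsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ssrsurvey)
```

`ssrsurvey` implements the desk half of a low-coverage genome survey: the
statistics a lab computes between receiving short-read survey data for a
non-model organism and ordering primers for its first microsatellite panel.
This vignette records the models behind each stage, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generators do and do not establish about real data.

## The k-mer spectrum model

A k-mer spectrum is the histogram `n_d` of how many distinct k-mers occur
exactly `d` times in a read set. For a diploid genome sequenced to k-mer
coverage $\lambda$ the spectrum is modelled as a mixture:

* **erroneous k-mers** concentrated at depth 1–2 (each sequencing error
  creates up to k novel k-mers);
* a **heterozygous component**: a k-mer window hits a heterozygous site with
  probability $f = 1-(1-r)^k$ at per-base heterozygosity $r$ (independence
  approximation). Such windows differ between the two haplotypes, so they
  contribute *two* distinct k-mers each sampled at half coverage,
  $\mathrm{Poisson}(\lambda/2)$;
* a **homozygous unique component** at $\mathrm{Poisson}(\lambda)$;
* **repeat families** of copy number $m$ at $\mathrm{Poisson}(m\lambda)$,
  the "fat tail".

The estimators in `profile_genome()` are:

* **Error cutoff** (`find_error_cutoff`): the first local minimum of `n_d`
  scanning upward from depth 1 — the valley between the error spike and the
  genomic peaks. A spectrum that rises from its first support depth has no
  error component (cutoff = that depth); a monotonically decreasing spectrum
  has no genomic peak and is rejected as uninformative.
* **Peak depth** (`estimate_peak_depth`): all local maxima above the cutoff
  (after 3-point smoothing) with height ≥ 10% of the tallest are candidates.
  In a strongly heterozygous genome the *tallest* maximum can be the
  half-depth heterozygous peak, so if a candidate exists at about twice the
  depth of the tallest one (tolerance `max(2, 0.1·q)`) **and** its height is
  at least 70% of the tallest, that doubled depth is returned as the
  homozygous peak.
* **Genome size** (`estimate_genome_size`): `total k-mer observations /
  peak depth`; the revised size removes the observations below the error
  cutoff from the numerator first.
* **Heterozygosity** (`estimate_heterozygosity`): least-squares fit of
  Poisson-shaped components at $\lambda/2$, $\lambda$ and $2\lambda$ to
  `n_d` on `[cutoff, 2·peak]`. With weights $a$ (half depth) and $b$ (full
  depth), $f = a/(a+2b)$ (het k-mers are counted twice) and
  $r = 1-(1-f)^{1/k}$. The weight must be significantly positive
  (t > 2), otherwise 0 is returned.
* **Repeat fraction** (`estimate_repeat_fraction`): the share of
  non-erroneous observations at depths beyond `multiplier × peak`
  (default multiplier 2).

### Design notes on the peak heuristic

A plain "if a maximum exists at twice the depth of another, take the doubled
one" rule is ambiguous in repeat-rich genomes: two-copy repeat families
produce a genuine local maximum at $2\lambda$, and the rule as stated would
take it for the homozygous peak and halve the genome size. The echo of a
two-copy family is, however, always much smaller than the main peak (its
distinct k-mer count is divided by the copy number), whereas a genuine
heterozygous/homozygous pair has comparable heights. Anchoring at the
tallest maximum and requiring the doubled candidate to reach 70% of its
height resolves both published-style spectra (half-depth peak slightly
taller than the homozygous peak) and spectra with up to ~80% repeat content.
The guard fails for extreme heterozygosity (above roughly 2.4% per base,
where the homozygous peak drops below 70% of the heterozygous one);
`peak_depth` can be supplied explicitly for such data. Because a Poisson
mode is a two-point plateau ($p_{\lambda-1} = p_\lambda$), the detected peak
can sit one depth unit left of the true coverage; the downstream estimates
inherit at most that ±1 discretisation (≈2.3% at 44× coverage).

The three-component fit exists for the same reason: inside the fit window
`[cutoff, 2·peak]` lies the left half of the two-copy repeat shoulder, and
without a $2\lambda$ basis its mass would leak into the full-depth weight
and bias $f$ downward. With the basis included, the fit spans the simulated
mixture exactly.

The error-exclusion rule, the repeat-tail multiplier and the exact method
behind a published "revised" genome size vary between surveys and are
rarely stated; the revised size and repeat fraction here are therefore
validated by simulation recovery, not against any published value.

## SSR mining

`find_ssrs()` reproduces the standard MISA screening conventions:

* only records of at least `min_scaffold_len` (default 1000 bp) are scanned;
* a locus is a maximal run of a primitive motif of period 1–6 repeated at
  least `min_repeats[period]` times (defaults 10, 6, 5, 5, 5, 5);
* maximality is in whole units: a trailing or leading partial unit extends
  neither the repeat count nor the coordinates (`(AG)6A` is six repeats);
* runs break at `N`; a run reportable at several periods is reported at its
  smallest qualifying period (equivalently, non-primitive motifs such as
  `ATAT` are never reported); when two candidate loci overlap — e.g. a
  mononucleotide run abutting a dinucleotide run that shares its first
  base — the smaller period wins, then the leftmost;
* coordinates are 1-based inclusive, and the motif is reported as it first
  appears at the locus start (leftmost-unit convention), so the same locus
  on the reverse strand may be reported with coordinates shifted by up to
  period−1 bases.

`canonical_class()` groups motifs by rotation and reverse complement
(`TAT`, `ATA`, `AAT`, `ATT`, `TTA`, `TAA` → `AAT/ATT`), the grouping used
in survey distribution tables. `summarize_ssrs()` bins repeat counts into
{5, 6, 7, 8, 9, 10, 11–20, >20} — kept disjoint even though printed tables
sometimes label the penultimate bin "10–20" — and reports the mean
inter-locus distance `scanned bp / loci / 1000` kb. `ssr_percentages()`
derives per-period and per-class shares; it accepts explicit period and
grand totals because printed survey tables occasionally carry subtotals
that disagree with the sum of their own rows, and reproducing the printed
arithmetic then requires the printed totals.

## Primer design

`design_for_locus()` is an exhaustive constraint search over all
(forward window, reverse window) pairs flanking a locus, with the classic
SSR-screening envelope as default `primer_constraints()`: product
100–300 bp, primer 18–27 nt, GC 40–70%, Tm 57–63 °C, optima
200 / 20 / 50 / 60. Melting temperatures use the SantaLucia 1998 unified
nearest-neighbor parameters at 50 mM monovalent salt and 0.25 µM oligo
(`melting_temp`, Wallace 2/4 rule available for hand checks). Candidates
are ranked by unweighted L1 deviation from the optima, ties broken by
leftmost forward start then shortest product, making the search
deterministic. Self-complementarity, hairpins and 3′-end stability are out
of scope, as is any in-silico PCR specificity check. `dedupe_pairs()`
collapses pairs with identical forward and reverse sequences, the natural
reading of "non-redundant primer pairs" when no redundancy criterion is
published.

## Marker diversity statistics

For each locus over the typed individuals of a chosen subset
(`locus_stats`): Na is the number of distinct alleles; Ho the fraction of
heterozygous typed individuals; expected heterozygosity
$He = 1-\sum_i f_i^2$ from the allele frequencies, reported both as-is and
with the small-sample correction $2n/(2n-1)$ (the form population-genetics
packages conventionally print — which is why published He columns can
exceed the PIC column at the same locus); and
$PIC = 1-\sum_i f_i^2$, the gene-diversity form that marker surveys in
this field state explicitly (not Botstein's full expression with the
pairwise correction term — the two agree at Na = 2 boundary behaviour but
diverge for multi-allelic loci, and the stated formula is authoritative
here). Botstein classes are low (PIC < 0.25), moderate, and high
(PIC > 0.5); the boundary values, which the strict published inequalities
leave unassigned, go to moderate. Missing calls are excluded listwise per
locus. `summarize_panel()` totals and averages these per-locus columns and
accepts any table with `na`, `pic`, `ho` and `he` columns, so a printed
marker table can be summarised directly.

## Clustering

`band_matrix()` converts co-dominant allele-size calls into the dominant
band scoring used with gel-based marker panels: one 0/1 column per
(locus, allele), with the columns of a missing call masked and deleted
pairwise. The genetic similarity coefficient defaults to simple matching
(`(m11+m00)/total`), the common choice for band data in NTSYS-style
analyses; Dice and Jaccard are selectable, and since the coefficient behind
any given published GSC range is usually unstated, no published range is
treated as a reference value. `upgma()` converts to distance `1 − GSC` and
agglomerates with size-weighted average linkage, merge height `d/2`, ties
broken by the lexicographically smallest member id, so runs are exactly
reproducible; the result is ultrametric, serialises to Newick, and
`cut_clusters(tree, s)` cuts at height `(1−s)/2`. Identical band profiles
always merge first at height 0. Bootstrap support and ordination are out
of scope.

## Synthetic data: what it emulates and what it does not

The three generators are first-class, seeded, pure functions of their spec.

* `simulate_scaffolds()` draws i.i.d. background at a target GC (default
  0.37, a typical angiosperm value) and substitutes planted SSR strings in
  exactly. Each scaffold is redrawn until mining it — on both strands —
  returns exactly the planted loci, so recovery tests have a crisp truth
  set. Real scaffolds are not i.i.d.: they carry compound and interrupted
  repeats, GC heterogeneity and assembly gaps, none of which are emulated.
* `simulate_kmer_histogram()` draws the mixture above with multinomial
  depth sampling; repeat families use copy numbers {2, 4, 8} with equal
  genome mass — enough to produce a fat tail qualitatively, not a repeat
  landscape. Depths are Poisson, not negative binomial: real spectra are
  overdispersed and GC-biased, so recovery under this generator shows
  correctness of the estimators' arithmetic, not robustness to platform
  effects. Defaults (44× coverage, k = 17, heterozygosity 0.017,
  repeat-rich) mirror a published survey of a heterozygous woody plant.
* `simulate_genotypes()` is a Balding–Nichols-style model: flat-Dirichlet
  ancestral frequencies, per-population Dirichlet perturbation with
  concentration `(1−d)/d` so `divergence` plays the role of Fst,
  Hardy–Weinberg individuals, uniform missingness. Defaults (two
  populations of 10 + 5, 36 loci, 2–7 alleles) mirror a two-species
  screening panel. Loci are unlinked and allele sizes homoplasy-free,
  unlike real microsatellites.

Test problem sizes were chosen to make sampling noise negligible relative
to the tolerances while keeping the default suite in the tens of seconds:
spectra of 5–10 Mb at 44×, fifty 5-kb scaffolds with thirty planted loci,
and one hundred 16-individual panels for clustering recovery.

## Known limitations

* The peak heuristic needs a manual override above ~2.4% heterozygosity,
  and inherits a ±1-depth plateau ambiguity (~2.3% on genome size at 44×).
* PIC here equals gene diversity by definition; do not compare against
  software that implements Botstein's full correction.
* Primer scoring ignores thermodynamic self-structure; designed pairs are
  candidates for wet-lab screening, not validated assays.
* Compound/interrupted SSRs are not joined or reported; a
  `report-compound` extension hook is reserved in the miner's design.
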