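Package: ssrsurvey
Title: Genome Survey Profiling and Genomic SSR Marker Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for low-coverage genome survey analysis and microsatellite
    (SSR) marker development in non-model plants. Implements k-mer spectrum
    profiling (genome size, heterozygosity and repeat-content estimation from
    a depth histogram), assembly summary statistics (Nx lengths, GC content),
    MISA-style perfect SSR mining with canonical motif classification,
    constraint-based PCR primer design around SSR loci, per-locus marker
    diversity statistics (Na, Ho, He, PIC with Botstein polymorphism classes),
    and UPGMA clustering of individuals from marker band profiles with Newick
    export. Ships seeded simulators for scaffolds with planted SSRs, mixture
    k-mer spectra, and two-population diploid genotype matrices so every stage
    can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
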