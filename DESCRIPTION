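Package: lncstruct
Title: Integrative Structure Analysis of Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for dissecting the architecture of large,
    multi-domain long noncoding RNAs such as MEG3. Processes per-nucleotide
    chemical-probing signals (SHAPE fragment analysis and mutational-profiling
    counts) into normalized, classified reactivity profiles; performs
    probing-directed minimum-free-energy folding with partition-function pair
    probabilities and Shannon entropies; calls differential protections
    between in-cell and protein-free probing experiments; scans folded
    transcripts for long-range kissing-loop pseudoknots between hairpin-loop
    motifs and distal complementary tandem repeats, designs compensatory
    rescue mutants, and scores covariation support across structure-annotated
    alignments; and quantifies tertiary compaction from single-particle AFM
    topographies (row-wise power spectral densities with auto-affine fits)
    and from Hill-type magnesium titrations of hydration radii. Seeded
    generators emulate every input class so the whole pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
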