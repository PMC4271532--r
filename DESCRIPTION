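Package: ptcpop
Title: Population Analysis of Premature Termination Codons in Strain
    Genome Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls constitutive premature termination codon (PTC),
    splice-site and start-codon variants from per-strain pseudochromosome
    assemblies, polarizes them against two outgroup genomes, bins them by
    derived allele frequency, and characterizes the host genes by
    expression breadth, tissue specificity (tau), top-tissue enrichment,
    chromosomal distribution, gene age and origination mechanism, with
    false-positive-rate stratified resampling to check the robustness of
    the conclusions.  Ships a synthetic-data generator that produces
    reference genomes, strain panels, outgroup base tables, expression
    matrices and gene-age tables with known planted truth, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
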