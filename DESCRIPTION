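Package: sangerkit
Title: Processing and Assembly of Sanger Sequencing Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable workflow for Sanger sequencing data: reading and
    writing ABIF chromatogram files, quality trimming (modified Mott and
    sliding-window algorithms), secondary-peak detection, assembly of forward
    and reverse reads into consensus contigs with IUPAC ambiguity codes,
    contig alignment, a BIONJ quality-control tree, indel and stop-codon
    screening against an amino-acid reference, FASTA outputs, a static
    hierarchical HTML report, and a synthetic chromatogram simulator for
    fully reproducible testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    optparse,
    tibble,
    dplyr,
    generics,
    purrr,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
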