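Package: cfmix
Title: Cell-Free DNA Methylation Deconvolution, Fragmentomics and
    Nucleosome Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for plasma cell-free DNA assayed by
    long-read sequencing with direct methylation calls. Estimates
    cell-type composition and tumor-derived fraction from per-CpG
    methylation via non-negative least squares deconvolution against a
    reference atlas, quantifies hypomethylation of solo-WCGW CpGs in
    partially methylated domains within 10-Mbp bins stratified by copy
    number, builds flank-normalized methylation metaplots around
    transcription-factor binding sites, computes fragment-length
    statistics (short mono- and dinucleosome ratios) and 4-mer fragment
    end-motif frequencies with differential testing, and profiles
    phased-nucleosome coverage around CTCF sites. A truth-known
    synthetic-data generator emulates every input dialect so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
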