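Package: medsweep
Title: Selective-Sweep Scans, Synteny Dating and Gene-Loss Screens for
    Plant Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed selective-sweep detection from two-population SNP
    panels (Weir-Cockerham Fst and per-population nucleotide diversity over
    sliding windows, top-percentile screening, candidate-gene extraction),
    k-mer based genome-size estimation from sequencing reads, syntenic
    anchor chaining with fourfold-degenerate transversion (4DTv) distances
    and distribution-peak detection, an ordered best-hit "absent region"
    procedure for calling genes lost during domestication, hypergeometric
    GO enrichment with rich factors, and IUPAC promoter-motif counting.
    Ships deterministic synthetic-data generators with known truth so the
    whole pipeline is testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
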