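Package: ribopause
Title: Ribosome Profiling Analysis of EF-P Dependent Translational Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify translational pausing from bacterial ribosome
    profiling data. Computes per-codon ribosome occupancy from aligned
    footprints or coverage tracks, scores diprolyl (PPX) motifs and de novo
    peaks with a gene-normalized pausing index, classifies pauses and their
    elongation-factor-P (EF-P) dependence across strains and replicates,
    analyses nascent-peptide sequence context (Z-2/Z-3 residues, amino-acid
    classes), scans upstream regions for anti-Shine-Dalgarno hybridization
    potential with a nearest-neighbor RNA duplex model, annotates A-site
    codon rarity, and compares footprint ratios with external protein
    abundance ratios. Includes a fully parameterized negative-binomial
    ribo-seq simulator with planted stall sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
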