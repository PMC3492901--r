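Package: dhewscan
Title: Nucleotide Diversity and Compound Neutrality-Test Outlier Scans
    for Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-gene nucleotide diversity and divergence estimation from
    haploid resequencing alignments (theta_pi, Watterson's theta, Dxy,
    synonymous/nonsynonymous site partitioning, Ka/Ks), four neutrality
    statistics (Tajima's D, Fay and Wu's normalized H, Ewens-Watterson F,
    Kelly's ZnS) with empirical P-values from a built-in standard
    neutral-model coalescent simulator, the compound DHEW outlier test
    with simulation-calibrated significance levels, across-locus
    bootstrap comparisons of species means, and a synthetic study
    generator emulating multi-species conifer candidate-gene
    resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    boot,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
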