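Package: viromock
Title: Simulated Viral Mock Communities and Metagenome Assembly Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to benchmark viral metagenome (virome) assembly and
    diversity estimation without real sequencing data. Simulates evolved
    viral mock communities (sibling genomes generated along random trees at
    chosen transition rates, power-law rank abundances), shotgun reads with
    platform-style error profiles and full ground-truth provenance, and
    scores assembly outputs for genome reconstruction fidelity: overall and
    maximum contig coverage, contig accuracy, chimericity (read-origin
    entropy), and cross-genome interference (coverage-by-others). Builds
    contig spectra by coverage-limited subsampling and greedy overlap
    clustering, and estimates community richness and evenness by fitting
    rank-abundance models through Lander-Waterman island statistics, with a
    frequency-count estimator and clustering-based richness (with genome
    length correction) for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
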