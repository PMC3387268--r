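Package: hypoxamir
Title: Small RNA Profiling and miRNA-Mediated Regulatory Networks Under
    Short-Term Waterlogging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a small-RNA
    analysis workflow for short-term waterlogging (hypoxia) stress in maize
    roots: adapter trimming and tag collapsing of small RNA-seq libraries,
    reads-per-million normalisation, chi-square differential expression of
    known mature miRNA signatures, novel miRNA discovery by hairpin
    secondary-structure evaluation, rule-based plant miRNA target
    prediction with positional mismatch scoring, promoter cis-regulatory
    element over-representation against position weight matrices, stem-loop
    RT primer construction and delta-delta-Ct relative quantification, and
    assembly of the resulting TF-to-miRNA-to-target regulatory network.
    Ships a fully deterministic synthetic-data generator with a truth
    manifest so every stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    igraph,
    jsonlite,
    xml2,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
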