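Package: tcrlens
Title: TCR-Beta Repertoire Simulation, Annotation, and Case-Control Analysis
Version: 0.1.0
Authors@R: person("tcrlens", "developers", email = "tcrlens@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of T cell receptor beta-chain
    (TCR-beta) CDR3 repertoires: a V(D)J recombination cohort simulator with
    ground truth, Smith-Waterman germline V/J assignment and CDR3 junction
    extraction from FASTQ reads, repertoire descriptive statistics (D50
    diversity, abundance bins, CDR3 length/composition/hydrophilicity),
    group-level V-J combination usage analysis (asymmetric combination
    detection, PCA ordination, PERMANOVA), and a random-forest
    leave-one-out-cross-validated classifier with ROC/AUC and bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    vegan,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
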