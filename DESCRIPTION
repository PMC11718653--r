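Package: baitbias
Title: Study Bias and the Emergence of Power-Law Degree Distributions in
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how study bias (preferential selection of
    well-studied bait proteins) and experimental error rates shape the degree
    distributions of aggregated protein-protein interaction (PPI) networks.
    Provides ground-truth network generators (Erdos-Renyi and Barabasi-Albert),
    discrete power-law fitting with Kolmogorov-Smirnov cutoff selection and
    bootstrap goodness-of-fit testing, a simulator of biased aggregated bait-prey
    testing (AP-MS and Y2H modes), a closed-form model of aggregated AP-MS
    testing with power-law-distributed bait usage, bait/prey degree corrections,
    and distribution-level comparison of observed networks against simulated
    ensembles via earth mover's distance, signed sum-of-distance differences,
    and K-nearest-neighbour origin classification. Reads study catalogs from
    PSI-MITAB 2.5/2.7 or role-annotated TSV files and can generate fully
    synthetic study catalogs emulating real catalog statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
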