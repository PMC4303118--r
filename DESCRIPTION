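Package: tyroflow
Title: Comparative Tyrosine Phosphoproteomics with Spike-In Normalisation,
    Moderated Contrasts, Random-Forest Signatures and aCGH Copy-Number Calling
Version: 0.1.0
Authors@R: person("tyroflow", "maintainers", email = "tyroflow@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for label-free phosphotyrosine (pY)
    profiling of tumour classes: parsing of MaxQuant-Evidence-style peptide
    tables, spike-in standard normalisation, localization-probability and
    presence filtering, conditional k-nearest-neighbour imputation,
    empirical-Bayes moderated pairwise contrasts with Storey-type q-values
    and class-specific pY-site calling, a two-step random-forest tumour-type
    signature with permutation importance, hypergeometric pathway
    over-representation, provenance-annotated protein interaction networks,
    and an array-CGH arm with circular binary segmentation and plateau-based
    copy-number state calling. A synthetic-data generator plants known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
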