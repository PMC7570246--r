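Package: epidiv
Title: Epigenetic Diversity Analysis of MSAP and TMD Band Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing DNA-methylation diversity scored with
    methylation-sensitive amplified polymorphism (MSAP) and transposon
    methylation display (TMD) marker systems. Paired MseI/MspI and
    MseI/HpaII digest band calls are classified into the four canonical
    band types and converted to total, full, hemi- and non-methylation
    rates with group contrasts; dominant-marker diversity indices (Nei's
    gene diversity, Shannon's information index, effective number of
    alleles, polymorphic information content), pairwise epigenetic
    distances, principal coordinate analysis, Mantel tests, one-level
    AMOVA with permutation significance, neighbor-joining trees, and
    Evanno delta-K post-processing of clustering log-probabilities are
    provided, together with a dose-dependent demethylation simulator and
    a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vegan,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
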