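Package: pwdmicro
Title: Early-Life Faecal Microbiota Signatures of Post-Weaning Diarrhoea in Piglets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end statistical pipeline for discriminating piglets
    susceptible to post-weaning diarrhoea from healthy littermates using
    early-life faecal microbiota data. Covers capillary-electrophoresis
    fingerprint preprocessing and alpha diversity, binary-Jaccard community
    comparison with ANOSIM permutation testing, negative-binomial exact
    tests for differential OTU abundance with common-dispersion estimation
    and false-discovery-rate control, two-stage cross-validated sparse
    PLS-DA with stability selection, sparse PLS relevance networks, qPCR
    absolute quantification, dry-matter based diarrhoea classification and
    cohort-level univariate statistics. Includes a fully seeded synthetic
    cohort generator (litters, NB OTU counts, fingerprint traces, qPCR
    runs, phenotypes) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    pracma,
    zoo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mixOmics,
    edgeR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
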