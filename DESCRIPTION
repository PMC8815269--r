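Package: pepScreen
Title: GWAS-Informed Drug Repurposing via Pathway Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in-silico drug repurposing screen that starts from
    disease risk genes and ends at candidate drugs with viability-screen
    support. Perturbagen gene-rank profiles (Connectivity-Map style) are
    converted to pathway expression profiles with a Kolmogorov-Smirnov
    running-sum statistic, drugs are ranked per risk gene by a
    second-level enrichment of the gene's pathway annotations, per-gene
    candidate lists are merged by co-occurrence, and the merged drug set
    is mapped back to the pathways it collectively regulates (drug-set
    enrichment E-scores). Pooled viability-screen statistics (mean
    sensitivity ranking, Mann-Whitney tests against a reference
    treatment, replicate concordance, mutation association, differential
    expression of sensitive versus non-sensitive lines) validate the
    candidates. Seeded generators produce profile corpora and viability
    screens with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
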