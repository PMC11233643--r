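Package: mtwas
Title: Multi-Tissue Transcriptome-Wide Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains multi-tissue gene-expression prediction models and tests
    gene-trait associations. Missing per-tissue expression is imputed by an
    iterative random-forest scheme that borrows information across tissues;
    cis-eQTLs are then partitioned into cross-tissue eQTLs (selected on
    principal components of the imputed sample-by-tissue matrix) and
    tissue-specific eQTLs (selected per tissue conditional on the cross-tissue
    set) by stepwise regression under the extended Bayesian information
    criterion; effect sizes are estimated by weighted least squares that
    down-weights imputed samples. Gene-level association statistics are
    computed from individual-level data or from GWAS summary statistics with a
    block LD reference. A bundled simulator generates genotypes with
    autoregressive linkage disequilibrium, multi-tissue expression with shared
    and tissue-specific architecture, missingness masks, traits and summary
    statistics, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
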