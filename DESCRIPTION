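Package: mirilqtl
Title: Expression QTL Mapping in Mutation-Introgressed Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An eQTL analysis pipeline for small recombinant inbred line (RIL)
    panels carrying an introgressed, selected mutation (miRILs), modelled on the
    N2 x CB4856 Caenorhabditis elegans design. Provides expression-marker
    genetic-map construction (parental centering, windowed correlation against a
    reference cis-eQTL effect panel, genotype calling, imputation and
    informative-marker pruning), single-marker linear-model genome scans with
    permutation-based FDR thresholds, 1.5-drop confidence intervals and 2-Mb
    cis/trans classification, Poisson trans-band (hotspot) detection with
    adjacent-bin merging, cross-study replication and trans-band uniqueness
    tests, map-aware QTL power simulation, hypergeometric gene-set enrichment
    with category and overlap filters, and modifier-allele concordance analysis.
    A synthetic-data module simulates the full miRIL design (selfing with
    selection at a fixed locus, planted cis/trans/trans-band architecture) so
    every stage is testable without microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
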