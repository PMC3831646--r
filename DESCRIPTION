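Package: PrimerClade
Title: Clade-Specific Degenerate Primer Design and Clone Library Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs clade-specific degenerate PCR primers for 16S rRNA gene
    surveys and analyses the resulting clone libraries. From a multiple
    alignment of a target clade it builds a threshold-encoded IUPAC consensus
    (ignoring indels), extracts low-degeneracy sliding windows, merges them
    into conserved domains and enumerates every 20-30 nt candidate primer with
    at most two degenerate positions. Candidates and primer pairs are screened
    against a taxonomically labelled reference database with a mismatch-
    tolerant ungapped scanner, producing per-taxon coverage/specificity
    tables, in-silico PCR amplicon predictions and nested-PCR simulations.
    Downstream clone-library tools provide Needleman-Wunsch based top-hit
    retrieval, step-wise consensus taxonomy assignment, average-linkage OTU
    clustering and analytic or Monte-Carlo rarefaction. Seeded generators
    produce hierarchically structured synthetic databases with planted primer
    signatures so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'iupac.R'
    'AllClasses.R'
    'consensus.R'
    'enumerate.R'
    'scan.R'
    'pairs.R'
    'community.R'
    'synthetic.R'
    'io.R'
    'config.R'
    'PrimerClade-package.R'
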