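Package: branchedselex
Title: Branched-SELEX High-Throughput Sequencing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for branched (parallel single-round) SELEX
    experiments read out by high-throughput sequencing. Demultiplexes barcoded
    paired-end amplicon reads, merges pairs and extracts variable regions,
    dereplicates and clusters sequences at an identity threshold to obtain
    per-sample copy numbers, converts copy numbers into pool fractions and
    enrichment factors across parallel selection branches (target point
    mutants, conformers and target-ligand complexes), infers aptamer
    binding-site profiles and conformational/competition behaviour from
    relative enrichment factors, and extracts conserved degenerate consensus
    motifs within aptamer families. Includes a branched-selection simulator
    with known ground truth (pool composition, affinity model, multinomial
    read sampling, sequencing errors) and analytic enrichment-factor oracles
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
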