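Package: degscan
Title: Phosphodegron Consensus Motifs and Proteome Scanning for E3-Ligase Substrate Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving Cdc4 phosphodegron (CPD) consensus motifs from
    experimentally validated degron windows, scanning a canonical proteome for
    candidate E3-ligase (FBXW7) substrates, annotating matches with known
    phosphosites at the phospho-acceptor ('0') and '+4' positions, scoring
    cross-species conservation of matched windows in ortholog alignments, and
    testing candidate gene lists for gene-set overrepresentation with
    Benjamini-Hochberg false-discovery-rate control. Includes a synthetic-data
    generator (background proteomes with implanted degrons, ortholog families,
    phosphosite tables, gene-set collections with a spiked enriched set) so the
    whole pipeline is testable without external databases, and a command-line
    driver for the end-to-end workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
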