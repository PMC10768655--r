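Package: domrep
Title: Protein Domain Repertoire Evolution on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolution of protein domain repertoires
    across genomes. Extracts open reading frames from genomic sequences in
    all six frames, parses and filters HMMER3 per-domain (domtblout) hit
    tables at conditional and full-sequence E-value thresholds, assembles
    taxa-by-domain copy-count matrices, reconstructs ancestral domain counts
    on a rooted tree by linear (Wagner) parsimony treating counts as
    meristic characters, calls per-branch gain, duplication and loss events,
    and exports event maps as iTOL symbol datasets. Includes simulators for
    Yule trees, repertoire evolution with ground-truth event logs, planted
    ORF genomes and synthetic domtblout tables so every stage is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
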