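#!/usr/bin/env Rscript
# Stage 3: domain annotation and matrix assembly. Each taxon's domtblout
# table is parsed, hits are filtered at the 0.001 full-sequence and
# conditional E-value thresholds, repertoires are counted, and the
# taxa x domain copy-count matrix is written.

suppressPackageStartupMessages(library(domrep))

fx <- "results/fixtures"
files <- list.files(fx, pattern = "\\.domtblout$", full.names = TRUE)
repertoires <- lapply(files, function(f) {
  taxon <- sub("\\.domtblout$", "", basename(f))
  hits <- parse_domtblout(f)
  kept <- filter_hits(hits, seq_evalue_max = 1e-3, dom_evalue_max = 1e-3)
  message(taxon, ": ", nrow(kept), "/", nrow(hits), " hits kept")
  build_repertoire(kept, taxon)
})

m <- build_matrix(repertoires)
message("matrix: ", nrow(m), " taxa x ", ncol(m),
        " non-redundant domains; ", sum(m), " domain copies total")
write_matrix_tsv(m, "results/matrix.tsv")
message("wrote results/matrix.tsv")
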