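#!/usr/bin/env Rscript
# Stage 1: simulate the study system. A 20-taxon Yule time tree stands in
# for the time-calibrated organism tree, and a gain/duplication/loss
# process run along it yields per-taxon domain repertoires with a complete
# ground-truth event log. Per-taxon domtblout tables and one genome with
# planted ORFs are written so downstream stages consume the same file
# formats the real pipeline would.

suppressPackageStartupMessages(library(domrep))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 42

phy <- simulate_yule_tree(20, birth_rate = 1, seed = seed)
writeLines(write_newick(phy), file.path(out, "tree.nwk"))
message("tree: 20 taxa, root height ",
        round(max(ape::node.depth.edgelength(phy)), 3))

params <- evolution_params(
  gain_rate = 0.15, dup_rate = 0.25, loss_rate = 0.2,
  root_repertoire = c(Ca_hom_mod = 1L, `EF-hand_1` = 2L, Calpain_III = 1L,
                      S100 = 1L, Thioredoxin = 1L, Vinculin = 1L),
  seed = seed + 1)
sim <- simulate_repertoire_evolution(phy, params)
utils::write.table(sim$truth_log, file.path(out, "truth_events.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("simulated ", nrow(sim$truth_log), " unit events over ",
        nrow(phy$edge), " branches")

for (i in seq_along(sim$leaf_repertoires)) {
  r <- sim$leaf_repertoires[[i]]
  cat(make_domtblout_fixture(r, decoys = 6, seed = seed + 10 + i),
      file = file.path(out, paste0(r$taxon, ".domtblout")))
}
message("wrote ", length(sim$leaf_repertoires), " domtblout tables")

# one genome with planted ORFs for the ORF-extraction stage
proteins <- with(list(), {
  set.seed(seed)
  vapply(1:12, function(i)
    paste0("M", paste(sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]],
                             59, replace = TRUE), collapse = "")), "")
})
g <- plant_orfs(proteins, spacer_length = 60, seed = seed,
                genome_id = "SYN_T1")
writeLines(c(paste0(">", g$id, " ", g$organism), g$seq),
           file.path(out, "SYN_T1.fa"))
utils::write.table(attr(g, "planted"), file.path(out, "SYN_T1.planted.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("planted genome: ", nchar(g$seq), " nt, ", length(proteins),
        " ORFs")
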