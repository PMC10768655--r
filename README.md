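# domrep — protein domain repertoire evolution on phylogenies

`domrep` traces how the protein-domain content of genomes evolves along a
phylogeny. It was built around the evolutionary analysis of the calcium
homeostasis modulator CALHM6 — a single-domain (`Ca_hom_mod`) channel
protein — but every stage is generic: any set of genomes, any Pfam-style
domain annotation, any rooted time tree.

The pipeline mirrors the way such studies are actually run:

1. **ORF extraction** — all ATG-initiated, stop-terminated open reading
   frames in the six reading frames of each genome, translated to protein
   (`find_orfs`, `write_protein_fasta`).
2. **Domain annotation** — HMMER3 per-domain tabular output (`domtblout`)
   is parsed and filtered at inclusive thresholds on both the full-sequence
   E-value and the per-domain conditional E-value (c-Evalue), 0.001 by
   default; every surviving hit contributes one domain copy
   (`parse_domtblout`, `filter_hits`, `build_repertoire`).
3. **Matrix assembly** — per-taxon repertoires become a taxa × domain
   copy-count matrix, the character data (`build_matrix`).
4. **Ancestral reconstruction** — each domain's copy count is treated as a
   meristic (additive) character and reconstructed at every internal node
   by linear (Wagner) parsimony: the cost of changing count *i* to *j*
   along a branch is |i − j|, minimized over all ancestral assignments
   (`sankoff_linear`, `wagner_down_pass`, `assign_states`).
5. **Event calling** — count changes along each branch are classified:
   0 → k is one **gain** (plus k − 1 duplications), an increment of an
   existing count is that many **duplications**, a decrement is that many
   unit **losses** (`classify_branch`, `call_events`, `summarize_events`).
6. **Visualization** — events are exported as an iTOL `DATASET_SYMBOL`
   annotation, one square per branch and event type (gain green, loss
   white, duplication purple) sized by event count (`export_itol`).

A simulation suite (`simulate_yule_tree`, `simulate_repertoire_evolution`,
`plant_orfs`, `make_domtblout_fixture`) generates Yule time trees,
repertoires evolving by per-copy gain/duplication/loss with a ground-truth
event log, genomes with planted ORFs and synthetic domtblout tables, so the
whole pipeline is testable without NCBI genomes, Pfam or HMMER.

## The model

For one domain with leaf counts `x`, the ancestral counts minimize

    L(a) = Σ_branches |a(child) − a(parent)|,   a(leaf) = x(leaf)

over integer assignments `a` — Wagner parsimony for ordered characters,
computed by the Farris interval pass on binary trees and a Sankoff dynamic
programme with linear costs (states bounded by the leaf maximum, which is
provably sufficient) on arbitrary multifurcating trees. Most-parsimonious
reconstructions are generally non-unique; `domrep` reports one canonical
assignment under a declared tie-break (root takes the smallest optimal
state; children take the optimal state closest to their parent) and both
engines are validated against exhaustive enumeration.

## Worked example

The published per-branch event log for the CALHM6 domain ships with the
package and reproduces the study's accounting:

```r
library(domrep)
log <- read.delim(system.file("extdata", "calhm6_ca_hom_mod_events.tsv",
                              package = "domrep"))
summarize_events(events_from_typed_log(log, domain = "Ca_hom_mod"))$totals
#>        gains duplications       losses        total
#>            1            6           14           21

classify_branch(1, 4)   # branch n3 -> n4: 1 ancestral copy, 4 descendant
#>        gains duplications       losses
#>            0            3            0
classify_branch(4, 0)   # branch n11 -> Salmo salar
#>        gains duplications       losses
#>            0            0            4
```

So across the 20-organism tree the domain shows a single gain, six
duplications and fourteen losses, with the gain at the base and the
duplications concentrated toward the mammals.

The staged drivers under `analysis/` run the full simulated study —
`Rscript analysis/01_simulate_fixtures.R` through
`analysis/05_calhm6_worked_example.R` — writing trees, matrices, event
tables and iTOL datasets under `results/`. On the default seed the
simulation plants 46 unit events, of which the parsimony reconstruction
explains the leaf counts with cost 27 (parsimony is a lower bound on the
true number of events).

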