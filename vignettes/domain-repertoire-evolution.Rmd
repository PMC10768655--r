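---
title: "Tracing domain repertoire evolution by linear parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing domain repertoire evolution by linear parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domrep)
```

## The problem

A genome's *domain repertoire* is the multiset of protein-domain families
(with copy counts) encoded by its predicted proteins. Comparing repertoires
across species on a dated phylogeny lets one ask where a domain family was
gained, where it duplicated, and where copies were lost. `domrep`
implements this analysis for the calcium homeostasis modulator domain
(`Ca_hom_mod`, the single domain of the CALHM channel proteins) and its
interaction partners, but nothing in the machinery is specific to that
system.

The pipeline has six stages — ORF extraction, domain annotation, matrix
assembly, ancestral reconstruction, event calling, iTOL export — each
exposed as ordinary functions plus the staged drivers in `analysis/`.

## ORF extraction

All three reading frames of both strands are scanned. An ORF runs from an
ATG to the first in-frame stop; the stop is inside the nucleotide span and
outside the translation. Two conventions had to be fixed that genome
annotation pipelines rarely state:

* **Start policy.** In the default `maximal` mode only the first ATG after
  the previous in-frame stop opens an ORF, which bounds the output size; an
  `all-starts` mode reports one ORF per ATG for callers that genuinely want
  every frame. The maximal set is always a subset of the all-starts set.
* **Length cutoff.** `min_aa = 50` by default — the conventional smallest
  ORF length treated as plausibly coding in eukaryotic genome scans. The
  cutoff is a parameter, not a claim.
* **Truncated ORFs.** ORFs that run off the sequence end without a stop are
  excluded by default (`include_incomplete` re-enables them): on complete
  genome assemblies they are artifacts of the sequence boundary.
* **Ambiguity codes** never match ATG or a stop, and any codon containing
  one translates to `X`, even when the code would be unambiguous (e.g.
  `GGN`). This is deliberately conservative: a repertoire should not gain a
  domain via an uncertain base.

Coordinates are 0-based half-open on the forward strand for both strands,
so an ORF and its mirror image on the reverse complement map onto each
other by `L − end, L − start`. The calls are validated against an
exhaustive per-position oracle in the test suite.

## Domain annotation

Hits come from HMMER3's per-domain tabular output (`domtblout`), which the
package parses and writes itself (22 fixed whitespace-separated columns
plus a free-text description). Two filtering decisions:

* The "per-domain conditional value" threshold is applied to the
  **c-Evalue** column — HMMER's conditional E-value — not the independent
  i-Evalue; "conditional" is HMMER's own name for that column. Both it and
  the full-sequence E-value threshold default to `0.001`, and both are
  **inclusive** (`<=`), so a hit exactly at threshold is kept.
* **Every kept hit is one domain copy.** No collapsing of repeated hits of
  a family within one ORF, and no overlap resolution between ORFs; the
  repertoire semantics are declared rather than inferred, and an optional
  envelope-overlap de-duplication (`dedup_overlaps`, keep best domain
  score) exists for users who want it, off by default.

Running `hmmscan` itself is out of scope: hit tables are declared inputs,
which keeps the pipeline testable without Pfam.

## The count matrix

Repertoires assemble into a taxa × domain matrix of non-negative integer
copy counts: rows in input order, columns lexicographically sorted (so
serialized outputs are byte-stable), zeros for absences. The **counts**,
not presence/absence, are the character states passed to reconstruction;
`presence_absence()` is retained for the reduced view. All-zero columns
are dropped — a zero-variance character can produce no events.

## Linear parsimony

Copy counts are meristic (additive) characters: changing count $i$ to $j$
along a branch costs $|i-j|$, and the ancestral assignment minimizes the
total cost

$$L(a) \;=\; \sum_{(p,c)\,\in\,\text{branches}} |a(c) - a(p)|,
\qquad a(\text{leaf}) = x(\text{leaf}).$$

Branch lengths play no role. Two engines compute the optimum:

* `wagner_down_pass()` — the Farris interval pass for binary trees: a leaf
  gets $[x,x]$; an internal node gets the intersection of its children's
  intervals, or, when they are disjoint, the gap between them with the cost
  incremented by the gap width.
* `sankoff_linear()` — the general dynamic programme over states
  $0..S$, multifurcations included, with the min-plus convolution against
  $|i-j|$ computed in $O(S)$ by a two-pass distance transform. $S$
  defaults to the maximum leaf count, which is sufficient: with linear
  costs no optimal ancestral state can exceed the leaf range.

Both agree with each other and with exhaustive enumeration
(`brute_force_parsimony`) on every rooted topology with 3–4 leaves under
all leaf-state vectors in $\{0..4\}$, and on seeded random instances at
5–6 leaves; the DP cost is also cross-checked against an independent
Sankoff implementation (`phangorn`).

### Tie-breaking

Most-parsimonious reconstructions are usually non-unique, and the
gain/loss/duplication decomposition (though never the total cost) depends
on which one is reported. `assign_states()` makes one canonical choice:
the root takes the smallest state in its optimal set, and each node then
takes the state minimising its subtree cost plus the distance to its
parent's assigned state, ties toward the smaller state. The default
`root-smallest` policy biases ancestral counts low — i.e. toward gains and
duplications rather than losses near the root; `root-largest` is available
as the opposite convention. The choice is declared, deterministic, and
byte-reproducible.

## Event calling

For each branch and domain, the count change is classified:

| parent | child | events |
|---|---|---|
| 0 | k > 0 | 1 gain + (k − 1) duplications |
| p > 0 | c > p | c − p duplications |
| p | c < p | p − c losses |
| p | p | none |

Two conventions worth making explicit: a 0 → k jump is *one* gain plus
k − 1 duplications (published event tables only ever show the 0 → 1 case,
so the decomposition for k > 1 had to be declared); and each unit
decrement is one loss event, so the complete disappearance of 4 copies on
one branch is 4 losses — matching how published per-branch tables count
"Loss 4". Events attach to branches (identified by the child node), never
to the root. Conservation holds by construction: the root count plus the
signed event sum along any root-to-leaf path equals the leaf count, and
the total number of unit events equals the parsimony cost exactly.

The iTOL export writes a `DATASET_SYMBOL` file: one square per branch and
event type anchored at the child node, gain `#00A550`, loss `#FFFFFF`,
duplication `#6A0DAD`, symbol size linear in the event count, the three
types staggered along the branch so they stay visible together.

## The simulators, and what passing tests mean

`simulate_yule_tree()` grows a pure-birth tree: with $k$ lineages the next
speciation waits $\mathrm{Exp}(k\lambda)$; after the $n$-th lineage one
more waiting time is drawn and the tree is cut, so the root height is
$\sum_{k=2}^{n}\mathrm{Exp}(k\lambda)$ with mean
$\sum_{k=2}^{n} 1/(k\lambda)$ — the calibration the test suite checks by
Monte Carlo (2,000 replicates at $n=5$, $\lambda=1$, against the analytic
value $1.2833$, within three standard errors).

`simulate_repertoire_evolution()` runs a continuous-time Markov process
down each branch: gains at `gain_rate` per unit time drawing fresh names
from a domain pool, duplications and losses at per-copy rates, all rates
re-evaluated after every event, so losses are naturally absorbed at zero.
Every unit event is logged; replaying the log from the root reproduces the
leaf repertoires exactly, which pins the simulator's bookkeeping
independently of the reconstruction. Default rates (gain 0.1, duplication
0.2, loss 0.2 per unit time) give a few tens of events on a 20-taxon tree
of unit-order height — sparse enough that repertoires stay small, dense
enough that all three event types occur.

The fixture generators close the loop on file formats:
`plant_orfs()` reverse-translates proteins (first codon per amino acid,
deterministic) into `ATG…TAA` ORFs separated by G-free spacers built from
`TTAA` repeats — no spurious ATG can occur in a spacer, and every reading
frame hits a stop within 12 nt, so planted ORFs are recovered exactly at
their planted coordinates. `make_domtblout_fixture()` writes one clearly
passing hit per repertoire copy (E-values ≤ 10⁻⁴) plus decoys that fail
the conditional-E-value criterion (≥ 10⁻²), so the parse → filter → count
chain must recover the planted repertoire exactly.

**What this does not show.** The simulation emulates the *event structure*
of repertoire evolution, not its sequence-level reality: no substitution
process, no correlated domains, no rate variation across lineages, no
annotation noise beyond threshold-straddling decoys. Passing tests certify
the pipeline's algebra — parsing, counting, optimality, event accounting —
not that real Pfam scans of real genomes are error-free.

### Identifiability of single-event histories

`simulate_single_event_history()` plants at most one unit event per domain
for the recovery tests. One caveat is intrinsic to parsimony, not to the
implementation: a single unit **loss** on a branch incident to the root
admits two most-parsimonious readings — the loss there, or a duplication
on the sister branch — because the data cannot orient a change across the
root. The root-smallest policy deterministically picks the duplication
reading. The constrained generator therefore plants losses only on
branches *not* incident to the root (gains and duplications are
root-identifiable under the policy and may land anywhere); in that regime
the reconstruction provably has a unique optimum and event recovery is
exact, which the suite verifies on 100 seeded replicates. In the
unconstrained regime only the lower bound — parsimony cost ≤ true unit
events — is claimed, and checked.

## Numerical and design choices

* All state spaces are bounded integers; there is no floating-point
  tolerance anywhere in the reconstruction.
* Trees: rooted, possibly multifurcating `ape::phylo` objects; unlabeled
  internal nodes are auto-named `n2, n3, …` by preorder position, the
  numbering convention of the published node labels.
* Problem sizes in the test suite — exhaustive sweeps at 3–4 leaves with
  sampled 5–6-leaf instances, 100-replicate recovery runs on 8-taxon
  trees, a 2,000-replicate Yule calibration — were chosen so the whole
  suite completes in well under a minute while each property is exercised
  across its full combinatorial core.
* Every simulator is a pure function of its seed; the pipeline driver
  writes an MD5 manifest and double-runs to byte-identical outputs.

## Known limitations

* Parsimony reports *one* most-parsimonious reconstruction; alternative
  optima can redistribute events among branches (never changing the
  total). Event maps near the root should be read with the tie-break
  policy in mind.
* Gain events cannot be distinguished from many independent unit gains of
  the same family on different branches by count data alone; the event
  taxonomy is the standard branch-wise reading, not a homology claim.
* The ORF stage is a scanner, not a gene finder: no splicing, no
  codon-usage model, standard genetic code only.
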