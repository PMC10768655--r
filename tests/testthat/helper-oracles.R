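# Independent oracles and generators used across the suite. These stay
# deliberately naive (per-position scans, exhaustive enumeration) so they
# share no code with the implementation they check.

# Exhaustive per-position ORF scan: tests every codon position on both
# strands independently.
oracle_orfs <- function(seq_fwd, min_aa, mode = "maximal",
                        genome_id = "genome") {
  seq_fwd <- toupper(seq_fwd)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else domrep::reverse_complement(seq_fwd)
    L <- nchar(s)
    codon_at <- function(p) substr(s, p + 1L, p + 3L)  # 0-based
    for (p in seq(0L, max(L - 3L, 0L))) {
      if (p + 3L > L) next
      if (codon_at(p) != "ATG") next
      # walk to the first in-frame stop
      q <- p
      found <- FALSE
      while (q + 3L <= L) {
        if (codon_at(q) %in% stops && q > p) { found <- TRUE; break }
        q <- q + 3L
      }
      if (!found) next                      # incomplete ORFs excluded
      aa_len <- (q - p) / 3L
      if (aa_len < min_aa) next
      if (mode == "maximal") {
        # disqualified if an in-frame ATG exists after the previous stop
        r <- p - 3L
        earlier <- FALSE
        while (r >= 0L) {
          cc <- codon_at(r)
          if (cc %in% stops) break
          if (cc == "ATG") { earlier <- TRUE; break }
          r <- r - 3L
        }
        if (earlier) next
      }
      local_start <- p; local_end <- q + 3L
      if (strand == "+") {
        start <- local_start; end <- local_end
      } else {
        start <- L - local_end; end <- L - local_start
      }
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, frame = local_start %% 3L,
        start = start, end = end, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer()))
  out <- do.call(rbind, rows)
  out[order(match(out$strand, c("+", "-")), out$frame, out$start), ,
      drop = FALSE]
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# All rooted binary topologies (as newick strings) over a label set.
all_rooted_topologies <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(labels)
  out <- character(0)
  rest <- labels[-1L]
  for (k in 0:(n - 2L)) {                 # size of left clade minus one
    combs <- utils::combn(rest, k, simplify = FALSE)
    if (k == 0L) combs <- list(character(0))
    for (cc in combs) {
      left <- c(labels[1L], cc)
      right <- setdiff(labels, left)
      for (lt in all_rooted_topologies(left))
        for (rt in all_rooted_topologies(right))
          out <- c(out, paste0("(", lt, ",", rt, ")"))
    }
  }
  out
}

# Random binary tree with branch lengths, via the package's own Yule
# simulator but relabeled, for property tests where only shape matters.
random_binary_tree <- function(n_leaves, seed) {
  phy <- domrep::simulate_yule_tree(n_leaves, 1, seed = seed)
  phy$tip.label <- paste0("t", seq_len(n_leaves))
  phy
}

random_states <- function(phy, max_state, seed) {
  domrep:::with_seed(seed, {
    stats::setNames(sample(0:max_state, ape::Ntip(phy), replace = TRUE),
                    phy$tip.label)
  })
}

# Expand wide branch-event records into unit events for truth-log
# comparison.
expand_units <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(child = character(), domain = character(),
                      event = character(), count = integer()))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    data.frame(child = r$child, domain = r$domain,
               event = rep(c("gain", "duplication", "loss"),
                           c(r$gains, r$duplications, r$losses)),
               count = 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

sort_units <- function(units) {
  out <- units[order(units$child, units$domain, units$event), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
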