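# Deterministic reverse translation: first codon (in genetic-code table
# order) per amino acid, so ATG for M, GCT for A, etc.
first_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(unname(gc))
  stats::setNames(vapply(aas, function(a) names(gc)[gc == a][1L], ""), aas)
}

reverse_translate <- function(protein) {
  tab <- first_codon_table()
  aa <- strsplit(protein, "")[[1L]]
  bad <- setdiff(aa, names(tab))
  if (length(bad) > 0L)
    stop("cannot reverse-translate symbols: ", paste(bad, collapse = ", "))
  paste(tab[aa], collapse = "")
}

# Spacer built from the TTAA repeat: G-free, so it can contain no ATG and
# no TAG/TGA, while TAA occurs every 4 nt, covering all three reading
# frames within any 12 nt window. Reading frames entering a spacer
# therefore always terminate, and no ORF can start inside one.
spacer_seq <- function(len, offset = 0L) {
  stopifnot(len >= 16L)
  base <- strrep("TTAA", ceiling((len + offset) / 4L) + 1L)
  substr(base, offset + 1L, offset + len)
}

#' Build a synthetic genome with planted ORFs
#'
#' Concatenates reverse-translated ORFs (`ATG` + codons + `TAA`) separated
#' by stop-rich spacers, and records the planted forward-strand coordinates
#' for assertions. Spacers contain stop codons in every reading frame and
#' no `ATG`, so [find_orfs()] in maximal mode recovers every planted ORF at
#' its planted coordinates.
#'
#' @param proteins character vector of amino-acid sequences; each must
#'   start with `M` and contain no stop symbol.
#' @param spacer_length spacer length in nt (>= 16).
#' @param seed integer seed (randomises spacer phase) or `NULL`.
#' @param genome_id id for the resulting genome record.
#' @return one-row data frame (`id`, `organism`, `seq`) as from
#'   [read_fasta()], with attribute `planted`: a data frame of
#'   `orf_index`, `start`, `end`, `protein`.
#' @export
plant_orfs <- function(proteins, spacer_length = 60L, seed = NULL,
                       genome_id = "synthetic_genome") {
  stopifnot(length(proteins) > 0L)
  if (any(grepl("\\*", proteins)))
    stop("planted proteins must not contain stop symbols")
  if (!all(startsWith(proteins, "M")))
    stop("planted proteins must start with M (the ATG start supplies it)")
  with_seed(seed, {
    orf_nt <- vapply(proteins,
                     function(p) paste0(reverse_translate(p), "TAA"), "",
                     USE.NAMES = FALSE)
    pieces <- character(2L * length(orf_nt) + 1L)
    starts <- integer(length(orf_nt))
    pos <- 0L
    for (i in seq_along(orf_nt)) {
      sp <- spacer_seq(spacer_length, offset = sample(0:3, 1L))
      pieces[2L * i - 1L] <- sp
      pos <- pos + nchar(sp)
      starts[i] <- pos
      pieces[2L * i] <- orf_nt[i]
      pos <- pos + nchar(orf_nt[i])
    }
    pieces[length(pieces)] <- spacer_seq(spacer_length,
                                         offset = sample(0:3, 1L))
    genome <- data.frame(id = genome_id, organism = "synthetic",
                         seq = paste(pieces, collapse = ""),
                         stringsAsFactors = FALSE)
    attr(genome, "planted") <- data.frame(
      orf_index = seq_along(proteins), start = starts,
      end = starts + nchar(orf_nt), protein = proteins,
      stringsAsFactors = FALSE)
    genome
  })
}

#' Build a synthetic domtblout table for a repertoire
#'
#' One clearly passing hit (full-sequence and conditional E-values at most
#' `1e-4`) per repertoire copy, plus `decoys` clearly failing hits
#' (conditional E-value at least `1e-2`), so parsing, filtering at the
#' 0.001 thresholds and repertoire construction recover the input exactly.
#'
#' @param repertoire a `domain_repertoire`.
#' @param decoys number of failing decoy hits.
#' @param seed integer seed or `NULL`.
#' @return domtblout text (single string).
#' @export
make_domtblout_fixture <- function(repertoire, decoys = 0L, seed = NULL) {
  with_seed(seed, {
    cnt <- repertoire$counts
    doms <- rep(names(cnt), times = cnt)
    n_pass <- length(doms)
    n <- n_pass + decoys
    if (n == 0L) return(write_domtblout(parse_domtblout(text = "#"),
                                        file = NULL))
    target <- c(doms, if (decoys > 0L) sprintf("DECOY_%03d", seq_len(decoys)))
    pass <- c(rep(TRUE, n_pass), rep(FALSE, decoys))
    seq_ev <- ifelse(pass, 10^-stats::runif(n, 5, 9), 10^stats::runif(n, -1, 1))
    c_ev <- ifelse(pass, 10^-stats::runif(n, 5, 9), 10^stats::runif(n, -2, 0))
    ali_from <- sample(5:40, n, replace = TRUE)
    ali_len <- sample(40:180, n, replace = TRUE)
    hits <- data.frame(
      target_name = target,
      target_accession = sprintf("PF%05d.1", match(target, unique(target))),
      tlen = ali_len + 10L,
      query_name = sprintf("%s|+|0|%d", repertoire$taxon, seq_len(n) * 1000L),
      query_accession = "-",
      qlen = ali_from + ali_len + 60L,
      seq_evalue = signif(seq_ev, 3), seq_score = round(stats::runif(n, 10, 300), 1),
      seq_bias = round(stats::runif(n, 0, 3), 1),
      domain_index = 1L, domain_total = 1L,
      c_evalue = signif(c_ev, 3), i_evalue = signif(c_ev * 10, 3),
      dom_score = round(stats::runif(n, 10, 280), 1),
      dom_bias = round(stats::runif(n, 0, 3), 1),
      hmm_from = 1L, hmm_to = ali_len,
      ali_from = ali_from, ali_to = ali_from + ali_len - 1L,
      env_from = pmax(1L, ali_from - 2L), env_to = ali_from + ali_len + 1L,
      acc = round(stats::runif(n, 0.7, 0.99), 2),
      description = ifelse(pass, "synthetic planted hit", "synthetic decoy"),
      stringsAsFactors = FALSE)
    write_domtblout(hits, file = NULL)
  })
}
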