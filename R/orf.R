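STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' Scans the three reading frames of both strands of a genomic sequence.
#' An ORF runs from an ATG to the first in-frame stop codon; the stop is
#' included in the nucleotide span and excluded from the translation.
#' Ambiguity codes never match ATG or a stop codon, and any codon containing
#' one translates to `X`.
#'
#' Coordinates are 0-based half-open on the **forward** strand regardless of
#' ORF strand; for minus-strand ORFs `nt_seq` is the reverse complement of
#' the forward-strand slice `[start, end)`. `frame` is the 0/1/2 offset on
#' the strand that was scanned.
#'
#' @param genome either a single nucleotide string or a one-row data frame
#'   with columns `id` and `seq` (as returned by [read_fasta()]).
#' @param min_aa minimum translated length in amino acids (default 50).
#' @param mode `"maximal"` (default): only the first ATG after the previous
#'   in-frame stop opens an ORF; `"all-starts"`: every ATG opens one.
#' @param include_incomplete also report ORFs truncated by the sequence end
#'   without a stop codon (default `FALSE`).
#' @param genome_id identifier used in `orf_id` when `genome` is a bare
#'   string.
#' @return data frame with columns `genome_id`, `orf_id`, `strand`, `frame`,
#'   `start`, `end`, `nt_seq`, `aa_seq`, `aa_len`, sorted by
#'   (strand, frame, start). `orf_id` is `genome_id|strand|frame|start`.
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 2)
#' @export
find_orfs <- function(genome, min_aa = 50L, mode = c("maximal", "all-starts"),
                      include_incomplete = FALSE, genome_id = "genome") {
  mode <- match.arg(mode)
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1L, all(c("id", "seq") %in% names(genome)))
    genome_id <- genome$id
    seq_fwd <- toupper(genome$seq)
  } else {
    stopifnot(is.character(genome), length(genome) == 1L)
    seq_fwd <- toupper(genome)
  }
  stopifnot(min_aa >= 1L)
  L <- nchar(seq_fwd)

  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < 2L) next
      first <- frame + 1L
      starts_nt <- seq(first, by = 3L, length.out = ncod)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% STOP_CODONS)
      if (length(atg) == 0L) next
      # next in-frame stop at or after each codon position
      for (i in atg) {
        js <- stp[stp > i]
        if (length(js) == 0L) {
          if (!include_incomplete) next
          j_end <- ncod          # runs to last complete codon, no stop
          has_stop <- FALSE
        } else {
          j_end <- js[1L]
          has_stop <- TRUE
        }
        if (mode == "maximal") {
          prev_stop <- stp[stp < i]
          floor_cod <- if (length(prev_stop) == 0L) 0L else max(prev_stop)
          earlier_atg <- atg[atg > floor_cod & atg < i]
          if (length(earlier_atg) > 0L) next
        }
        aa_len <- if (has_stop) j_end - i else j_end - i + 1L
        if (aa_len < min_aa) next
        local_start0 <- frame + (i - 1L) * 3L
        local_end <- frame + (if (has_stop) j_end else j_end) * 3L
        nt_seq <- substr(s, local_start0 + 1L, local_end)
        if (strand == "+") {
          start <- local_start0; end <- local_end
        } else {
          start <- L - local_end; end <- L - local_start0
        }
        aa_seq <- translate_nt(nt_seq)
        out[[length(out) + 1L]] <- data.frame(
          genome_id = genome_id,
          orf_id = paste(genome_id, strand, frame, start, sep = "|"),
          strand = strand, frame = frame,
          start = start, end = end,
          nt_seq = nt_seq, aa_seq = aa_seq, aa_len = nchar(aa_seq),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(), orf_id = character(),
                      strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      nt_seq = character(), aa_seq = character(),
                      aa_len = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$strand, c("+", "-")), res$frame, res$start), ]
  rownames(res) <- NULL
  res
}
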