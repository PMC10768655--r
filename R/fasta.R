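#' Read a FASTA file into a sequence table
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a plain
#' data frame. The token before the first whitespace in each header becomes
#' the sequence `id`; the remainder of the header (if any) is kept as
#' `organism`, which is how per-organism genome files are usually labelled.
#' Sequences are uppercased and whitespace inside records is stripped.
#'
#' @param file path to a FASTA file.
#' @param text FASTA content as a single string (alternative to `file`).
#' @return data frame with columns `id`, `organism`, `seq`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 Homo sapiens", "ACGT", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fa")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  if (is.null(file)) stop("either 'file' or 'text' must be supplied")
  raw <- readLines(file, warn = FALSE)
  nonblank <- raw[nzchar(trimws(raw))]
  if (length(nonblank) == 0L) stop("empty FASTA input: ", file)
  if (!startsWith(nonblank[1L], ">"))
    stop("malformed FASTA: sequence data before the first '>' header")
  set <- Biostrings::readBStringSet(file)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  organism <- ifelse(grepl("\\s", headers),
                     sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  data.frame(id = ids, organism = organism, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write translated ORF proteins to FASTA
#'
#' One record per protein with the ORF identifier as header, mirroring the
#' per-organism protein files fed to a profile-HMM scan. Round-trips through
#' [read_fasta()] on `(id, seq)`.
#'
#' @param proteins data frame with columns `orf_id` and `aa_seq`
#'   (e.g. the output of [find_orfs()]).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_protein_fasta <- function(proteins, file) {
  stopifnot(is.data.frame(proteins),
            all(c("orf_id", "aa_seq") %in% names(proteins)))
  if (anyDuplicated(proteins$orf_id))
    stop("duplicate orf_id in protein set: ",
         paste(unique(proteins$orf_id[duplicated(proteins$orf_id)]),
               collapse = ", "))
  set <- Biostrings::AAStringSet(stats::setNames(proteins$aa_seq,
                                                 proteins$orf_id))
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Reverse complement of a nucleotide sequence
#'
#' IUPAC ambiguity codes are complemented to their IUPAC counterparts
#' (N stays N); non-IUPAC characters are an error.
#'
#' @param nt nucleotide string.
#' @return the reverse-complemented string, uppercase.
#' @examples
#' reverse_complement("AAGN")  # "NCTT"
#' @export
reverse_complement <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(nt))))
}

#' Translate a nucleotide sequence codon by codon
#'
#' Standard genetic code. Any codon containing a character other than
#' A/C/G/T translates to `X` (ambiguity codes are never resolved, even when
#' the amino acid would be unambiguous). A trailing stop codon is excluded
#' from the output; internal stops, which cannot occur in well-formed ORFs,
#' are rendered as `*`.
#'
#' @param nt nucleotide string whose length is a multiple of 3.
#' @return amino-acid string.
#' @examples
#' translate_nt("ATGAAATAA")  # "MK"
#' translate_nt("ATGNNA")     # "MX"
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L)
    stop("sequence length (", n, ") is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  ambiguous <- grepl("[^ACGT]", codons)
  aa[ambiguous] <- "X"
  if (length(aa) > 0L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}
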