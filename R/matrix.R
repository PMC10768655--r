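#' Assemble repertoires into a taxa x domain count matrix
#'
#' Rows are taxa in input order; columns are the lexicographically sorted
#' union of domain names across repertoires, so output is byte-stable.
#' Entry (t, d) is the copy count of domain d in taxon t, 0 when absent.
#' Row sums therefore equal repertoire totals. All-zero columns cannot
#' arise from repertoires and are dropped defensively.
#'
#' @param repertoires list of `domain_repertoire` objects with unique taxa.
#' @return integer matrix with taxa as rownames and domains as colnames.
#' @examples
#' r1 <- domain_repertoire("t1", c(A = 2))
#' r2 <- domain_repertoire("t2", c(A = 1, B = 3))
#' build_matrix(list(r1, r2))
#' @export
build_matrix <- function(repertoires) {
  taxa <- vapply(repertoires, function(r) r$taxon, "")
  if (anyDuplicated(taxa))
    stop("duplicate taxon: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  domains <- nonredundant_domains(repertoires)
  m <- matrix(0L, nrow = length(taxa), ncol = length(domains),
              dimnames = list(taxa, domains))
  for (i in seq_along(repertoires)) {
    cnt <- repertoires[[i]]$counts
    if (length(cnt) > 0L) m[i, names(cnt)] <- as.integer(cnt)
  }
  if (ncol(m) > 0L) m <- m[, colSums(m) > 0L, drop = FALSE]
  m
}

#' Collapse counts to presence/absence
#'
#' @param m taxa x domain count matrix.
#' @return matrix with entries `min(count, 1)`; idempotent.
#' @export
presence_absence <- function(m) {
  m[m > 1L] <- 1L
  m
}

#' Extract one domain column as leaf character states
#'
#' @param m taxa x domain count matrix.
#' @param domain domain name (must be a column of `m`).
#' @return named integer vector, taxon -> copy count.
#' @export
extract_character <- function(m, domain) {
  if (!domain %in% colnames(m))
    stop("domain '", domain, "' not present in matrix")
  stats::setNames(as.integer(m[, domain]), rownames(m))
}

#' Write / read the count matrix as TSV
#'
#' Header row holds domain names; the first column (`taxon`) holds taxa.
#' `read_matrix_tsv(write_matrix_tsv(m))` is the identity.
#'
#' @param m taxa x domain count matrix.
#' @param file path.
#' @return the path invisibly (`write`); an integer matrix (`read`).
#' @export
write_matrix_tsv <- function(m, file) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file) {
  nf <- utils::count.fields(file, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged matrix TSV: rows have differing field counts")
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (names(df)[1L] != "taxon") stop("matrix TSV must start with a 'taxon' column")
  taxa <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  if (ncol(body) == 0L)
    return(matrix(integer(0), nrow = length(taxa), ncol = 0L,
                  dimnames = list(taxa, NULL)))
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(taxa, names(body)))
  if (anyNA(vals)) stop("non-numeric cell in matrix TSV")
  if (any(vals < 0)) stop("negative cell in matrix TSV")
  if (any(vals != round(vals))) stop("non-integer cell in matrix TSV")
  storage.mode(vals) <- "integer"
  vals
}

#' Write the matrix as a NEXUS characters block
#'
#' Interoperability with legacy parsimony software; counts are encoded as
#' the symbols 0-9, so counts above 9 are rejected.
#'
#' @param m taxa x domain count matrix.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_matrix_nexus <- function(m, file) {
  if (any(m > 9L))
    stop("NEXUS symbol encoding supports counts 0-9 only; max observed is ",
         max(m))
  taxa <- gsub("[^A-Za-z0-9_.]", "_", rownames(m))
  rows <- paste0("    ", formatC(taxa, width = max(nchar(taxa)), flag = "-"),
                 "  ", apply(m, 1L, paste, collapse = ""))
  lines <- c("#NEXUS", "",
             "BEGIN DATA;",
             paste0("  DIMENSIONS NTAX=", nrow(m), " NCHAR=", ncol(m), ";"),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
             "  MATRIX", rows, "  ;", "END;")
  writeLines(lines, file)
  invisible(file)
}
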