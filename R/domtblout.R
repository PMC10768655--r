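# HMMER3 --domtblout dialect: '#' comment lines, then data lines of 22
# whitespace-separated columns followed by a free-text description.
DOMTBL_COLS <- c(
  "target_name", "target_accession", "tlen",
  "query_name", "query_accession", "qlen",
  "seq_evalue", "seq_score", "seq_bias",
  "domain_index", "domain_total",
  "c_evalue", "i_evalue", "dom_score", "dom_bias",
  "hmm_from", "hmm_to", "ali_from", "ali_to", "env_from", "env_to",
  "acc")
DOMTBL_NUMERIC <- c("tlen", "qlen", "seq_evalue", "seq_score", "seq_bias",
                    "domain_index", "domain_total", "c_evalue", "i_evalue",
                    "dom_score", "dom_bias", "hmm_from", "hmm_to",
                    "ali_from", "ali_to", "env_from", "env_to", "acc")

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' One row per domain hit. The 22 fixed columns are split on whitespace;
#' everything after the 22nd token is kept verbatim as `description`
#' (it may contain spaces, or be `-`).
#'
#' @param file path to a domtblout file.
#' @param text domtblout content as a single string (alternative to `file`).
#' @return data frame of hits with columns `target_name`,
#'   `target_accession`, `tlen`, `query_name`, `query_accession`, `qlen`,
#'   `seq_evalue`, `seq_score`, `seq_bias`, `domain_index`, `domain_total`,
#'   `c_evalue`, `i_evalue`, `dom_score`, `dom_bias`, `hmm_from`, `hmm_to`,
#'   `ali_from`, `ali_to`, `env_from`, `env_to`, `acc`, `description`.
#' @export
parse_domtblout <- function(file = NULL, text = NULL) {
  lines <- read_input_lines(file, text)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- which(keep)
  rows <- vector("list", length(data_lines))
  for (k in seq_along(data_lines)) {
    ln <- data_lines[k]
    m <- gregexpr("\\S+", ln)[[1]]
    if (length(m) < 22L)
      stop("domtblout line ", line_no[k], ": expected >= 22 columns, found ",
           length(m))
    tok <- regmatches(ln, gregexpr("\\S+", ln))[[1]][1:22]
    desc_start <- m[22L] + attr(m, "match.length")[22L]
    description <- sub("^\\s+", "", substring(ln, desc_start))
    if (!nzchar(description)) description <- "-"
    rows[[k]] <- c(tok, description)
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(
      c(rep(list(character()), 2), list(numeric()),
        rep(list(character()), 2), rep(list(numeric()), 17),
        list(character())),
      c(DOMTBL_COLS, "description")), stringsAsFactors = FALSE)
    # fix types below anyway
    return(df)
  }
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- c(DOMTBL_COLS, "description")
  for (col in DOMTBL_NUMERIC) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop("domtblout line ", line_no[bad[1L]], ": cannot parse numeric '",
           col, "' value '", df[[col]][bad[1L]], "'")
    df[[col]] <- v
  }
  for (col in c("domain_index", "domain_total", "hmm_from", "hmm_to",
                "ali_from", "ali_to", "env_from", "env_to", "tlen", "qlen"))
    df[[col]] <- as.integer(df[[col]])
  rownames(df) <- NULL
  df
}

#' Write domain hits in domtblout dialect
#'
#' Emits text that [parse_domtblout()] reads back with identical field
#' values (numbers are written with full precision). Used for fixtures and
#' to persist filtered hit tables.
#'
#' @param hits data frame of hits as returned by [parse_domtblout()].
#' @param file output path or connection; `NULL` returns the text.
#' @return the text when `file` is `NULL`, otherwise invisibly `NULL`.
#' @export
write_domtblout <- function(hits, file = NULL) {
  header <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    paste("# target name", "accession", "tlen", "query name", "accession",
          "qlen", "E-value", "score", "bias", "#", "of", "c-Evalue",
          "i-Evalue", "score", "bias", "from", "to", "from", "to", "from",
          "to", "acc", "description of target", sep = " "),
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  if (nrow(hits) == 0L) return(emit_lines(header, file))
  num <- function(x) vapply(x, function(v) format(v, digits = 17,
                                                  trim = TRUE), "")
  fields <- cbind(
    hits$target_name, hits$target_accession, num(hits$tlen),
    hits$query_name, hits$query_accession, num(hits$qlen),
    num(hits$seq_evalue), num(hits$seq_score), num(hits$seq_bias),
    num(hits$domain_index), num(hits$domain_total),
    num(hits$c_evalue), num(hits$i_evalue),
    num(hits$dom_score), num(hits$dom_bias),
    num(hits$hmm_from), num(hits$hmm_to),
    num(hits$ali_from), num(hits$ali_to),
    num(hits$env_from), num(hits$env_to), num(hits$acc),
    hits$description)
  lines <- apply(fields, 1L, paste, collapse = " ")
  emit_lines(c(header, lines), file)
}

#' Filter domain hits at E-value thresholds
#'
#' Keeps exactly the hits with full-sequence E-value and per-domain
#' conditional E-value (c-Evalue) at or below their thresholds; both
#' criteria are inclusive and both default to the 0.001 used for repertoire
#' construction. Order is preserved.
#'
#' @param hits data frame of hits.
#' @param seq_evalue_max full-sequence E-value threshold (default `1e-3`).
#' @param dom_evalue_max conditional per-domain E-value threshold
#'   (default `1e-3`).
#' @return the kept hits.
#' @export
filter_hits <- function(hits, seq_evalue_max = 1e-3, dom_evalue_max = 1e-3) {
  stopifnot(seq_evalue_max > 0, dom_evalue_max > 0)
  keep <- hits$seq_evalue <= seq_evalue_max & hits$c_evalue <= dom_evalue_max
  res <- hits[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collapse overlapping domain envelopes within a query
#'
#' Optional de-duplication (off by default in the pipeline): within each
#' query sequence, hits whose envelope coordinates overlap a better-scoring
#' kept hit are dropped (greedy by descending domain score).
#'
#' @param hits data frame of hits.
#' @return the retained hits, original order.
#' @export
dedup_overlaps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  keep <- logical(nrow(hits))
  for (q in unique(hits$query_name)) {
    idx <- which(hits$query_name == q)
    idx <- idx[order(-hits$dom_score[idx])]
    taken <- list()
    for (i in idx) {
      from <- hits$env_from[i]; to <- hits$env_to[i]
      overlaps <- any(vapply(taken, function(r) from <= r[2] && to >= r[1],
                             logical(1)))
      if (!overlaps) {
        keep[i] <- TRUE
        taken[[length(taken) + 1L]] <- c(from, to)
      }
    }
  }
  res <- hits[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a domain repertoire from filtered hits
#'
#' Every hit contributes one copy of its domain family; the repertoire maps
#' each family seen at least once to its copy count.
#'
#' @param hits data frame of (already filtered) hits.
#' @param taxon organism name the repertoire belongs to.
#' @return an object of class `domain_repertoire`: a list with `taxon` and
#'   `counts` (named integer vector, names sorted).
#' @export
build_repertoire <- function(hits, taxon) {
  stopifnot(is.character(taxon), length(taxon) == 1L, nzchar(taxon))
  if (nrow(hits) == 0L) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    tab <- table(hits$target_name)
    counts <- stats::setNames(as.integer(tab), names(tab))
    counts <- counts[order(names(counts))]
  }
  structure(list(taxon = taxon, counts = counts),
            class = "domain_repertoire")
}

#' @export
print.domain_repertoire <- function(x, ...) {
  cat("Domain repertoire of", x$taxon, "-", length(x$counts),
      "families,", sum(x$counts), "copies\n")
  if (length(x$counts) > 0L) print(utils::head(x$counts, 20L))
  invisible(x)
}

#' Construct a repertoire directly from counts
#'
#' @param taxon organism name.
#' @param counts named non-negative integer vector; zero entries are
#'   dropped (absent domains are omitted from repertoires).
#' @return a `domain_repertoire`.
#' @export
domain_repertoire <- function(taxon, counts) {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    if (is.null(names(counts))) stop("'counts' must be named by domain")
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[order(names(counts))]
  }
  structure(list(taxon = taxon, counts = counts),
            class = "domain_repertoire")
}

#' Union of domain names across repertoires
#'
#' @param repertoires list of `domain_repertoire` objects.
#' @return lexicographically sorted character vector of domain names seen
#'   in at least one repertoire (the non-redundant domain set).
#' @export
nonredundant_domains <- function(repertoires) {
  nm <- unique(unlist(lapply(repertoires, function(r) names(r$counts)),
                      use.names = FALSE))
  sort(nm)
}

#' Write / read a repertoire as two-column TSV
#'
#' `domain<TAB>count`, sorted by domain name.
#' @param repertoire a `domain_repertoire`.
#' @param file output path.
#' @return the path invisibly (`write`); a `domain_repertoire` (`read`).
#' @export
write_repertoire_tsv <- function(repertoire, file) {
  df <- data.frame(domain = names(repertoire$counts),
                   count = as.integer(repertoire$counts))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_repertoire_tsv
#' @param taxon taxon name to attach when reading.
#' @export
read_repertoire_tsv <- function(file, taxon) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  domain_repertoire(taxon, stats::setNames(df$count, df$domain))
}
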