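# Branch-wise interpretation of ancestral count changes: appearance from
# zero is one gain (plus duplications for any further copies), an increment
# of an existing count is that many duplications, a decrement is that many
# unit losses. A branch never carries both a loss and a gain/duplication
# for the same domain.

#' Classify the count change along one branch
#'
#' @param parent_count reconstructed copy count at the parent node.
#' @param child_count copy count at the child node.
#' @return integer vector `c(gains, duplications, losses)`:
#'   * parent 0, child k > 0: one gain and k - 1 duplications;
#'   * child > parent > 0: child - parent duplications;
#'   * child < parent: parent - child losses (each unit decrement is one
#'     loss event);
#'   * no change: all zero.
#' @examples
#' classify_branch(1, 4)  # 3 duplications
#' classify_branch(4, 0)  # 4 losses
#' @export
classify_branch <- function(parent_count, child_count) {
  stopifnot(length(parent_count) == 1L, length(child_count) == 1L,
            parent_count >= 0, child_count >= 0)
  p <- as.integer(parent_count); ch <- as.integer(child_count)
  if (p == 0L && ch > 0L) {
    out <- c(1L, ch - 1L, 0L)
  } else if (ch > p) {
    out <- c(0L, ch - p, 0L)
  } else if (ch < p) {
    out <- c(0L, 0L, p - ch)
  } else {
    out <- c(0L, 0L, 0L)
  }
  stats::setNames(out, c("gains", "duplications", "losses"))
}

#' Call gain/duplication/loss events on every branch
#'
#' Applies the branch classification to (parent state, child state) for
#' every branch and domain; zero-event records are dropped. Output order is
#' deterministic: branches in preorder, then domain name.
#'
#' @param phy rooted `phylo` with node labels.
#' @param assignments list of `ancestral_assignment` objects covering every
#'   node of `phy` (see [reconstruct_asr()]).
#' @return data frame with columns `parent`, `child`, `domain`, `gains`,
#'   `duplications`, `losses`.
#' @export
call_events <- function(phy, assignments) {
  if (inherits(assignments, "ancestral_assignment"))
    assignments <- list(assignments)
  labs <- node_labels(phy)
  doms <- vapply(assignments, function(a) a$domain, "")
  assignments <- assignments[order(doms)]
  for (a in assignments) {
    missing <- setdiff(labs, names(a$state))
    if (length(missing) > 0L)
      stop("assignment for domain '", a$domain,
           "' missing nodes: ", paste(missing, collapse = ", "))
  }
  br <- branch_table(phy)
  rows <- list()
  for (b in seq_len(nrow(br))) {
    for (a in assignments) {
      p <- a$state[[br$parent[b]]]
      ch <- a$state[[br$child[b]]]
      if (p == ch) next
      ev <- classify_branch(p, ch)
      rows[[length(rows) + 1L]] <- data.frame(
        parent = br$parent[b], child = br$child[b], domain = a$domain,
        gains = ev[["gains"]], duplications = ev[["duplications"]],
        losses = ev[["losses"]], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_event_records())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Convert a typed event log to branch event records
#'
#' Published event tables usually list one row per branch with an event
#' type and a count (e.g. `duplication 3`). This expands such a log into
#' the wide `gains`/`duplications`/`losses` record format used by
#' [summarize_events()] and [export_itol()].
#'
#' @param log data frame with columns `parent`, `child`, `event`
#'   (`"gain"`, `"duplication"` or `"loss"`), `count`, and optionally
#'   `domain`.
#' @param domain domain name to attach when `log` has no `domain` column.
#' @return branch event records data frame.
#' @export
events_from_typed_log <- function(log, domain = "Ca_hom_mod") {
  stopifnot(all(c("parent", "child", "event", "count") %in% names(log)))
  bad <- setdiff(log$event, c("gain", "duplication", "loss"))
  if (length(bad) > 0L)
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  if (!"domain" %in% names(log)) log$domain <- domain
  data.frame(
    parent = log$parent, child = log$child, domain = log$domain,
    gains = ifelse(log$event == "gain", log$count, 0L),
    duplications = ifelse(log$event == "duplication", log$count, 0L),
    losses = ifelse(log$event == "loss", log$count, 0L),
    stringsAsFactors = FALSE)
}

empty_event_records <- function() {
  data.frame(parent = character(), child = character(),
             domain = character(), gains = integer(),
             duplications = integer(), losses = integer(),
             stringsAsFactors = FALSE)
}

#' Summarize branch event records
#'
#' @param records data frame of branch event records (see [call_events()]).
#' @return list with `totals` (named vector: gains, duplications, losses,
#'   total) and `per_domain` (data frame of per-domain sums).
#' @export
summarize_events <- function(records) {
  totals <- c(gains = sum(records$gains),
              duplications = sum(records$duplications),
              losses = sum(records$losses))
  totals <- c(totals, total = sum(totals))
  per_domain <- if (nrow(records) == 0L) {
    data.frame(domain = character(), gains = integer(),
               duplications = integer(), losses = integer(),
               total = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(records[c("gains", "duplications", "losses")],
                            by = list(domain = records$domain), FUN = sum)
    agg$total <- agg$gains + agg$duplications + agg$losses
    agg[order(agg$domain), , drop = FALSE]
  }
  rownames(per_domain) <- NULL
  list(totals = totals, per_domain = per_domain)
}

#' Write / read branch event records as TSV
#'
#' `parent<TAB>child<TAB>domain<TAB>gains<TAB>duplications<TAB>losses`.
#' @param records event records data frame.
#' @param file path.
#' @return the path invisibly (`write`); a records data frame (`read`).
#' @export
write_events_tsv <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("parent", "child", "domain", "gains", "duplications", "losses")
  if (!all(need %in% names(df)))
    stop("event TSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}
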