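ITOL_COLORS <- c(gain = "#00A550", loss = "#FFFFFF",
                 duplication = "#6A0DAD")
# mid-branch positions staggered per event type so symbols don't overplot
ITOL_POSITIONS <- c(gain = 0.25, duplication = 0.5, loss = 0.75)

#' Export branch events as an iTOL symbol dataset
#'
#' Emits a `DATASET_SYMBOL` annotation file for the Interactive Tree Of
#' Life: one data line per (branch, event type), anchored to the child node
#' label, square symbols (shape 2), gain = green `#00A550`, loss = white
#' `#FFFFFF`, duplication = purple `#6A0DAD`, symbol size scaled linearly
#' with the event count.
#'
#' @param phy rooted `phylo` with node labels (branch anchors must exist).
#' @param records branch event records (see [call_events()]).
#' @param domain_filter optional domain name; only its events are exported.
#' @param label dataset label shown in iTOL.
#' @param base_size symbol size for a single event.
#' @param file output path; `NULL` returns the text.
#' @return the dataset text when `file` is `NULL`, else invisibly `NULL`.
#' @export
export_itol <- function(phy, records, domain_filter = NULL,
                        label = "Domain events", base_size = 10,
                        file = NULL) {
  if (!is.null(domain_filter)) {
    records <- records[records$domain == domain_filter, , drop = FALSE]
    label <- paste(label, "-", domain_filter)
  }
  labs <- node_labels(phy)
  unknown <- setdiff(records$child, labs)
  if (length(unknown) > 0L)
    stop("event records reference nodes absent from the tree: ",
         paste(unique(unknown), collapse = ", "))
  header <- c(
    "DATASET_SYMBOL",
    "SEPARATOR TAB",
    paste("DATASET_LABEL", label, sep = "\t"),
    "COLOR\t#000000",
    "LEGEND_TITLE\tDomain events",
    "LEGEND_SHAPES\t2\t2\t2",
    paste("LEGEND_COLORS", ITOL_COLORS[["gain"]],
          ITOL_COLORS[["duplication"]], ITOL_COLORS[["loss"]], sep = "\t"),
    "LEGEND_LABELS\tGain\tDuplication\tLoss",
    "MAXIMUM_SIZE\t50",
    "DATA")
  lines <- character(0)
  if (nrow(records) > 0L) {
    long <- list()
    for (type in c("gain", "duplication", "loss")) {
      cnt <- switch(type, gain = records$gains,
                    duplication = records$duplications,
                    loss = records$losses)
      sel <- which(cnt > 0L)
      if (length(sel) == 0L) next
      long[[type]] <- stats::aggregate(
        list(count = cnt[sel]), by = list(child = records$child[sel]),
        FUN = sum)
      long[[type]]$type <- type
    }
    long <- do.call(rbind, long)
    if (!is.null(long) && nrow(long) > 0L) {
      long <- long[order(match(long$child, labs),
                         match(long$type, names(ITOL_COLORS))), ]
      # ID  symbol  size  color  fill  position
      lines <- paste(long$child, 2,
                     base_size * long$count,
                     ITOL_COLORS[long$type], 1,
                     ITOL_POSITIONS[long$type], sep = "\t")
    }
  }
  emit_lines(c(header, lines), file)
}
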