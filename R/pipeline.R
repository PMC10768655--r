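CONFIG_DEFAULTS <- list(
  fasta = NULL,            # named list/vector: taxon -> genome FASTA path
  domtblout = NULL,        # named list/vector: taxon -> domtblout path
  tree = NULL,             # newick file path
  seq_evalue_max = 1e-3,
  dom_evalue_max = 1e-3,
  min_aa = 50L,
  orf_mode = "maximal",
  tie_break = "root-smallest",
  domain_filter = NULL,    # e.g. "Ca_hom_mod"
  out_dir = "domrep_out",
  seed = NULL,
  verbose = TRUE)

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; absent keys take the defaults (E-value
#' thresholds `1e-3`, `min_aa` 50, maximal ORF mode, root-smallest
#' tie-break).
#'
#' @param path YAML file.
#' @return named list of class `domrep_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw)
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a `domrep_config` (or plain list of settings).
#' @export
write_config <- function(config, path) {
  keep <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(keep, path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(cfg$seq_evalue_max > 0, cfg$dom_evalue_max > 0, cfg$min_aa >= 1)
  if (!cfg$orf_mode %in% c("maximal", "all-starts"))
    stop("orf_mode must be 'maximal' or 'all-starts'")
  if (!cfg$tie_break %in% c("root-smallest", "root-largest"))
    stop("tie_break must be 'root-smallest' or 'root-largest'")
  for (key in c("fasta", "domtblout")) {
    paths <- cfg[[key]]
    if (is.null(paths)) next
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stop("'", key, "' entries must be named by taxon")
    missing <- paths[!file.exists(unlist(paths))]
    if (length(missing) > 0L)
      stop("missing ", key, " file(s): ",
           paste(unlist(missing), collapse = ", "))
  }
  if (!is.null(cfg$tree) && !file.exists(cfg$tree))
    stop("missing tree file: ", cfg$tree)
  structure(cfg, class = "domrep_config")
}

#' Run the full domain-repertoire evolution pipeline
#'
#' Executes the stages in order -- ORF extraction (when genome FASTAs are
#' given), domain annotation from domtblout tables, matrix assembly,
#' ancestral reconstruction, event calling, iTOL export -- skipping stages
#' whose inputs are supplied pre-computed. Running a profile-HMM search is
#' never attempted: domtblout tables are declared inputs. All outputs land
#' in `out_dir` together with a manifest listing each file with an MD5
#' checksum; a fixed config and inputs give byte-identical outputs.
#'
#' @param config a `domrep_config` from [load_config()], or a list of the
#'   same settings.
#' @return invisibly, the manifest data frame (`file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "domrep_config")) {
    config <- utils::modifyList(CONFIG_DEFAULTS, config)
    config <- validate_config(config)
  }
  cfg <- config
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add_out <- function(p) outputs <<- c(outputs, p)

  stage <- "orfs"
  res <- tryCatch({
    if (!is.null(cfg$fasta)) {
      for (taxon in names(cfg$fasta)) {
        genome <- read_fasta(cfg$fasta[[taxon]])
        orfs <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i)
          find_orfs(genome[i, ], min_aa = cfg$min_aa, mode = cfg$orf_mode)))
        say("[orfs] ", taxon, ": ", nrow(orfs), " ORFs >= ", cfg$min_aa,
            " aa")
        faa <- file.path(cfg$out_dir, paste0(taxon, ".faa"))
        write_protein_fasta(orfs, faa)
        add_out(faa)
      }
    }

    stage <- "annotate"
    if (is.null(cfg$domtblout))
      stop("no domtblout inputs; profile-HMM hit tables are required")
    repertoires <- list()
    for (taxon in names(cfg$domtblout)) {
      hits <- parse_domtblout(cfg$domtblout[[taxon]])
      kept <- filter_hits(hits, cfg$seq_evalue_max, cfg$dom_evalue_max)
      say("[annotate] ", taxon, ": ", nrow(kept), "/", nrow(hits),
          " hits kept at E <= ", cfg$seq_evalue_max)
      rep <- build_repertoire(kept, taxon)
      rep_path <- file.path(cfg$out_dir, paste0(taxon, ".repertoire.tsv"))
      write_repertoire_tsv(rep, rep_path)
      add_out(rep_path)
      repertoires[[taxon]] <- rep
    }

    stage <- "matrix"
    m <- build_matrix(repertoires)
    say("[matrix] ", nrow(m), " taxa x ", ncol(m), " domains")
    mat_path <- file.path(cfg$out_dir, "matrix.tsv")
    write_matrix_tsv(m, mat_path)
    add_out(mat_path)

    stage <- "asr"
    if (is.null(cfg$tree)) stop("no tree input; a rooted newick is required")
    phy <- parse_newick(paste(readLines(cfg$tree, warn = FALSE),
                              collapse = ""))
    domains <- colnames(m)
    if (!is.null(cfg$domain_filter)) {
      if (!cfg$domain_filter %in% domains)
        stop("domain filter '", cfg$domain_filter,
             "' not present in the matrix")
      domains <- cfg$domain_filter
    }
    asr <- reconstruct_asr(phy, m, policy = cfg$tie_break,
                           domains = domains)
    say("[asr] ", length(asr), " domains reconstructed; total cost ",
        sum(vapply(asr, function(a) a$cost, 0L)))
    asr_path <- file.path(cfg$out_dir, "asr.tsv")
    utils::write.table(asr_table(asr), asr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add_out(asr_path)

    stage <- "events"
    records <- call_events(phy, asr)
    summ <- summarize_events(records)
    say("[events] gains ", summ$totals[["gains"]], ", duplications ",
        summ$totals[["duplications"]], ", losses ",
        summ$totals[["losses"]])
    ev_path <- file.path(cfg$out_dir, "events.tsv")
    write_events_tsv(records, ev_path)
    add_out(ev_path)

    stage <- "itol"
    itol_path <- file.path(cfg$out_dir, "events_itol.txt")
    export_itol(phy, records, domain_filter = cfg$domain_filter,
                file = itol_path)
    add_out(itol_path)
    TRUE
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  stage <- "manifest"
  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    bytes = unname(file.size(outputs)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("[done] ", nrow(manifest), " artifacts in ", cfg$out_dir)
  invisible(manifest)
}
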