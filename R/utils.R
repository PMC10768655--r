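#' Evaluate code with a temporarily seeded RNG
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded simulators are byte-reproducible without clobbering the
#' session's random stream. A `NULL` seed evaluates `code` unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer or NULL")
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Write lines to `file` (path or connection); file = NULL returns a single
# newline-terminated string instead (used by fixture generators).
emit_lines <- function(lines, file = NULL) {
  if (is.null(file)) {
    if (length(lines) == 0L) return("")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  writeLines(lines, file)
  invisible(NULL)
}

# Accept either a path/connection or literal text for parsers.
read_input_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    return(unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE))
  }
  if (is.null(file)) stop("either 'file' or 'text' must be supplied")
  readLines(file, warn = FALSE)
}
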