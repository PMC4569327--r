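#' Write / read an evaluation trace as JSON lines
#'
#' One JSON object per line and per evaluation: `eval_index`, genome
#' `values`, the matrix of clamped replicate `raw` patterns, the median
#' `phenotype` and the archive `cell`.  The format round-trips losslessly
#' through [read_trace_jsonl()], so every report quantity can be recomputed
#' from the saved log.
#'
#' @param state a `pse_state` (or [evaluate_design()] result).
#' @param path output file.
#' @export
write_trace_jsonl <- function(state, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(state$trace_n)) {
    rec <- state$trace[[i]]
    writeLines(jsonlite::toJSON(
      list(eval_index = rec$eval_index, values = rec$values,
           raw = rec$raw, phenotype = rec$phenotype, cell = rec$cell),
      digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_trace_jsonl
#' @return `read_trace_jsonl()` returns the list of evaluation records.
#' @export
read_trace_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec$values <- as.numeric(rec$values)
    rec$raw <- matrix(as.numeric(rec$raw), ncol = length(rec$phenotype))
    rec$phenotype <- as.numeric(rec$phenotype)
    rec$cell <- as.integer(rec$cell)
    rec$eval_index <- as.integer(rec$eval_index)
    rec
  })
}

#' Write the per-evaluation CSV summary
#'
#' Columns: `eval_index`, genome values, phenotype, cell coordinates and the
#' cumulative `volume` discovered.
#'
#' @inheritParams write_trace_jsonl
#' @export
write_trace_csv <- function(state, path) {
  write.csv(pse_trace(state), path, row.names = FALSE)
  invisible(path)
}
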