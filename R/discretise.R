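#' Pattern-space discretisation
#'
#' Defines the regular grid of cells covering the pattern (phenotype) space:
#' one step size per dimension, anchored on 0, with optional artificial
#' clamping bounds used to focus the exploration (values beyond a clamp are
#' set back to it, per simulation, before any aggregation).
#'
#' @param step positive numeric vector, one step size per pattern dimension.
#' @param lower_clamp,upper_clamp optional numeric vectors (NA = no clamp on
#'   that dimension) applied to raw pattern values before cell assignment.
#' @return An object of class `pse_discretisation`.
#' @examples
#' d <- discretisation(step = c(1, 0.2, 0.1), lower_clamp = c(NA, -1, NA))
#' discretise_phenotype(c(64, 0.5, 0.25), d)
#' @export
discretisation <- function(step, lower_clamp = NULL, upper_clamp = NULL) {
  step <- as.numeric(step)
  m <- length(step)
  stopifnot(m >= 1, all(step > 0))
  if (is.null(lower_clamp)) lower_clamp <- rep(NA_real_, m)
  if (is.null(upper_clamp)) upper_clamp <- rep(NA_real_, m)
  lower_clamp <- as.numeric(lower_clamp)
  upper_clamp <- as.numeric(upper_clamp)
  stopifnot(length(lower_clamp) == m, length(upper_clamp) == m)
  both <- !is.na(lower_clamp) & !is.na(upper_clamp)
  stopifnot(all(lower_clamp[both] < upper_clamp[both]))
  structure(list(step = step, lower_clamp = lower_clamp,
                 upper_clamp = upper_clamp, m = m),
            class = "pse_discretisation")
}

#' @export
print.pse_discretisation <- function(x, ...) {
  cat("Pattern-space discretisation (", x$m, " dimensions)\n", sep = "")
  cat("  step:", x$step, "\n")
  if (any(!is.na(x$lower_clamp))) cat("  lower clamp:", x$lower_clamp, "\n")
  if (any(!is.na(x$upper_clamp))) cat("  upper clamp:", x$upper_clamp, "\n")
  invisible(x)
}

#' Clamp a raw pattern vector to the discretisation bounds
#'
#' @param raw numeric pattern vector.
#' @param d a [discretisation()].
#' @return The clamped vector.
#' @export
clamp_pattern <- function(raw, d) {
  if (length(raw) != d$m)
    stop("pattern has length ", length(raw), ", expected ", d$m)
  lo <- d$lower_clamp
  hi <- d$upper_clamp
  out <- raw
  has_lo <- !is.na(lo)
  has_hi <- !is.na(hi)
  out[has_lo] <- pmax(out[has_lo], lo[has_lo])
  out[has_hi] <- pmin(out[has_hi], hi[has_hi])
  out
}

#' Locate a pattern in its archive cell
#'
#' Clamps the raw pattern, then assigns each dimension to the half-open cell
#' `[k*step, (k+1)*step)` anchored on 0; a value exactly on a boundary belongs
#' to the upper cell.
#'
#' @inheritParams clamp_pattern
#' @return list with `phenotype` (clamped values) and `cell` (integer coords).
#' @export
discretise_phenotype <- function(raw, d) {
  ph <- clamp_pattern(raw, d)
  cell <- as.integer(floor(ph / d$step))
  list(phenotype = ph, cell = cell)
}

cell_key <- function(cell) paste(cell, collapse = ",")

key_to_cell <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

#' Hit-map archive
#'
#' The sparse archive at the heart of the exploration: an associative table
#' from integer cell coordinates to the number of evaluated individuals whose
#' phenotype fell in that cell.  Absent cells implicitly count 0, so the
#' (possibly unbounded) pattern space never needs explicit bounds.  The object
#' has reference semantics (a hash environment); use [hitmap_copy()] for an
#' independent copy.
#'
#' @return An empty `pse_hitmap`.
#' @seealso [record_hit()], [hit_count()], [volume_discovered()]
#' @export
hitmap <- function() {
  structure(list(counts = new.env(hash = TRUE, parent = emptyenv())),
            class = "pse_hitmap")
}

#' Record one hit in a cell
#'
#' @param h a [hitmap()].
#' @param cell integer cell coordinates.
#' @return `h`, invisibly (the archive is updated in place).
#' @export
record_hit <- function(h, cell) {
  key <- cell_key(cell)
  cur <- h$counts[[key]]
  h$counts[[key]] <- if (is.null(cur)) 1L else cur + 1L
  invisible(h)
}

#' Hit count of a cell (0 if never visited)
#' @inheritParams record_hit
#' @export
hit_count <- function(h, cell) {
  cur <- h$counts[[cell_key(cell)]]
  if (is.null(cur)) 0L else cur
}

#' Number of pattern-space cells discovered
#'
#' The exploration-progress metric: the number of cells with a positive hit
#' count.
#' @param h a [hitmap()].
#' @export
volume_discovered <- function(h) length(h$counts)

#' Total number of recorded hits
#' @param h a [hitmap()].
#' @export
hit_total <- function(h) {
  keys <- ls(h$counts, all.names = TRUE)
  if (length(keys) == 0) return(0L)
  sum(vapply(keys, function(k) h$counts[[k]], integer(1)))
}

#' Independent copy of a hit map
#' @param h a [hitmap()].
#' @export
hitmap_copy <- function(h) {
  out <- hitmap()
  for (k in ls(h$counts, all.names = TRUE)) out$counts[[k]] <- h$counts[[k]]
  out
}

#' @export
as.data.frame.pse_hitmap <- function(x, ...) {
  keys <- ls(x$counts, all.names = TRUE)
  if (length(keys) == 0)
    return(data.frame(cell = character(0), count = integer(0)))
  data.frame(cell = keys,
             count = vapply(keys, function(k) x$counts[[k]], integer(1)),
             row.names = NULL)
}

#' @export
print.pse_hitmap <- function(x, ...) {
  cat("Hit-map archive:", volume_discovered(x), "cells,",
      hit_total(x), "hits\n")
  invisible(x)
}
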