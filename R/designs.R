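#' A-priori experiment designs
#'
#' Containers for point sets in the parameter space produced by the three
#' baseline samplers benchmarked against the exploration engine.
#'
#' @param points n x K matrix of points inside the bounds.
#' @param type provenance label: "grid", "lhs" or "sobol".
#' @param bounds the [bounds()] the points live in.
#' @return An object of class `pse_design`.
#' @export
design <- function(points, type, bounds) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == bounds$k,
            all(points >= matrix(bounds$lower, nrow(points), bounds$k,
                                 byrow = TRUE)),
            all(points <= matrix(bounds$upper, nrow(points), bounds$k,
                                 byrow = TRUE)))
  structure(list(points = points, type = type, bounds = bounds),
            class = "pse_design")
}

#' @export
print.pse_design <- function(x, ...) {
  cat("Design (", x$type, "): ", nrow(x$points), " points in ",
      x$bounds$k, " dimensions\n", sep = "")
  invisible(x)
}

#' Regular grid design
#'
#' `levels` evenly spaced values per dimension, endpoints included, full
#' Cartesian product: `levels^K` points.
#'
#' @param levels samples per parameter domain (>= 2).
#' @param bnd a [bounds()].
#' @export
regular_grid <- function(levels, bnd) {
  stopifnot(levels >= 2)
  axes <- lapply(seq_len(bnd$k), function(k)
    seq(bnd$lower[k], bnd$upper[k], length.out = levels))
  design(as.matrix(expand.grid(axes)), "grid", bnd)
}

#' Latin hypercube design
#'
#' Per dimension, one point uniformly jittered inside each of `n` equal
#' strata, with strata assigned by independent uniform permutations
#' (plain, non-optimised LHS via `lhs::randomLHS`, current RNG stream).
#'
#' @param n number of points.
#' @param bnd a [bounds()].
#' @export
latin_hypercube <- function(n, bnd) {
  stopifnot(n >= 1)
  u <- lhs::randomLHS(n, bnd$k)
  pts <- sweep(sweep(u, 2, bnd$upper - bnd$lower, "*"), 2, bnd$lower, "+")
  design(pts, "lhs", bnd)
}

# Joe-Kuo (new-joe-kuo-6) primitive polynomials and initial direction
# numbers for Sobol dimensions 2..10; dimension 1 is the van der Corput
# sequence in base 2.
.sobol_dirs <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

# 31-bit direction integers v_j for one dimension, j = 1..nbits.
sobol_direction_integers <- function(dim, nbits = 31L) {
  if (dim == 1L) {
    m <- rep(1L, nbits)
  } else {
    dd <- .sobol_dirs[[dim - 1L]]
    s <- dd$s; a <- dd$a
    m <- integer(nbits)
    m[seq_len(min(s, nbits))] <- dd$m[seq_len(min(s, nbits))]
    if (nbits > s) {
      for (j in (s + 1L):nbits) {
        val <- bitwXor(m[j - s], bitwShiftL(m[j - s], s))
        if (s > 1L) {
          for (i in seq_len(s - 1L)) {
            a_i <- bitwAnd(bitwShiftR(a, s - 1L - i), 1L)
            if (a_i == 1L) val <- bitwXor(val, bitwShiftL(m[j - i], i))
          }
        }
        m[j] <- val
      }
    }
  }
  vapply(seq_len(nbits), function(j) bitwShiftL(m[j], nbits - j), integer(1))
}

#' Sobol sequence design
#'
#' The first `n` points of the standard unscrambled Sobol sequence in
#' Gray-code order (Joe-Kuo direction numbers, the all-zero initial point
#' skipped), affinely rescaled to the bounds.  Deterministic; supports up to
#' 10 dimensions.
#'
#' @param n number of points.
#' @param bnd a [bounds()].
#' @export
sobol_sequence <- function(n, bnd) {
  stopifnot(n >= 1)
  k <- bnd$k
  if (k > 10L)
    stop("Sobol direction-number table covers up to 10 dimensions, got ", k)
  nbits <- 31L
  v <- lapply(seq_len(k), sobol_direction_integers, nbits = nbits)
  u <- matrix(0, n, k)
  state <- integer(k)
  for (i in seq_len(n)) {
    # transition from point i-1 to point i (the zero point is i = 0):
    # flip the direction whose index is the lowest zero bit of i-1
    prev <- i - 1L
    c_ix <- 1L
    while (bitwAnd(prev, 1L) == 1L) {
      prev <- bitwShiftR(prev, 1L)
      c_ix <- c_ix + 1L
    }
    for (d in seq_len(k)) state[d] <- bitwXor(state[d], v[[d]][c_ix])
    u[i, ] <- state / 2^nbits
  }
  pts <- sweep(sweep(u, 2, bnd$upper - bnd$lower, "*"), 2, bnd$lower, "+")
  design(pts, "sobol", bnd)
}

#' Evaluate a design through the model/measure pipeline
#'
#' Each design point is evaluated exactly like an exploration individual —
#' same replicate RNG streams, per-replicate clamping, median aggregation and
#' cell assignment — and the same trace format is produced, so discovery
#' curves of designs and explorations are directly comparable.
#'
#' @param des a [design()].
#' @param model a [model_plugin()].
#' @param replications replicate simulations per point.
#' @param d the pattern-space [discretisation()].
#' @param master_seed seed for the evaluation streams.
#' @return A `pse_state`-like object (hit map, trace); use [pse_trace()].
#' @export
evaluate_design <- function(des, model, replications, d, master_seed = 42L) {
  cfg <- list(replications = as.integer(replications), discretisation = d)
  state <- new.env(parent = emptyenv())
  state$hitmap <- hitmap()
  state$eval_count <- 0L
  state$trace <- vector("list", max(256L, nrow(des$points)))
  state$trace_n <- 0L
  rng <- rng_master(master_seed)
  state$eval_rng <- rng$eval_base
  class(state) <- c("pse_design_eval", "pse_state")
  for (i in seq_len(nrow(des$points))) {
    g <- genome(des$points[i, ])
    do_evaluation(state, g, model, cfg)
  }
  state$population <- NULL
  state
}
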