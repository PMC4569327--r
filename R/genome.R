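#' Parameter-space bounds
#'
#' The search domain: a box in R^K, one `[lower, upper]` interval per model
#' parameter.
#'
#' @param lower,upper numeric vectors of equal length with `lower < upper`.
#' @param names optional parameter names.
#' @return An object of class `pse_bounds`.
#' @export
bounds <- function(lower, upper, names = NULL) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), length(lower) >= 1,
            all(lower < upper))
  if (!is.null(names)) stopifnot(length(names) == length(lower))
  structure(list(lower = lower, upper = upper, k = length(lower),
                 names = names),
            class = "pse_bounds")
}

#' @export
print.pse_bounds <- function(x, ...) {
  nm <- if (is.null(x$names)) paste0("p", seq_len(x$k)) else x$names
  cat("Parameter bounds (K = ", x$k, ")\n", sep = "")
  for (i in seq_len(x$k))
    cat(sprintf("  %-10s [%g, %g]\n", nm[i], x$lower[i], x$upper[i]))
  invisible(x)
}

clamp_to_bounds <- function(values, b) pmin(pmax(values, b$lower), b$upper)

#' Construct a genome
#'
#' A genome encodes one value per model parameter, plus the self-adaptive
#' per-gene mutation scales used by the adaptive Cauchy mutation.  Scales are
#' dimensionless: the mutation step multiplies them by the domain width.
#'
#' @param values numeric parameter vector (inside the bounds).
#' @param scales positive mutation scales; default 0.1 per gene.
#' @export
genome <- function(values, scales = rep(0.1, length(values))) {
  stopifnot(length(values) == length(scales), all(scales > 0))
  structure(list(values = as.numeric(values), scales = as.numeric(scales)),
            class = "pse_genome")
}

#' Draw a uniform random genome
#'
#' Initial individuals are drawn uniformly in each parameter's domain, from
#' the current RNG stream.
#'
#' @param b a [bounds()].
#' @param scale_init initial mutation scale per gene.
#' @export
random_genome <- function(b, scale_init = 0.1) {
  genome(runif(b$k, b$lower, b$upper), rep(scale_init, b$k))
}

#' Simulated binary crossover (SBX)
#'
#' Per-gene SBX with distribution index `eta`: the spread factor beta is drawn
#' from the standard polynomial density, the two symmetric children are
#' formed, and one of the two is kept (chosen at random per gene), so the
#' expected child equals the parents' midpoint.  Mutation scales are
#' recombined as the per-gene arithmetic mean.  The child is clamped to the
#' bounds.
#'
#' @param a,b parent [genome()]s sharing the same bounds.
#' @param bnd the shared [bounds()].
#' @param eta positive SBX distribution index (default 2).
#' @return One child genome.
#' @export
sbx_crossover <- function(a, b, bnd, eta = 2) {
  k <- length(a$values)
  u <- runif(k)
  beta <- ifelse(u <= 0.5,
                 (2 * u) ^ (1 / (eta + 1)),
                 (1 / (2 * (1 - u))) ^ (1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * a$values + (1 - beta) * b$values)
  c2 <- 0.5 * ((1 - beta) * a$values + (1 + beta) * b$values)
  pick <- runif(k) < 0.5
  child <- ifelse(pick, c1, c2)
  genome(clamp_to_bounds(child, bnd), (a$scales + b$scales) / 2)
}

#' Self-adaptive Cauchy mutation
#'
#' Each gene's mutation scale is first perturbed log-normally,
#' `s' = s * exp(tau * N(0,1))` with `tau = 1/sqrt(2K)`, then the gene is
#' moved by `s' * (upper - lower) * Cauchy(0,1)`.  The heavy Cauchy tail
#' yields mostly small steps with occasional long jumps, keeping distant
#' regions of the domain reachable; the updated scales are stored back in the
#' genome.  Values are clamped to the bounds.
#'
#' @param g a [genome()].
#' @param bnd the [bounds()].
#' @return The mutated genome.
#' @export
adaptive_cauchy_mutate <- function(g, bnd) {
  k <- length(g$values)
  tau <- 1 / sqrt(2 * k)
  scales <- g$scales * exp(tau * rnorm(k))
  step <- scales * (bnd$upper - bnd$lower) * rcauchy(k)
  genome(clamp_to_bounds(g$values + step, bnd), scales)
}
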