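#' Measurement windows for the order parameters
#'
#' The two time horizons are tied to the geometry so that measured
#' displacements stay within the torus's unambiguous range:
#' `T_d = min(E_W, E_H) / (4 * step_size)` (relative diffusion) and
#' `T_v = min(E_W, E_H) / (2 * step_size)` (velocity).  Each measure is
#' averaged over up to five anchor times `t = steps - k*T` (k = 1..5);
#' anchors with `t < 0` are dropped (at the 32/0.05/1000 defaults all five
#' diffusion anchors are valid but only three velocity anchors fit).
#'
#' @param params a [flock_params()].
#' @param steps simulation length in steps.
#' @return An object of class `measure_config` with fields `t_d`, `t_v`,
#'   `anchors_d`, `anchors_v`, `normaliser`.
#' @export
measure_config <- function(params, steps = 1000) {
  e <- min(params$e_w, params$e_h)
  t_d <- as.integer(round(e / (4 * params$step_size)))
  t_v <- as.integer(round(e / (2 * params$step_size)))
  anchors <- function(T) {
    a <- steps - (1:5) * T
    as.integer(a[a >= 0 & a + T <= steps])
  }
  structure(list(t_d = t_d, t_v = t_v,
                 anchors_d = anchors(t_d), anchors_v = anchors(t_v),
                 normaliser = e, steps = as.integer(steps)),
            class = "measure_config")
}

#' @export
print.measure_config <- function(x, ...) {
  cat("Measure config: T_d =", x$t_d, "(anchors",
      paste(x$anchors_d, collapse = ", "), "), T_v =", x$t_v, "(anchors",
      paste(x$anchors_v, collapse = ", "), "), normaliser", x$normaliser,
      "\n")
  invisible(x)
}

#' Size of the largest cluster
#'
#' Particles within distance `r_vis` of one another (toroidal metric) are
#' connected; clusters are the connected components of the resulting graph,
#' and the first order parameter is the size of the largest one, measured on
#' the final state.
#'
#' @param positions n x 2 position matrix.
#' @param r_vis connection radius.
#' @param e_w,e_h torus dimensions.
#' @return Integer cluster size in `[1, n]`.
#' @export
largest_cluster_size <- function(positions, r_vis, e_w, e_h) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 1)
  .largest_cluster_cpp(positions, r_vis, e_w, e_h)
}

#' Voronoi neighbours under periodic boundaries
#'
#' Delaunay adjacency (the dual of the Voronoi diagram) computed on a 3x3
#' tiling of the points so that cells wrap correctly across the torus edges;
#' neighbours of the central-tile points are mapped back to original indices
#' and de-duplicated.  For fewer than 3 points, or when the tiled geometry is
#' degenerate (e.g. all collinear), the documented fallback is the 6 nearest
#' neighbours by toroidal distance.
#'
#' @inheritParams largest_cluster_size
#' @return List of integer neighbour index vectors (symmetric adjacency).
#' @export
voronoi_neighbours_torus <- function(positions, e_w, e_h) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 1) return(list(integer(0)))
  adj <- NULL
  if (n >= 3) {
    adj <- .torus_voronoi_cpp(positions, e_w, e_h)
    if (any(lengths(adj) == 0)) adj <- NULL # degenerate tiled geometry
  }
  if (is.null(adj)) {
    # degenerate-geometry fallback: 6 nearest neighbours, symmetrised
    dm <- .torus_dist_cpp(positions, e_w, e_h)
    diag(dm) <- Inf
    adj <- lapply(seq_len(n), function(i)
      order(dm[i, ])[seq_len(min(6L, n - 1L))])
    for (i in seq_len(n))
      for (j in adj[[i]])
        if (!(i %in% adj[[j]])) adj[[j]] <- sort(c(adj[[j]], i))
    adj <- lapply(adj, function(v) sort(unique(as.integer(v))))
  }
  adj
}

#' Relative diffusion
#'
#' The solid/liquid order parameter: for each anchor time t, each particle i
#' with Voronoi neighbours j (taken at time t) contributes
#' `mean_j(1 - r_ij^2(t) / r_ij^2(t + T_d))` with toroidal distances r_ij;
#' values are averaged over particles, then over anchors.  Rigid motion gives
#' exactly 0, fully mixing (liquid) motion about 1, and contraction negative
#' values.  Particles without neighbours are skipped; a coincident pair at
#' t + T_d uses the floor `(1e-6 * step_size)^2` on the denominator.  The raw
#' (unclamped) value is returned — clamping to the exploration's artificial
#' lower bound is the engine's job.
#'
#' @param traj a `flock_trajectory` containing each anchor t and t + T_d.
#' @param cfg a [measure_config()].
#' @return Raw relative diffusion (0 when no particle has neighbours at any
#'   anchor).
#' @export
relative_diffusion <- function(traj, cfg) {
  p <- traj$params
  eps2 <- (1e-6 * p$step_size)^2
  per_anchor <- numeric(0)
  for (t in cfg$anchors_d) {
    s0 <- snapshot_at(traj, t)
    s1 <- snapshot_at(traj, t + cfg$t_d)
    nbr <- voronoi_neighbours_torus(s0$positions, p$e_w, p$e_h)
    d0 <- .torus_dist_cpp(s0$positions, p$e_w, p$e_h)
    d1 <- .torus_dist_cpp(s1$positions, p$e_w, p$e_h)
    deg <- lengths(nbr)
    if (any(deg > 0)) {
      ii <- rep.int(seq_along(nbr), deg)
      jj <- unlist(nbr, use.names = FALSE)
      ix <- cbind(ii, jj)
      vals <- 1 - d0[ix]^2 / pmax(d1[ix]^2, eps2)
      per_particle <- rowsum(vals, ii)[, 1] / deg[deg > 0]
      per_anchor <- c(per_anchor, mean(per_particle))
    }
  }
  if (length(per_anchor) == 0) return(0)
  mean(per_anchor)
}

#' Normalized mean velocity
#'
#' The moving/stationary order parameter: the net displacement of each
#' particle over a window of `T_v` steps (minimal-image Euclidean distance
#' between its positions at t and t + T_v), averaged over particles and over
#' the valid anchors, divided by `min(E_W, E_H)`.  A particle moving straight
#' covers `T_v * step_size = min(E_W, E_H)/2` and scores exactly 0.5, the
#' maximum.
#'
#' @param traj a `flock_trajectory` containing each anchor t and t + T_v.
#' @param cfg a [measure_config()].
#' @export
mean_velocity <- function(traj, cfg) {
  if (length(cfg$anchors_v) == 0)
    stop("no valid velocity anchors: simulation shorter than T_v")
  p <- traj$params
  per_anchor <- vapply(cfg$anchors_v, function(t) {
    s0 <- snapshot_at(traj, t)
    s1 <- snapshot_at(traj, t + cfg$t_v)
    mean(toroidal_distance(s0$positions, s1$positions, p$e_w, p$e_h))
  }, numeric(1))
  mean(per_anchor) / cfg$normaliser
}

measure_snapshot_times <- function(cfg) {
  sort(unique(c(cfg$anchors_d, cfg$anchors_d + cfg$t_d,
                cfg$anchors_v, cfg$anchors_v + cfg$t_v, cfg$steps)))
}

#' Run one flocking simulation and measure its pattern
#'
#' Simulates the flock (initial state from the current RNG stream unless
#' `init` is given), storing exactly the snapshots the measures need, and
#' returns the raw pattern vector `(largest cluster size, relative
#' diffusion, mean velocity)`.
#'
#' @param params a [flock_params()].
#' @param steps simulation length (must be at least `T_v`).
#' @param init optional initial `flock_state`.
#' @return Named numeric vector `(cluster, delta, velocity)`.
#' @export
measure_pattern <- function(params, steps = 1000, init = NULL) {
  cfg <- measure_config(params, steps)
  if (length(cfg$anchors_v) == 0)
    stop("steps = ", steps, " is shorter than T_v = ", cfg$t_v)
  traj <- simulate_flock(params, steps, measure_snapshot_times(cfg),
                         init = init)
  final <- snapshot_at(traj, steps)
  c(cluster = as.numeric(largest_cluster_size(final$positions, params$r_vis,
                                              params$e_w, params$e_h)),
    delta = relative_diffusion(traj, cfg),
    velocity = mean_velocity(traj, cfg))
}

#' Built-in flocking model plugin
#'
#' Packages the boids simulator and the three order parameters as a model
#' plugin for the exploration engine.  The genome is the five free
#' parameters `(r_vis, min_sep, max_turn_s, max_turn_a, max_turn_c)`; the
#' bounds are `[0, min(E_W, E_H)]` for the two radii and `[0, pi]` for the
#' turn caps.  The default pattern-space discretisation uses steps
#' `(1, 0.2, 0.1)` with the artificial lower clamp of -1 on relative
#' diffusion (any lower replicate value is set back to -1 so the search is
#' not pushed towards ever-stronger contraction).
#'
#' @param base a [flock_params()] providing the fixed parameters
#'   (environment, boid count, speed).
#' @param steps simulation length per evaluation.
#' @return A [model_plugin()] with `bounds` and `discretisation` attached.
#' @export
flocking_model <- function(base = flock_params(), steps = 1000) {
  e <- min(base$e_w, base$e_h)
  b <- bounds(rep(0, 5), c(e, e, pi, pi, pi),
              names = c("r_vis", "min_sep", "max_turn_s", "max_turn_a",
                        "max_turn_c"))
  d <- discretisation(step = c(1, 0.2, 0.1),
                      lower_clamp = c(NA, -1, NA))
  force(base); force(steps)
  model_plugin(
    name = "flocking", k = 5, m = 3,
    fn = function(v) {
      p <- base
      p$r_vis <- v[1]; p$min_sep <- v[2]
      p$max_turn_s <- v[3]; p$max_turn_a <- v[4]; p$max_turn_c <- v[5]
      measure_pattern(p, steps)
    },
    bounds = b, discretisation = d)
}
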