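#' Boids flocking model parameters
#'
#' The collective-motion test model: `n_b` self-propelled boids on a 2-D
#' torus of size `e_w` x `e_h`.  At every time step each boid computes a new
#' heading from its neighbours within radius `r_vis` — avoiding a too-close
#' nearest neighbour (closer than `min_sep`) takes precedence over aligning
#' with the flockmates' mean heading and turning towards their mean position
#' — and then advances by `step_size` along the new heading.  All updates are
#' simultaneous.  The three `max_turn_*` angles cap the separation,
#' alignment and cohesion turns respectively.
#'
#' Defaults fix the environment at 32 x 32 with 128 boids and speed 0.05;
#' the five remaining parameters are the free parameters explored by the
#' engine.
#'
#' @param e_w,e_h environment width and height.
#' @param n_b number of boids.
#' @param step_size distance travelled per step.
#' @param r_vis vision radius (neighbourhood).
#' @param min_sep minimum separation; closer nearest neighbours trigger
#'   avoidance.
#' @param max_turn_s,max_turn_a,max_turn_c maximum turn angles (radians) for
#'   separation, alignment, cohesion.
#' @param separation_sign -1 (default) turns *away* from the too-close
#'   neighbour's heading; +1 applies the turn towards it.
#' @return An object of class `flock_params`.
#' @export
flock_params <- function(e_w = 32, e_h = 32, n_b = 128, step_size = 0.05,
                         r_vis = 4, min_sep = 1,
                         max_turn_s = pi / 8, max_turn_a = pi / 16,
                         max_turn_c = pi / 16, separation_sign = -1) {
  stopifnot(e_w > 0, e_h > 0, n_b >= 1, step_size > 0,
            r_vis >= 0, min_sep >= 0,
            max_turn_s >= 0, max_turn_s <= pi,
            max_turn_a >= 0, max_turn_a <= pi,
            max_turn_c >= 0, max_turn_c <= pi,
            separation_sign %in% c(-1, 1))
  structure(list(e_w = e_w, e_h = e_h, n_b = as.integer(n_b),
                 step_size = step_size, r_vis = r_vis, min_sep = min_sep,
                 max_turn_s = max_turn_s, max_turn_a = max_turn_a,
                 max_turn_c = max_turn_c, separation_sign = separation_sign),
            class = "flock_params")
}

#' @export
print.flock_params <- function(x, ...) {
  cat(sprintf(paste0("Flocking model: %d boids on a %g x %g torus, ",
                     "step %g\n  rVis %g, minSep %g, maxTurn S/A/C ",
                     "%.4g/%.4g/%.4g\n"),
              x$n_b, x$e_w, x$e_h, x$step_size, x$r_vis, x$min_sep,
              x$max_turn_s, x$max_turn_a, x$max_turn_c))
  invisible(x)
}

#' Turn limiter
#'
#' `limit_turn(a, m) = sign(a) * min(|a|, m)`: caps the magnitude of a turn
#' angle at `m` while preserving its sign.
#'
#' @param a turn angle (radians).
#' @param m maximum magnitude (radians, >= 0).
#' @export
limit_turn <- function(a, m) {
  stopifnot(all(m >= 0))
  sign(a) * pmin(abs(a), m)
}

#' Signed angle from one heading to another
#'
#' Returns the minimal-magnitude angle `d` in `(-pi, pi]` such that
#' `(from + d) mod 2pi == to`; exactly opposite headings give `+pi`.
#'
#' @param from,to headings (radians).
#' @export
angle_between <- function(from, to) {
  a <- (to - from) %% (2 * pi)
  ifelse(a > pi, a - 2 * pi, a)
}

#' Minimal-image displacement and distance on the torus
#'
#' The shortest displacement from `p` to `q` under periodic boundary
#' conditions, each component in `(-E/2, E/2]`.
#'
#' @param p,q length-2 position vectors (or matrices with 2 columns).
#' @param e_w,e_h torus dimensions.
#' @export
toroidal_delta <- function(p, q, e_w, e_h) {
  d <- q - p
  wrap1 <- function(v, E) {
    m <- v %% E
    ifelse(m > E / 2, m - E, m)
  }
  if (is.matrix(d)) cbind(wrap1(d[, 1], e_w), wrap1(d[, 2], e_h))
  else c(wrap1(d[1], e_w), wrap1(d[2], e_h))
}

#' @rdname toroidal_delta
#' @export
toroidal_distance <- function(p, q, e_w, e_h) {
  d <- toroidal_delta(p, q, e_w, e_h)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

wrap_position <- function(pos, e_w, e_h) {
  cbind(pos[, 1] %% e_w, pos[, 2] %% e_h)
}

new_flock_state <- function(positions, headings) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, length(headings) == nrow(positions))
  structure(list(positions = positions, headings = headings %% (2 * pi)),
            class = "flock_state")
}

#' @export
print.flock_state <- function(x, ...) {
  cat("Flock state:", nrow(x$positions), "boids\n")
  invisible(x)
}

#' Random initial flock
#'
#' Positions uniform on the torus, headings uniform on `[0, 2pi)`, drawn from
#' the current RNG stream.
#'
#' @param params a [flock_params()].
#' @return A `flock_state`.
#' @export
initialise_flock <- function(params) {
  n <- params$n_b
  new_flock_state(cbind(runif(n, 0, params$e_w), runif(n, 0, params$e_h)),
                  runif(n, 0, 2 * pi))
}

#' Visible neighbours of a boid
#'
#' Indices of the other boids within toroidal distance `r_vis` (inclusive).
#'
#' @param state a `flock_state`.
#' @param i boid index.
#' @param params a [flock_params()].
#' @export
neighbour_set <- function(state, i, params) {
  d <- toroidal_distance(matrix(state$positions[i, ], nrow(state$positions),
                                2, byrow = TRUE),
                         state$positions, params$e_w, params$e_h)
  setdiff(which(d <= params$r_vis), i)
}

#' New heading of one boid (reference implementation)
#'
#' The per-boid turning rule, computed from the current state: separation
#' from a too-close nearest neighbour takes precedence; otherwise the
#' alignment turn (towards the circular mean of neighbour headings, capped at
#' `max_turn_a`) and the cohesion turn (towards the bearing of the mean
#' minimal-image displacement to the neighbours, capped at `max_turn_c`) are
#' summed.  A boid with no neighbours keeps its heading.  This R version is
#' the readable reference for the compiled kernel used by [flock_step()].
#'
#' @inheritParams neighbour_set
#' @return The new heading in `[0, 2pi)`.
#' @export
new_heading <- function(state, i, params) {
  h <- state$headings[i]
  nbrs <- neighbour_set(state, i, params)
  if (length(nbrs) == 0) return(h %% (2 * pi))
  deltas <- toroidal_delta(matrix(state$positions[i, ], length(nbrs), 2,
                                  byrow = TRUE),
                           state$positions[nbrs, , drop = FALSE],
                           params$e_w, params$e_h)
  dists <- sqrt(rowSums(deltas^2))
  j <- nbrs[which.min(dists)]
  if (min(dists) < params$min_sep) {
    turn <- params$separation_sign *
      limit_turn(angle_between(h, state$headings[j]), params$max_turn_s)
    return((h + turn) %% (2 * pi))
  }
  turn <- 0
  sc <- sum(cos(state$headings[nbrs]))
  ss <- sum(sin(state$headings[nbrs]))
  if (sqrt(sc^2 + ss^2) > 1e-12)
    turn <- turn + limit_turn(angle_between(h, atan2(ss, sc)),
                              params$max_turn_a)
  md <- colMeans(deltas)
  if (sqrt(sum(md^2)) > 1e-12)
    turn <- turn + limit_turn(angle_between(h, atan2(md[2], md[1])),
                              params$max_turn_c)
  (h + turn) %% (2 * pi)
}

#' One synchronous flock update
#'
#' All new headings are computed from the time-t state; then every boid
#' advances `step_size` along its *new* heading and positions wrap on the
#' torus.
#'
#' @param state a `flock_state`.
#' @param params a [flock_params()].
#' @return The updated `flock_state`.
#' @export
flock_step <- function(state, params) {
  res <- .flock_step_cpp(state$positions, state$headings,
                         params$e_w, params$e_h, params$step_size,
                         params$r_vis, params$min_sep,
                         params$max_turn_s, params$max_turn_a,
                         params$max_turn_c, params$separation_sign)
  new_flock_state(res$positions, res$headings)
}

# Pure-R step used to cross-check the compiled kernel in tests.
flock_step_r <- function(state, params) {
  n <- nrow(state$positions)
  hn <- vapply(seq_len(n), function(i) new_heading(state, i, params),
               numeric(1))
  pos <- state$positions +
    params$step_size * cbind(cos(hn), sin(hn))
  new_flock_state(wrap_position(pos, params$e_w, params$e_h), hn)
}

#' Simulate a flock, storing selected snapshots
#'
#' Iterates [flock_step()] for `steps` updates from `init` (or a random
#' initial flock drawn from the current RNG stream), keeping only the states
#' at `snapshot_times` (time 0 = initial state); the final state is always
#' kept.
#'
#' @param params a [flock_params()].
#' @param steps number of updates.
#' @param snapshot_times integer times in `[0, steps]` to store.
#' @param init optional initial `flock_state`.
#' @return A `flock_trajectory`: list of snapshots (named by time), `steps`
#'   and `params`.
#' @export
simulate_flock <- function(params, steps, snapshot_times = integer(0),
                           init = NULL) {
  stopifnot(steps >= 0)
  snapshot_times <- sort(unique(as.integer(c(snapshot_times, steps))))
  if (any(snapshot_times < 0 | snapshot_times > steps))
    stop("snapshot times must lie in [0, steps]")
  if (is.null(init)) init <- initialise_flock(params)
  snaps <- .flock_simulate_cpp(init$positions, init$headings,
                               as.integer(steps), snapshot_times,
                               params$e_w, params$e_h, params$step_size,
                               params$r_vis, params$min_sep,
                               params$max_turn_s, params$max_turn_a,
                               params$max_turn_c, params$separation_sign)
  snaps <- lapply(snaps, function(s) new_flock_state(s$positions, s$headings))
  names(snaps) <- as.character(snapshot_times)
  flock_trajectory(snaps, steps, params)
}

#' Construct a trajectory-snapshot container
#'
#' @param snapshots named list of `flock_state`s, names are integer times.
#' @param steps simulation length.
#' @param params the [flock_params()] that produced (or describe) it.
#' @export
flock_trajectory <- function(snapshots, steps, params) {
  structure(list(snapshots = snapshots, steps = as.integer(steps),
                 params = params),
            class = "flock_trajectory")
}

#' @export
print.flock_trajectory <- function(x, ...) {
  cat("Flock trajectory:", x$steps, "steps,", length(x$snapshots),
      "stored snapshots (t =", paste(names(x$snapshots), collapse = ", "),
      ")\n")
  invisible(x)
}

snapshot_at <- function(traj, t) {
  s <- traj$snapshots[[as.character(as.integer(t))]]
  if (is.null(s))
    stop("no snapshot stored at t = ", t, "; available: ",
         paste(names(traj$snapshots), collapse = ", "))
  s
}

#' Dump a trajectory as a long-format data frame
#'
#' Columns `t`, `boid`, `x`, `y`, `heading` — convenient for CSV export and
#' visual debugging.
#'
#' @param traj a `flock_trajectory`.
#' @export
trajectory_df <- function(traj) {
  do.call(rbind, lapply(names(traj$snapshots), function(tn) {
    s <- traj$snapshots[[tn]]
    data.frame(t = as.integer(tn), boid = seq_len(nrow(s$positions)),
               x = s$positions[, 1], y = s$positions[, 2],
               heading = s$headings)
  }))
}
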