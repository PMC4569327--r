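# Shared fixtures: tiny plug-in models and brute-force oracles.

# Toy staircase model: K = 2, M = 1, pattern floor(3 p1) + 3 floor(3 p2).
# Its reachable cell set is finite and enumerable by brute force, which makes
# it the oracle for exploration completeness.
staircase_model <- function() {
  model_plugin("staircase", k = 2, m = 1,
               fn = function(v) floor(3 * v[1]) + 3 * floor(3 * v[2]))
}

staircase_bounds <- function() bounds(c(0, 0), c(1, 1))

# All cells the staircase model can reach, by dense grid enumeration
# including the domain boundary (bounds clamping makes p = 1 attainable).
staircase_reachable_cells <- function() {
  g <- seq(0, 1, by = 0.01)
  vals <- outer(floor(3 * g), 3 * floor(3 * g), "+")
  sort(unique(as.integer(vals)))
}

# Constant model: every evaluation lands in the same cell.
constant_model <- function(value = c(0.5, 0.5)) {
  model_plugin("constant", k = 2, m = length(value),
               fn = function(v) value)
}

# Brute-force union-find largest component oracle (R implementation,
# independent of the compiled kernel).
largest_cluster_oracle <- function(positions, r_vis, e_w, e_h) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      dx <- abs(positions[i, 1] - positions[j, 1])
      dx <- min(dx, e_w - dx)
      dy <- abs(positions[i, 2] - positions[j, 2])
      dy <- min(dy, e_h - dy)
      if (sqrt(dx^2 + dy^2) <= r_vis) {
        ra <- find(i); rb <- find(j)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  max(table(vapply(seq_len(n), find, integer(1))))
}

# Torus Voronoi adjacency through deldir on the 3x3 tiling: the independent
# Delaunay oracle for the compiled triangulation.
voronoi_deldir_oracle <- function(positions, e_w, e_h) {
  n <- nrow(positions)
  off <- expand.grid(dx = c(-e_w, 0, e_w), dy = c(-e_h, 0, e_h))
  tx <- rep(positions[, 1], 9) + rep(off$dx, each = n)
  ty <- rep(positions[, 2], 9) + rep(off$dy, each = n)
  dd <- deldir::deldir(tx, ty, suppressMsge = TRUE)
  lo <- 4L * n
  i1 <- dd$delsgs$ind1; i2 <- dd$delsgs$ind2
  keep <- (i1 > lo & i1 <= lo + n) | (i2 > lo & i2 <= lo + n)
  i1 <- (i1[keep] - 1L) %% n + 1L
  i2 <- (i2[keep] - 1L) %% n + 1L
  sel <- i1 != i2
  pairs <- unique(rbind(cbind(i1[sel], i2[sel]), cbind(i2[sel], i1[sel])))
  lapply(seq_len(n), function(i)
    sort(unique(as.integer(pairs[pairs[, 1] == i, 2]))))
}

# Sequential-update boids step (deliberately wrong order semantics): the
# oracle showing that the synchronous kernel is not order-dependent.
flock_step_sequential <- function(state, params) {
  st <- state
  n <- nrow(st$positions)
  for (i in seq_len(n)) {
    h <- new_heading(st, i, params)
    st$headings[i] <- h
    st$positions[i, ] <- c(
      (st$positions[i, 1] + params$step_size * cos(h)) %% params$e_w,
      (st$positions[i, 2] + params$step_size * sin(h)) %% params$e_h)
  }
  st
}

# A full-torus lattice cohort sharing one heading: perfectly symmetric, so
# alignment and cohesion turns vanish and the motion is rigid.
lattice_cohort <- function(side = 4, e = 8, heading = 0) {
  sp <- e / side
  g <- expand.grid(x = (seq_len(side) - 0.5) * sp,
                   y = (seq_len(side) - 0.5) * sp)
  psexplore:::new_flock_state(as.matrix(g), rep(heading, side^2))
}
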