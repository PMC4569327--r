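test_that("turn limiting preserves sign and caps magnitude", {
  expect_equal(limit_turn(0.3, pi), 0.3)
  expect_equal(limit_turn(-2.0, 0.5), -0.5)
  expect_equal(limit_turn(0, 0), 0)
  expect_equal(limit_turn(c(1, -1, 0.1), 0.4), c(0.4, -0.4, 0.1))
})

test_that("heading difference is the minimal representative of its identity", {
  expect_equal(angle_between(0, pi / 2), pi / 2)
  expect_equal(angle_between(1.3, 1.3), 0)
  expect_equal(angle_between(0.1, 2 * pi - 0.1), -0.2)
  expect_equal(angle_between(0, pi), pi)  # exact opposition goes to +pi
  set.seed(1)
  h1 <- runif(200, 0, 2 * pi); h2 <- runif(200, 0, 2 * pi)
  a <- angle_between(h1, h2)
  expect_true(all(a > -pi & a <= pi))
  expect_equal((h1 + a) %% (2 * pi), h2 %% (2 * pi), tolerance = 1e-12)
})

test_that("minimal-image displacement wraps across the torus edges", {
  expect_equal(toroidal_delta(c(1, 1), c(1, 1), 32, 32), c(0, 0))
  expect_equal(toroidal_distance(c(0.1, 5), c(31.9, 5), 32, 32), 0.2)
  expect_equal(toroidal_distance(c(31.9, 5), c(0.1, 5), 32, 32), 0.2)
  set.seed(2)
  p <- cbind(runif(100, 0, 32), runif(100, 0, 32))
  q <- cbind(runif(100, 0, 32), runif(100, 0, 32))
  expect_equal(toroidal_distance(p, q, 32, 32),
               toroidal_distance(q, p, 32, 32))
  d <- toroidal_delta(p, q, 32, 32)
  expect_true(all(d[, 1] > -16 & d[, 1] <= 16))
})

test_that("neighbour sets match a brute-force scan", {
  set.seed(3)
  p <- flock_params(e_w = 10, e_h = 10, n_b = 30, r_vis = 2.5)
  st <- initialise_flock(p)
  for (i in c(1, 7, 30)) {
    brute <- which(vapply(seq_len(30), function(j) {
      j != i && toroidal_distance(st$positions[i, ], st$positions[j, ],
                                  10, 10) <= 2.5
    }, logical(1)))
    expect_identical(neighbour_set(st, i, p), brute)
  }
  p0 <- p; p0$r_vis <- 0
  expect_length(neighbour_set(st, 1, p0), 0)
  pall <- p; pall$r_vis <- 10 # beyond the torus diameter
  expect_length(neighbour_set(st, 1, pall), 29)
})

test_that("separation turns away from the crowding neighbour's heading", {
  # boid 1 at heading 0, too-close boid 2 at heading pi/2, unlimited turn:
  # away-turn lands at 3pi/2 (i.e. -pi/2)
  st <- psexplore:::new_flock_state(rbind(c(5, 5), c(5.2, 5)), c(0, pi / 2))
  p <- flock_params(e_w = 10, e_h = 10, n_b = 2, r_vis = 2, min_sep = 1,
                    max_turn_s = pi)
  expect_equal(new_heading(st, 1, p), 3 * pi / 2)
  # the literal-equation variant turns toward it instead
  p2 <- p; p2$separation_sign <- 1
  expect_equal(new_heading(st, 1, p2), pi / 2)
  # a boid with no neighbours keeps its heading
  lone <- psexplore:::new_flock_state(rbind(c(1, 1), c(8, 8)), c(0.7, 1))
  expect_equal(new_heading(lone, 1, p), 0.7)
})

test_that("aligned symmetric neighbourhoods leave the heading unchanged", {
  # four neighbours placed symmetrically around boid 1, all sharing heading
  st <- psexplore:::new_flock_state(
    rbind(c(5, 5), c(6, 5), c(4, 5), c(5, 6), c(5, 4)), rep(1.1, 5))
  p <- flock_params(e_w = 10, e_h = 10, n_b = 5, r_vis = 1.5, min_sep = 0.5,
                    max_turn_a = pi / 4, max_turn_c = pi / 4)
  expect_equal(new_heading(st, 1, p), 1.1)
})

test_that("compiled and reference steps agree on random states", {
  set.seed(4)
  for (rep in 1:5) {
    p <- flock_params(e_w = 8, e_h = 8, n_b = 15,
                      r_vis = runif(1, 0.5, 4), min_sep = runif(1, 0, 2),
                      max_turn_s = runif(1, 0, pi),
                      max_turn_a = runif(1, 0, pi),
                      max_turn_c = runif(1, 0, pi))
    st <- initialise_flock(p)
    s_cpp <- flock_step(st, p)
    s_r <- psexplore:::flock_step_r(st, p)
    expect_equal(s_cpp$positions, s_r$positions, tolerance = 1e-12)
    expect_equal(s_cpp$headings, s_r$headings, tolerance = 1e-12)
  }
})

test_that("updates are simultaneous, not sequential", {
  # three boids in a row, close enough that updating in index order would
  # feed boid 2 the already-updated state of boid 1
  st <- psexplore:::new_flock_state(
    rbind(c(4.0, 5), c(4.5, 5), c(5.0, 5)), c(0, pi / 2, pi))
  p <- flock_params(e_w = 10, e_h = 10, n_b = 3, r_vis = 0.8, min_sep = 1,
                    max_turn_s = pi / 2)
  sync <- flock_step(st, p)
  seq_ <- flock_step_sequential(st, p)
  expect_equal(sync$headings, psexplore:::flock_step_r(st, p)$headings)
  expect_false(isTRUE(all.equal(sync$headings, seq_$headings)))
})

test_that("permuting boid indices permutes the output identically", {
  set.seed(5)
  p <- flock_params(e_w = 8, e_h = 8, n_b = 12, r_vis = 3, min_sep = 1)
  st <- initialise_flock(p)
  out <- flock_step(st, p)
  perm <- sample(12)
  stp <- psexplore:::new_flock_state(st$positions[perm, ],
                                     st$headings[perm])
  outp <- flock_step(stp, p)
  expect_equal(outp$positions, out$positions[perm, ], tolerance = 1e-12)
  expect_equal(outp$headings, out$headings[perm], tolerance = 1e-12)
})

test_that("every boid advances exactly step_size and stays on the torus", {
  set.seed(6)
  p <- flock_params(e_w = 8, e_h = 8, n_b = 20, r_vis = 2, min_sep = 0.5,
                    step_size = 0.3)
  st <- initialise_flock(p)
  for (i in 1:20) {
    nxt <- flock_step(st, p)
    moved <- toroidal_distance(st$positions, nxt$positions, 8, 8)
    expect_equal(moved, rep(0.3, 20), tolerance = 1e-9)
    expect_true(all(nxt$positions >= 0 & nxt$positions[, 1] < 8 &
                    nxt$positions[, 2] < 8))
    expect_true(all(nxt$headings >= 0 & nxt$headings < 2 * pi))
    st <- nxt
  }
})

test_that("trajectories are translation-equivariant on the torus", {
  set.seed(7)
  p <- flock_params(e_w = 8, e_h = 8, n_b = 10, r_vis = 2, min_sep = 0.5)
  st <- initialise_flock(p)
  shift <- c(2.3, 5.1)
  st2 <- psexplore:::new_flock_state(
    psexplore:::wrap_position(sweep(st$positions, 2, shift, "+"), 8, 8),
    st$headings)
  t1 <- simulate_flock(p, 50, init = st)
  t2 <- simulate_flock(p, 50, init = st2)
  f1 <- t1$snapshots[["50"]]; f2 <- t2$snapshots[["50"]]
  delta <- toroidal_delta(f1$positions, f2$positions, 8, 8)
  expect_equal(delta[, 1], rep(2.3, 10), tolerance = 1e-8)
  expect_equal(delta[, 2], rep(5.1 - 8, 10), tolerance = 1e-8)
  expect_equal(f1$headings, f2$headings, tolerance = 1e-8)
})

test_that("random initial flocks are uniform and reproducible", {
  p <- flock_params(e_w = 32, e_h = 32, n_b = 100)
  set.seed(8)
  a <- initialise_flock(p)
  set.seed(8)
  b <- initialise_flock(p)
  expect_identical(a, b)
  set.seed(9)
  xs <- ys <- hs <- numeric(0)
  for (i in 1:100) {
    st <- initialise_flock(p)
    xs <- c(xs, st$positions[, 1]); ys <- c(ys, st$positions[, 2])
    hs <- c(hs, st$headings)
  }
  expect_gt(ks.test(xs, "punif", 0, 32)$p.value, 0.01)
  expect_gt(ks.test(ys, "punif", 0, 32)$p.value, 0.01)
  expect_gt(ks.test(hs, "punif", 0, 2 * pi)$p.value, 0.01)
})

test_that("snapshot storage keeps requested times plus the final state", {
  p <- flock_params(e_w = 8, e_h = 8, n_b = 5, r_vis = 0)
  set.seed(10)
  tr <- simulate_flock(p, 30, snapshot_times = c(0, 10, 20))
  expect_identical(names(tr$snapshots), c("0", "10", "20", "30"))
  expect_error(simulate_flock(p, 30, snapshot_times = 31), "\\[0, steps\\]")
  # steps = 0: the initial state only
  set.seed(10)
  tr0 <- simulate_flock(p, 0)
  expect_identical(names(tr0$snapshots), "0")
  # an isolated boid keeps its heading across all snapshots
  h0 <- tr$snapshots[["0"]]$headings
  for (s in tr$snapshots) expect_equal(s$headings, h0)
})

test_that("a symmetric same-heading lattice cohort moves rigidly", {
  st <- lattice_cohort(side = 4, e = 8, heading = pi / 7)
  p <- flock_params(e_w = 8, e_h = 8, n_b = 16, step_size = 0.05,
                    r_vis = 2.9, min_sep = 1)
  d0 <- psexplore:::.torus_dist_cpp(st$positions, 8, 8)
  tr <- simulate_flock(p, 100, init = st)
  d1 <- psexplore:::.torus_dist_cpp(tr$snapshots[["100"]]$positions, 8, 8)
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_equal(tr$snapshots[["100"]]$headings, rep(pi / 7, 16),
               tolerance = 1e-9)
})
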