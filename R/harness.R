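#' Discovery curve of a trace
#'
#' Cumulative count of first-visited pattern-space cells as a function of
#' the evaluation index — the exploration-progress metric.  Recomputed from
#' the trace, so any report built on it is a pure function of the logs.
#'
#' @param trace a trace data.frame ([pse_trace()]) or a `pse_state`.
#' @return data.frame with `eval_index` and `volume` (non-decreasing).
#' @export
discovery_curve <- function(trace) {
  if (inherits(trace, "pse_state")) trace <- pse_trace(trace)
  if (nrow(trace) == 0)
    return(data.frame(eval_index = integer(0), volume = integer(0)))
  ccols <- grep("^c[0-9]+$", names(trace), value = TRUE)
  keys <- do.call(paste, c(trace[ccols], sep = ","))
  data.frame(eval_index = trace$eval_index,
             volume = cumsum(!duplicated(keys)))
}

#' @export
plot.pse_state <- function(x, ...) {
  dc <- discovery_curve(x)
  plot(dc$eval_index, dc$volume, type = "s",
       xlab = "evaluations", ylab = "cells discovered", ...)
  invisible(x)
}

#' Thresholds for the qualitative collective-motion phases
#'
#' The five landmark behaviours of the flocking literature — gas, moving
#' solid, stationary solid, moving liquid, stationary liquid — are mapped to
#' regions of the (cluster, delta, velocity) pattern space.  A cohesive
#' flock holds at least `ceiling(cohesive_fraction * N_b)` boids (the
#' 125-of-128 convention); gas means no cluster above `gas_max_cluster`.
#' Relative diffusion near 0 is solid, near 1 liquid; velocity near 0 is
#' stationary, near the 0.5 maximum is moving.  The gaps between thresholds
#' are deliberate dead zones: descriptors falling there classify as
#' "unclassified" rather than being forced into a phase.
#'
#' @param cohesive_fraction fraction of `n_b` required for a cohesive flock.
#' @param gas_max_cluster largest cluster size still counting as gas.
#' @param solid_delta_max,liquid_delta_min relative-diffusion cutoffs.
#' @param stationary_v_max,moving_v_min velocity cutoffs.
#' @export
phase_thresholds <- function(cohesive_fraction = 125 / 128,
                             gas_max_cluster = 2,
                             solid_delta_max = 0.25,
                             liquid_delta_min = 0.75,
                             stationary_v_max = 0.1,
                             moving_v_min = 0.3) {
  stopifnot(solid_delta_max < liquid_delta_min,
            stationary_v_max < moving_v_min,
            cohesive_fraction > 0, cohesive_fraction <= 1)
  structure(list(cohesive_fraction = cohesive_fraction,
                 gas_max_cluster = gas_max_cluster,
                 solid_delta_max = solid_delta_max,
                 liquid_delta_min = liquid_delta_min,
                 stationary_v_max = stationary_v_max,
                 moving_v_min = moving_v_min),
            class = "phase_thresholds")
}

#' Classify a pattern descriptor into a collective-motion phase
#'
#' @param pattern numeric vector `(cluster, delta, velocity)`.
#' @param th a [phase_thresholds()].
#' @param n_b total number of boids.
#' @return One of "gas", "moving solid", "stationary solid",
#'   "moving liquid", "stationary liquid", "unclassified".
#' @export
classify_phase <- function(pattern, th = phase_thresholds(), n_b = 128) {
  cl <- pattern[[1]]; delta <- pattern[[2]]; v <- pattern[[3]]
  if (cl <= th$gas_max_cluster) return("gas")
  if (cl < ceiling(th$cohesive_fraction * n_b)) return("unclassified")
  solid <- delta <= th$solid_delta_max
  liquid <- delta >= th$liquid_delta_min
  moving <- v >= th$moving_v_min
  stationary <- v <= th$stationary_v_max
  if (solid && moving) "moving solid"
  else if (solid && stationary) "stationary solid"
  else if (liquid && moving) "moving liquid"
  else if (liquid && stationary) "stationary liquid"
  else "unclassified"
}

# ---- analytic trajectory fixtures -----------------------------------------

# Compact hexagonal-ish block of n offsets with spacing `sp`, centred on 0.
cluster_offsets <- function(n, sp) {
  side <- ceiling(sqrt(n))
  g <- expand.grid(ix = seq_len(side), iy = seq_len(side))[seq_len(n), ]
  off <- cbind((g$ix - (side + 1) / 2) * sp, (g$iy - (side + 1) / 2) * sp)
  off
}

#' Analytic trajectory fixtures
#'
#' Synthetic snapshot sets with exactly known geometry, used to pin the
#' order parameters to closed-form values:
#' * `make_rigid_trajectory()` — a compact block of boids sharing one
#'   heading and translating rigidly across the torus (all pairwise
#'   distances constant, so relative diffusion is exactly 0);
#' * `make_scaling_trajectory()` — the block's offsets from its centre are
#'   scaled by `factor^(t / T_d)`, so between any t and t + T_d every
#'   pairwise distance scales by `factor` and the relative diffusion is
#'   exactly `1 - 1/factor^2`;
#' * `make_straight_mover()` — a single boid advancing `step_size` per step
#'   on a fixed heading (mean velocity exactly 0.5 at the default geometry).
#'
#' Snapshots are generated at exactly the times the measures request.
#'
#' @param params a [flock_params()].
#' @param steps simulation length represented by the fixture.
#' @param heading common heading of the fixture boids.
#' @param spacing distance between adjacent block members.
#' @param origin position of the block centre (or the mover) at t = 0.
#' @return A `flock_trajectory`.
#' @export
make_rigid_trajectory <- function(params = flock_params(), steps = 1000,
                                  heading = 0, spacing = 1,
                                  origin = c(params$e_w / 2,
                                             params$e_h / 2)) {
  cfg <- measure_config(params, steps)
  times <- measure_snapshot_times(cfg)
  off <- cluster_offsets(params$n_b, spacing)
  u <- c(cos(heading), sin(heading))
  snaps <- lapply(times, function(t) {
    centre <- origin + t * params$step_size * u
    pos <- sweep(off, 2, centre, "+")
    new_flock_state(wrap_position(pos, params$e_w, params$e_h),
                    rep(heading, params$n_b))
  })
  names(snaps) <- as.character(times)
  flock_trajectory(snaps, steps, params)
}

#' @rdname make_rigid_trajectory
#' @param factor pairwise-distance scaling factor per `T_d` window.
#' @export
make_scaling_trajectory <- function(params = flock_params(), steps = 1000,
                                    factor = 2, spacing = 1,
                                    origin = c(params$e_w / 2,
                                               params$e_h / 2)) {
  cfg <- measure_config(params, steps)
  times <- measure_snapshot_times(cfg)
  off <- cluster_offsets(params$n_b, spacing)
  # keep the block inside half the torus at the largest scale reached
  max_scale <- max(factor^(times / cfg$t_d))
  max_ext <- max(abs(off)) * max_scale
  if (max_ext >= min(params$e_w, params$e_h) / 4)
    off <- off * (min(params$e_w, params$e_h) / 4) / (max_ext * 1.01)
  snaps <- lapply(times, function(t) {
    pos <- sweep(off * factor^(t / cfg$t_d), 2, origin, "+")
    new_flock_state(wrap_position(pos, params$e_w, params$e_h),
                    rep(0, params$n_b))
  })
  names(snaps) <- as.character(times)
  flock_trajectory(snaps, steps, params)
}

#' @rdname make_rigid_trajectory
#' @export
make_straight_mover <- function(params = flock_params(n_b = 1),
                                steps = 1000, heading = 0,
                                origin = c(params$e_w / 2, params$e_h / 2)) {
  params$n_b <- 1L
  cfg <- measure_config(params, steps)
  times <- measure_snapshot_times(cfg)
  u <- c(cos(heading), sin(heading))
  snaps <- lapply(times, function(t) {
    pos <- matrix(origin + t * params$step_size * u, 1, 2)
    new_flock_state(wrap_position(pos, params$e_w, params$e_h), heading)
  })
  names(snaps) <- as.character(times)
  flock_trajectory(snaps, steps, params)
}

# ---- benchmark ------------------------------------------------------------

#' Scaled-down benchmark configuration
#'
#' The desk-scale study conditions for comparing the exploration engine with
#' the a-priori designs on the flocking model: a 16 x 16 torus with 32
#' boids, 600-step simulations (so T_d = 80 and T_v = 160 fit the run),
#' 5 replications per evaluation, a 3000-evaluation budget per method, the
#' standard pattern-space discretisation, and 3 master seeds for the
#' stochastic methods.
#'
#' @param e environment size (width = height).
#' @param n_b number of boids.
#' @param steps simulation length.
#' @param replications replicates per evaluation.
#' @param budget evaluations per method.
#' @param seeds integer vector of master seeds for PSE and LHS.
#' @param mu initial population size for PSE (5% of the budget, mirroring
#'   the full-scale configuration).
#' @param reeval_prob re-evaluation probability for PSE.
#' @export
benchmark_config <- function(e = 16, n_b = 32, steps = 600,
                             replications = 5, budget = 3000,
                             seeds = c(1L, 2L, 3L),
                             mu = max(2L, as.integer(0.05 * budget)),
                             reeval_prob = 0.01) {
  structure(list(e = e, n_b = as.integer(n_b), steps = as.integer(steps),
                 replications = as.integer(replications),
                 budget = as.integer(budget), seeds = as.integer(seeds),
                 mu = as.integer(mu), reeval_prob = reeval_prob),
            class = "benchmark_config")
}

cell_set <- function(state) {
  ls(state$hitmap$counts, all.names = TRUE)
}

#' Benchmark the exploration engine against a-priori designs
#'
#' Runs PSE (one run per seed), LHS (one design per seed), the Sobol
#' sequence and the regular grid on the same flocking model, pattern-space
#' discretisation and evaluation budget (the grid uses the largest
#' `levels^5` not exceeding the budget), then reports per-method discovery
#' curves, discovered cell sets, final volumes and the pairwise
#' intersections of each baseline's cell set with the engine's.
#'
#' @param bench a [benchmark_config()].
#' @param progress print per-run progress lines.
#' @return A `benchmark_report` list with elements `curves`, `cells`,
#'   `volumes`, `intersections`, `traces` and the configuration.
#' @export
run_benchmark <- function(bench = benchmark_config(), progress = FALSE) {
  base <- flock_params(e_w = bench$e, e_h = bench$e, n_b = bench$n_b)
  model <- flocking_model(base, steps = bench$steps)
  d <- model$discretisation
  b <- model$bounds

  states <- list()
  for (s in bench$seeds) {
    cfg <- pse_config(b, d, mu = bench$mu,
                      max_evaluations = bench$budget,
                      replications = bench$replications,
                      reeval_prob = bench$reeval_prob, master_seed = s)
    if (progress) message("PSE seed ", s)
    states[[paste0("pse_seed", s)]] <- run_pse(cfg, model)
  }
  for (s in bench$seeds) {
    if (progress) message("LHS seed ", s)
    des <- with_rng_state(rng_master(s)$engine, function()
      latin_hypercube(bench$budget, b))$value
    states[[paste0("lhs_seed", s)]] <-
      evaluate_design(des, model, bench$replications, d, master_seed = s)
  }
  if (progress) message("Sobol")
  states[["sobol"]] <- evaluate_design(sobol_sequence(bench$budget, b),
                                       model, bench$replications, d,
                                       master_seed = bench$seeds[1])
  glevels <- max(2L, as.integer(floor(bench$budget^(1 / b$k))))
  if (progress) message("grid (", glevels, "^", b$k, " points)")
  states[["grid"]] <- evaluate_design(regular_grid(glevels, b), model,
                                      bench$replications, d,
                                      master_seed = bench$seeds[1])

  cells <- lapply(states, cell_set)
  volumes <- vapply(states, function(st) volume_discovered(st$hitmap),
                    integer(1))
  pse_names <- grep("^pse_", names(states), value = TRUE)
  pse_union <- unique(unlist(cells[pse_names]))
  others <- setdiff(names(states), pse_names)
  intersections <- lapply(others, function(nm)
    list(shared = length(intersect(cells[[nm]], pse_union)),
         only_method = length(setdiff(cells[[nm]], pse_union)),
         only_pse = length(setdiff(pse_union, cells[[nm]]))))
  names(intersections) <- others

  method_of <- sub("_seed[0-9]+$", "", names(volumes))
  summary_df <- do.call(rbind, lapply(unique(method_of), function(m) {
    v <- volumes[method_of == m]
    data.frame(method = m, runs = length(v), mean_volume = mean(v),
               sd_volume = if (length(v) > 1) sd(v) else NA_real_)
  }))
  structure(list(config = bench,
                 curves = lapply(states, discovery_curve),
                 cells = cells,
                 volumes = volumes,
                 summary = summary_df,
                 intersections = intersections,
                 traces = lapply(states, pse_trace)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (budget", x$config$budget, "evaluations,",
      x$config$replications, "replications)\n")
  cat("Final volumes discovered:\n")
  for (nm in names(x$volumes))
    cat(sprintf("  %-12s %d\n", nm, x$volumes[[nm]]))
  invisible(x)
}

#' Phases discovered in a trace
#'
#' Classifies every phenotype of a trace and tabulates the phases found.
#'
#' @param trace a trace data.frame ([pse_trace()]) or `pse_state`.
#' @param th a [phase_thresholds()].
#' @param n_b number of boids of the underlying model.
#' @export
phases_discovered <- function(trace, th = phase_thresholds(), n_b = 128) {
  if (inherits(trace, "pse_state")) trace <- pse_trace(trace)
  labels <- vapply(seq_len(nrow(trace)), function(i)
    classify_phase(c(trace$p1[i], trace$p2[i], trace$p3[i]), th, n_b),
    character(1))
  table(factor(labels, levels = c("gas", "moving solid", "stationary solid",
                                  "moving liquid", "stationary liquid",
                                  "unclassified")))
}
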