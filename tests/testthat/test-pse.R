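stair <- staircase_model()
sb <- staircase_bounds()
sd1 <- discretisation(1)

test_that("evaluation clamps each replicate before taking the median", {
  d <- discretisation(c(1, 0.2), lower_clamp = c(NA, -1))
  # model emits a different second component per replicate: -3, -2, 0
  vals <- c(-3, -2, 0)
  i <- 0
  m <- model_plugin("seq", 1, 2, function(v) {
    i <<- i + 1
    c(1, vals[i])
  })
  st <- psexplore:::rng_master(1)
  ev <- evaluate_individual(genome(0.5), m, 3, d, st$eval_base)
  # clamped replicates {-1, -1, 0} -> median -1
  expect_equal(ev$raw[, 2], c(-1, -1, 0))
  expect_equal(ev$individual$phenotype[2], -1)

  # constant model: phenotype equals the constant
  cm <- constant_model(c(0.4, 0.6))
  ev2 <- evaluate_individual(genome(c(0, 0)), cm, 5,
                             discretisation(c(0.2, 0.2)), st$eval_base)
  expect_equal(unname(ev2$individual$phenotype), c(0.4, 0.6))

  # odd replicate count: plain middle order statistic
  j <- 0
  m2 <- model_plugin("seq2", 1, 1, function(v) { j <<- j + 1
    c(0.1, 0.3, 0.2)[j] })
  ev3 <- evaluate_individual(genome(0.5), m2, 3, discretisation(0.1),
                             st$eval_base)
  expect_equal(unname(ev3$individual$phenotype), 0.2)

  # even replicate count: mean of the two middle values
  kk <- 0
  m3 <- model_plugin("seq3", 1, 1, function(v) { kk <<- kk + 1
    c(0.1, 0.4, 0.2, 0.3)[kk] })
  ev4 <- evaluate_individual(genome(0.5), m3, 4, discretisation(0.1),
                             st$eval_base)
  expect_equal(unname(ev4$individual$phenotype), 0.25)
})

test_that("a failing model surfaces the genome context", {
  bad <- model_plugin("bad", 1, 1, function(v) stop("boom"))
  st <- psexplore:::rng_master(1)
  expect_error(
    evaluate_individual(genome(0.123456), bad, 1, sd1, st$eval_base),
    "0.123456")
})

test_that("elitism keeps exactly one individual per occupied cell", {
  ind <- function(cell, tag) list(genome = genome(c(tag, 0)),
                                  phenotype = cell,
                                  cell = as.integer(cell))
  a <- ind(0, 1); b <- ind(0, 2); c3 <- ind(1, 3)
  set.seed(1)
  kept <- elitism_filter(list(a, b, c3))
  expect_length(kept, 2)
  cells <- vapply(kept, function(x) x$cell, integer(1))
  expect_setequal(cells, c(0L, 1L))
  # all-distinct input is unchanged; empty input stays empty
  expect_length(elitism_filter(list(a, c3)), 2)
  expect_length(elitism_filter(list()), 0)
  # over many draws both same-cell candidates get kept sometimes
  set.seed(2)
  tags <- replicate(400, {
    k <- elitism_filter(list(a, b))
    k[[1]]$genome$values[1]
  })
  expect_gt(sum(tags == 1), 50)
  expect_gt(sum(tags == 2), 50)
})

test_that("initialisation evaluates mu uniform genomes and filters them", {
  cfg <- pse_config(sb, sd1, mu = 1, max_evaluations = 1, master_seed = 4)
  st <- initialise_population(cfg, stair)
  expect_length(st$population, 1)
  expect_identical(hit_total(st$hitmap), 1L)

  # all genomes in one cell collapse to a single member
  cm <- constant_model(c(0.5, 0.5))
  cfg2 <- pse_config(sb, discretisation(c(1, 1)), mu = 20,
                     max_evaluations = 20, master_seed = 4)
  st2 <- initialise_population(cfg2, cm)
  expect_length(st2$population, 1)
  expect_identical(hit_total(st2$hitmap), 20L)
  expect_identical(volume_discovered(st2$hitmap), 1L)
})

test_that("each step consumes one evaluation and conserves hit counts", {
  cfg <- pse_config(sb, sd1, mu = 10, max_evaluations = 100, master_seed = 9)
  st <- initialise_population(cfg, stair)
  for (i in 1:30) {
    pse_step(st, cfg, stair)
    expect_identical(st$eval_count, 10L + i)
    expect_identical(hit_total(st$hitmap), st$eval_count)
    cells <- vapply(st$population, function(x) cell_key <- paste(x$cell,
                    collapse = ","), character(1))
    expect_false(anyDuplicated(cells) > 0)
    # every member's cell is present in the archive
    for (m in st$population) expect_gt(hit_count(st$hitmap, m$cell), 0L)
  }
})

test_that("forced re-evaluation reruns existing genomes unchanged", {
  cfg <- pse_config(sb, sd1, mu = 8, max_evaluations = 40,
                    reeval_prob = 1, master_seed = 2)
  st <- initialise_population(cfg, stair)
  pop_values <- lapply(st$population, function(m) m$genome$values)
  pse_step(st, cfg, stair)
  tr <- pse_trace(st)
  newg <- c(tr$g1[nrow(tr)], tr$g2[nrow(tr)])
  expect_true(any(vapply(pop_values, function(v) isTRUE(all.equal(v, newg)),
                         logical(1))))
})

test_that("runs are bit-reproducible from the master seed", {
  cfg <- pse_config(sb, sd1, mu = 15, max_evaluations = 150,
                    replications = 2, master_seed = 123)
  t1 <- pse_trace(run_pse(cfg, stair))
  t2 <- pse_trace(run_pse(cfg, stair))
  expect_identical(t1, t2)
  # budget mu: the run is the initial population only
  cfg0 <- pse_config(sb, sd1, mu = 12, max_evaluations = 12, master_seed = 5)
  st0 <- run_pse(cfg0, stair)
  expect_identical(st0$eval_count, 12L)
})

test_that("every trace genome lies inside the bounds and volume is monotone", {
  cfg <- pse_config(sb, sd1, mu = 20, max_evaluations = 300, master_seed = 31)
  tr <- pse_trace(run_pse(cfg, stair))
  expect_true(all(tr$g1 >= 0 & tr$g1 <= 1 & tr$g2 >= 0 & tr$g2 <= 1))
  expect_true(all(diff(tr$volume) >= 0))
  expect_identical(tr$volume[nrow(tr)],
                   length(unique(paste(tr$c1))))
})

test_that("the exploration discovers every enumerable staircase cell", {
  reachable <- staircase_reachable_cells()
  for (seed in 1:3) {
    cfg <- pse_config(sb, sd1, mu = 20, max_evaluations = 2000,
                      master_seed = seed)
    st <- run_pse(cfg, stair)
    found <- unname(sort(vapply(ls(st$hitmap$counts), as.integer, integer(1))))
    expect_identical(found, reachable)
  }
})

test_that("the generational pool variant spends the same budget", {
  cfg <- pse_config(sb, sd1, mu = 10, max_evaluations = 100,
                    lambda = 8, master_seed = 77)
  st <- run_pse(cfg, stair)
  expect_identical(st$eval_count, 100L)
  expect_identical(hit_total(st$hitmap), 100L)
  cells <- vapply(st$population, function(x) paste(x$cell, collapse = ","),
                  character(1))
  expect_false(anyDuplicated(cells) > 0)
})

test_that("island runs conserve hits and merge one-per-cell", {
  cfg <- pse_config(sb, sd1, mu = 20, max_evaluations = 220,
                    n_islands = 2, evals_per_island = 50, island_mu = 8,
                    master_seed = 13)
  st <- run_islands(cfg, stair)
  expect_identical(st$eval_count, 220L)
  expect_identical(hit_total(st$hitmap), 220L)
  cells <- vapply(st$population, function(x) paste(x$cell, collapse = ","),
                  character(1))
  expect_false(anyDuplicated(cells) > 0)
})

test_that("a single whole-population island reproduces the sequential volume", {
  cfg_seq <- pse_config(sb, sd1, mu = 15, max_evaluations = 200,
                        master_seed = 21)
  cfg_isl <- pse_config(sb, sd1, mu = 15, max_evaluations = 200,
                        n_islands = 1, evals_per_island = 185,
                        master_seed = 21)
  v_seq <- volume_discovered(run_pse(cfg_seq, stair)$hitmap)
  v_isl <- volume_discovered(run_islands(cfg_isl, stair)$hitmap)
  expect_identical(v_isl, v_seq)
})
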