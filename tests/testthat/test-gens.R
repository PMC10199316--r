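# GENS: chromosome constraints, operators, fitness, evolution.

test_that("tiny initial populations cover the whole admissible space", {
  set.seed(1)
  draws <- replicate(1000, random_chromosome(1L, 1L))
  expect_setequal(unique(draws), c(0L, 1L))

  # n = m = 3: every draw is inside the exhaustively enumerated set
  grid <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  admissible_set <- grid[apply(grid, 1L, check_admissible, m = 3L), ,
                         drop = FALSE]
  expect_equal(nrow(admissible_set), 20L) # monotone partial injections of 3->3
  keys <- apply(admissible_set, 1L, paste, collapse = ",")
  seen <- character(0)
  for (q in 1:1000) {
    v <- random_chromosome(3L, 3L)
    expect_true(check_admissible(v, 3L))
    seen <- union(seen, paste(v, collapse = ","))
  }
  expect_true(all(seen %in% keys))
  expect_gt(length(seen), 15L) # and most of the space is actually visited
})

test_that("init_population yields admissible rows in both modes", {
  set.seed(2)
  pop <- init_population(6L, 8L, 50L)
  expect_equal(dim(pop), c(50L, 6L))
  expect_true(all(apply(pop, 1L, check_admissible, m = 8L)))
  corr <- c(2L, 3L, NA, 5L, 6L, 7L)
  popd <- init_population(6L, 8L, 50L, corr)
  expect_true(all(apply(popd, 1L, check_admissible, m = 8L, corr = corr)))
})

test_that("fitness follows the three-criterion formula", {
  s <- make_structure(6, "helix", seed = 3)
  cfg <- heuristic_config()
  full <- 1:6
  f <- fitness(full, s, s, cfg)
  expect_equal(f$score, 6, tolerance = 1e-9) # rmsd 0, no bad pairs
  expect_equal(f$n_aligned, 6L)
  expect_equal(fitness(rep(0L, 6), s, s, cfg)$score, 0)

  # equal length, lower actual RMSD scores higher
  m <- perturb(s, noise_sigma = 0.3, seed = 4)
  v1 <- c(1:4, 0L, 0L)
  v2 <- c(1:3, 0L, 0L, 4L) # misassigned tail: higher rmsd
  f1 <- fitness(v1, s, m, cfg)
  f2 <- fitness(v2, s, m, cfg)
  expect_lt(f1$rmsd, f2$rmsd)
  expect_gt(f1$score, f2$score)

  # score reproduces the formula exactly
  fit <- alignment_rmsd(s, m, cbind(which(v2 > 0), v2[v2 > 0]))
  nbad <- sum(fit$pair_dist > cfg$bad_pair_cutoff)
  expect_equal(f2$score,
               4 - cfg$w_r * fit$rmsd - cfg$w_b * nbad -
                 cfg$w_p * max(0, fit$rmsd - cfg$U) * 4,
               tolerance = 1e-9)
  expect_error(fitness(c(3L, 2L, 0L, 0L, 0L, 0L), s, s, cfg), "inadmissible")
})

test_that("crossover of identical parents is the identity", {
  set.seed(5)
  for (q in 1:100) {
    v <- random_chromosome(8L, 10L)
    expect_identical(crossover(v, v), v)
  }
})

test_that("crossover fills from both parents and repairs duplicates", {
  set.seed(6)
  # disjoint supports merge cleanly whatever the cut points
  vi <- c(1L, 2L, 0L, 0L)
  vj <- c(0L, 0L, 3L, 4L)
  kids <- replicate(200, crossover(vi, vj))
  expect_true(all(apply(kids, 2L, check_admissible, m = 4L)))
  keys <- apply(kids, 2L, paste, collapse = ",")
  expect_true("1,2,3,4" %in% keys) # cuts covering 1..2 give the full merge

  # engineered duplicate: with parents [0,9,0] and [9,0,0], the only cut
  # producing a duplicate is (2,3) (probability 1/3), and the child [9,0,0]
  # can then arise only when the random repair keeps the first copy
  # (probability 1/2).  Expected frequency: exactly 1/6.
  a <- c(0L, 9L, 0L)
  b <- c(9L, 0L, 0L)
  hits <- 0L
  n_trials <- 3000L
  for (q in seq_len(n_trials)) {
    child <- crossover(a, b)
    expect_true(check_admissible(child, 9L))
    if (identical(child, c(9L, 0L, 0L))) hits <- hits + 1L
  }
  p0 <- 1 / 6
  expect_lt(abs(hits / n_trials - p0),
            3 * sqrt(p0 * (1 - p0) / n_trials))
})

test_that("mutation point counts follow the 65/15/10/10 distribution", {
  set.seed(7)
  v <- random_chromosome(10L, 12L)
  counts <- integer(4)
  for (q in 1:10000) {
    k <- attr(mutate(v, 12L), "points")
    counts[k] <- counts[k] + 1L
  }
  probs <- c(0.65, 0.15, 0.10, 0.10)
  for (k in 1:4) {
    sd_k <- sqrt(10000 * probs[k] * (1 - probs[k]))
    expect_lt(abs(counts[k] - 10000 * probs[k]), 3 * sd_k)
  }
})

test_that("mutation preserves admissibility over thousands of cases", {
  set.seed(8)
  corr <- c(1L, 2L, NA, 4L, 5L, 6L, 7L, NA)
  for (q in 1:2500) {
    v <- random_chromosome(8L, 9L)
    w <- mutate(v, 9L)
    expect_true(check_admissible(w, 9L))
    vd <- random_chromosome(8L, 9L, corr)
    wd <- mutate(vd, 9L, corr)
    expect_true(check_admissible(wd, 9L, corr))
  }
  # unassign on a single-assignment chromosome can reach the empty chromosome
  seen_empty <- FALSE
  for (q in 1:300) {
    w <- mutate(c(0L, 3L, 0L), 5L)
    if (all(w == 0L)) seen_empty <- TRUE
  }
  expect_true(seen_empty)
})

test_that("elitism keeps the best fitness non-decreasing", {
  s <- make_structure(12, "helix", seed = 9)
  m <- perturb(s, rigid = list(axis = c(0, 0, 1), angle = 0.4,
                               translation = c(1, 1, 1)),
               noise_sigma = 0.2, seed = 10)
  cfg <- heuristic_config(c = 40L)
  set.seed(11)
  pop <- init_population(12L, 12L, 40L)
  fit <- flexalign:::fitness_raw(pop, s, m, cfg)
  best <- max(fit$score)
  for (g in 1:30) {
    pop <- flexalign:::cpp_generation(pop, fit$score, 6L, 12L, integer(0),
                                      cfg$p_mut, cfg$p_cross,
                                      cfg$point_mut_probs)
    fit <- flexalign:::fitness_raw(pop, s, m, cfg)
    expect_gte(max(fit$score), best - 1e-9)
    best <- max(max(fit$score), best)
    expect_true(all(apply(pop, 1L, check_admissible, m = 12L)))
  }
})

test_that("gens_align self-alignment converges in both modes", {
  s <- make_structure(20, "helix", seed = 12)
  for (mode in c("seq_dep", "seq_indep")) {
    a <- gens_align(s, s, heuristic_config(mode = mode, seed = 5, cl = 60,
                                           cg = 300))
    expect_equal(a$n_pairs, 20L)
    expect_lt(a$rmsd, 1e-9)
    expect_equal(attr(a, "diagnostics")$stop_reason, "coverage")
  }
})

test_that("evolve reports disjoint alignments for two-transform fixtures", {
  fx <- two_fragment_fixture(seed = 7)
  cfg <- heuristic_config(mode = "seq_dep", U = 3.0, seed = 2, cg = 200,
                          cl = 60)
  sols <- evolve(fx$target, fx$model, cfg)
  expect_gte(length(sols), 2L)
  for (a in sols) expect_lte(a$rmsd, 3.0)
  keys <- lapply(sols, function(a) paste(a$pairs[, 1L], a$pairs[, 2L]))
  expect_true(length(intersect(keys[[1L]], keys[[2L]])) == 0L)
  # the two fragments end up covered by different solutions
  expect_gte(sols[[1L]]$n_pairs, 15L)
  expect_gte(sols[[2L]]$n_pairs, 15L)
})

test_that("gens_align archives are deterministic for a fixed seed", {
  fx <- two_fragment_fixture(seed = 3)
  cfg <- heuristic_config(mode = "seq_dep", U = 3.0, seed = 4, cg = 120,
                          cl = 60)
  s1 <- evolve(fx$target, fx$model, cfg)
  s2 <- evolve(fx$target, fx$model, cfg)
  expect_equal(length(s1), length(s2))
  for (k in seq_along(s1)) expect_identical(s1[[k]]$pairs, s2[[k]]$pairs)
})
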