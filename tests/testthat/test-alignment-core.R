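# Configuration, preference order, candidate pairs, oracle, stop controller.

fake_ali <- function(n_pairs, rmsd, created) {
  structure(list(n_pairs = as.integer(n_pairs), rmsd = rmsd,
                 created = created), class = "rna_alignment")
}

test_that("configuration invariants are enforced", {
  cfg <- heuristic_config()
  expect_equal(cfg$U, 3.5)
  expect_equal(cfg$U2, 0.65)
  expect_equal(cfg$U3, 1.0)
  expect_equal(cfg$c, 200L)
  expect_equal(cfg$cl, 300)
  expect_equal(cfg$cg, 300L)
  expect_equal(cfg$p_mut + cfg$p_cross + cfg$p_seed, 1)
  expect_equal(sum(cfg$point_mut_probs), 1)
  expect_error(heuristic_config(U = 25), "0, 20")
  expect_error(heuristic_config(U = 0), "0, 20")
  expect_error(heuristic_config(U2 = 1.2, U3 = 1.0), "U2 < U3")
  expect_error(heuristic_config(p_mut = 0.9), "sum to 1")
  expect_error(heuristic_config(point_mut_probs = c(1, 0, 0, 0.5)), "summing to 1")
})

test_that("configuration files overlay defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("U: 2.5", "c: 50", "mode: seq_dep", "threads: 2"), path)
  cfg <- load_config(path)
  expect_equal(cfg$U, 2.5)
  expect_equal(cfg$c, 50L)
  expect_equal(cfg$mode, "seq_dep")
  expect_equal(cfg$U2, 0.65) # untouched default
  cfg2 <- load_config(path, U = 4)
  expect_equal(cfg2$U, 4)
  writeLines("no_such_key: 1", path)
  expect_error(load_config(path), "unknown configuration")
})

test_that("is_better implements the longest-then-lowest-RMSD order", {
  U <- 3.5
  expect_true(is_better(fake_ali(10, 3.0, 1), fake_ali(8, 1.0, 2), U))
  expect_false(is_better(fake_ali(10, 3.0, 1), fake_ali(10, 2.0, 2), U))
  expect_true(is_better(fake_ali(10, 2.0, 2), fake_ali(10, 3.0, 1), U))
  # feasibility dominates: 1 feasible pair beats a long infeasible alignment
  expect_true(is_better(fake_ali(1, 0.5, 2), fake_ali(30, 9.0, 1), U))
  expect_false(is_better(fake_ali(30, 9.0, 1), fake_ali(1, 0.5, 2), U))
  # exact ties: first found wins
  expect_true(is_better(fake_ali(5, 1.0, 1), fake_ali(5, 1.0, 2), U))
  expect_false(is_better(fake_ali(5, 1.0, 2), fake_ali(5, 1.0, 1), U))
  # empty alignment is feasible-at-length-zero
  empty <- fake_ali(0, NA_real_, 1)
  expect_true(is_better(fake_ali(1, 1.0, 2), empty, U))
  expect_true(is_better(empty, fake_ali(4, 9.9, 2), U))
})

test_that("is_better is a strict total order on random alignments", {
  set.seed(5)
  pool <- lapply(1:40, function(i)
    fake_ali(sample(0:12, 1), c(sample(c(runif(1, 0, 6), NA), 1)), i))
  pool <- lapply(pool, function(a) {
    if (a$n_pairs == 0) a$rmsd <- NA_real_
    if (a$n_pairs > 0 && is.na(a$rmsd)) a$rmsd <- runif(1, 0, 6)
    a
  })
  U <- 3.5
  for (q in 1:300) {
    abc <- sample(40, 3, replace = TRUE)
    a <- pool[[abc[1]]]; b <- pool[[abc[2]]]; c <- pool[[abc[3]]]
    # antisymmetry (identical objects tie via created index)
    if (!identical(a, b)) expect_false(is_better(a, b, U) && is_better(b, a, U))
    # transitivity
    if (is_better(a, b, U) && is_better(b, c, U))
      expect_true(is_better(a, c, U))
  }
})

test_that("candidate pairs: seq_indep admits all, seq_dep by position", {
  t3 <- make_structure(3, "helix", seed = 1)
  m2 <- make_structure(3, "helix", seed = 2)
  p <- candidate_pairs(t3, m2, "seq_indep")
  expect_true(all(outer(1:3, 1:3, function(i, j)
    flexalign:::admits_pair(p, i, j))))

  t4 <- make_structure(4, "helix", seed = 1, bases = c("A", "C", "G", "U"))
  p4 <- candidate_pairs(t4, t4, "seq_dep")
  A <- flexalign:::admissible_matrix(p4)
  expect_equal(which(A, arr.ind = TRUE)[, 1], which(A, arr.ind = TRUE)[, 2],
               ignore_attr = TRUE)
  expect_equal(sum(A), 4L)
})

test_that("seq_dep on unequal lengths uses the best ungapped offset", {
  seq_long <- c("A", "C", "G", "U", "A", "C", "G", "U", "G", "G")
  tgt <- make_structure(6, "random_coil", seed = 1, bases = seq_long[3:8])
  mod <- make_structure(10, "random_coil", seed = 2, bases = seq_long)
  pred <- candidate_pairs(tgt, mod, "seq_dep")
  # independent offset scan over the base strings
  best <- -Inf; besto <- NA
  for (o in -(6 - 1):(10 - 1)) {
    i <- 1:6; j <- i + o; ok <- j >= 1 & j <= 10
    if (!any(ok)) next
    sc <- sum(seq_long[3:8][i[ok]] == seq_long[j[ok]])
    if (sc > best) { best <- sc; besto <- o }
  }
  expect_equal(besto, 2L)
  expect_equal(pred$corr, 1:6 + 2L)

  # unrelated sequences of different length: mode error
  t2 <- make_structure(7, "random_coil", seed = 1,
                       bases = c("A", "A", "A", "A", "A", "A", "A"))
  m2 <- make_structure(8, "random_coil", seed = 2,
                       bases = c("C", "G", "C", "G", "C", "G", "C", "G"))
  expect_error(candidate_pairs(t2, m2, "seq_dep"), "near-identical")
})

test_that("oracle_align finds exact optima on toy instances", {
  s <- make_structure(4, "helix", seed = 6)
  o <- oracle_align(s, s, 3.5, "seq_indep")
  expect_equal(o$n_pairs, 4L)
  expect_lt(o$rmsd, 1e-9)

  # rigid copy with one residue teleported far away, tight threshold
  m <- perturb(s, rigid = list(axis = c(0, 1, 1), angle = 0.5,
                               translation = c(2, 2, 2)),
               outliers = cbind(3L, 50), seed = 2)
  o2 <- oracle_align(s, m, 1.0, "seq_indep")
  expect_equal(o2$n_pairs, 3L)
  expect_false(3L %in% o2$pairs[, 2L])

  # U below every multi-pair optimum: single pair (or empty) remains
  a <- make_structure(4, "random_coil", seed = 11)
  b <- make_structure(4, "random_coil", seed = 99)
  o3 <- oracle_align(a, b, 0.05, "seq_indep")
  expect_lte(o3$n_pairs, 1L)
  if (o3$n_pairs == 1L) expect_lte(o3$rmsd, 0.05)

  expect_error(oracle_align(make_structure(9, "helix", seed = 1),
                            s, 3.5, "seq_indep"), "8")
})

test_that("monotone oracle never beats the unrestricted oracle", {
  for (q in 1:5) {
    inst <- toy_instance(q, nmax = 5)
    full <- oracle_align(inst$target, inst$model, 3.5, "seq_indep",
                         monotone = FALSE)
    mono <- oracle_align(inst$target, inst$model, 3.5, "seq_indep",
                         monotone = TRUE)
    expect_gte(full$n_pairs, mono$n_pairs)
    expect_lte(full$rmsd, 3.5)
  }
})

test_that("stop controller implements the four halting criteria", {
  mk <- function(...) heuristic_config(...)
  clock <- local({
    t <- 0
    function(advance = NULL) {
      if (!is.null(advance)) t <<- t + advance
      t
    }
  })
  cfg <- mk(cl = 300, cg = 3, bi0 = 10, delta_t = 2)
  ctrl <- stop_controller(cfg, now = function() clock())

  # (i) coverage always halts
  expect_true(stop_should_halt(ctrl, cfg, coverage_complete = TRUE))
  expect_equal(ctrl$reason, "coverage")

  # (iv) buffer: no improvement for bi0 seconds
  expect_false(stop_should_halt(ctrl, cfg))
  clock(9.5)
  expect_false(stop_should_halt(ctrl, cfg))
  clock(1)
  expect_true(stop_should_halt(ctrl, cfg))
  expect_equal(ctrl$reason, "buffer")

  # improvement extends the buffer by delta_t
  ctrl2 <- stop_controller(cfg, now = function() clock())
  s <- make_structure(4, "helix", seed = 1)
  a1 <- new_alignment(s, s, cbind(1:2, 1:2), "seq_indep", "oracle")
  expect_true(flexalign:::sc_offer(ctrl2, a1))
  clock(11) # 11 < bi0 + delta_t = 12 since the improvement
  expect_false(stop_should_halt(ctrl2, cfg))
  clock(1.5)
  expect_true(stop_should_halt(ctrl2, cfg))

  # (ii) wall clock cap
  ctrl3 <- stop_controller(cfg, now = function() clock())
  clock(300)
  expect_true(stop_should_halt(ctrl3, cfg))
  expect_equal(ctrl3$reason, "time")

  # (iii) stagnant generations, GENS only
  ctrl4 <- stop_controller(cfg, now = function() clock())
  for (g in 1:3) flexalign:::sc_note_generation(ctrl4, improved = FALSE)
  expect_false(stop_should_halt(ctrl4, cfg, use_generations = FALSE))
  expect_true(stop_should_halt(ctrl4, cfg, use_generations = TRUE))
  expect_equal(ctrl4$reason, "stagnation")
})
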