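# GENS: genetic algorithm over residue-assignment chromosomes.  A chromosome
# is an integer vector v of length n (target length); v[i] = j > 0 aligns
# target residue i with model residue j, v[i] = 0 leaves it unaligned.
# Admissibility: nonzero values are unique and strictly increasing along the
# chain (and, in sequence-dependent mode, equal to the positional
# correspondence).

#' Admissibility check for a chromosome
#'
#' @param v integer assignment vector (0 = unassigned).
#' @param m number of model residues.
#' @param corr optional sequence-dependent correspondence vector from
#'   [candidate_pairs()].
#' @return Logical scalar.
#' @export
is_admissible <- function(v, m, corr = NULL) {
  if (any(v < 0L) || any(v > m)) return(FALSE)
  nz <- v[v > 0L]
  if (anyDuplicated(nz) > 0L) return(FALSE)
  if (length(nz) > 1L && any(diff(nz) <= 0L)) return(FALSE)
  if (!is.null(corr)) {
    i <- which(v > 0L)
    if (any(is.na(corr[i])) || any(v[i] != corr[i])) return(FALSE)
  }
  TRUE
}

corr_arg <- function(corr) if (is.null(corr)) integer(0) else as.integer(corr)

# One random admissible chromosome: positions visited in random order, each
# assigned uniformly among 0 and the model indices that keep admissibility.
random_chromosome <- function(n, m, corr = NULL) {
  cpp_random_chromosome(n, m, corr_arg(corr))
}

#' Initial GENS population
#'
#' `c` admissible chromosomes, each filled position by position (in random
#' order, so no chain end is favored) with uniformly drawn still-available
#' model indices (or 0); every admissible assignment vector has nonzero
#' probability.
#'
#' @param n,m target and model residue counts.
#' @param c population size.
#' @param corr optional sequence-dependent correspondence vector.
#' @return A `c` x `n` integer matrix, one chromosome per row.
#' @export
init_population <- function(n, m, c, corr = NULL) {
  out <- matrix(0L, c, n)
  for (q in seq_len(c)) out[q, ] <- random_chromosome(n, m, corr)
  out
}

#' GENS fitness of chromosomes
#'
#' score = N_aligned - w_r * rmsd - w_b * N_bad - w_p * max(0, rmsd - U) *
#' N_aligned, where `rmsd` is the actual (optimal superposition, bead-level)
#' RMSD of the chromosome's pair set and `N_bad` counts aligned pairs whose
#' mean bead distance after that superposition exceeds `bad_pair_cutoff`
#' (default `U2`) — the "incorrectly aligned" residues. A cutoff at the
#' well-aligned-pair threshold is what gives the third criterion teeth: the
#' pooled RMSD dilutes the cost of an individual wrong pair roughly as 1/k,
#' so without a per-pair count the search happily accretes wrong pairs it
#' can never repair. The empty chromosome scores 0; higher is better.
#'
#' @param V an integer chromosome matrix (rows = individuals) or a single
#'   chromosome vector.
#' @param target,model [coarse_structure] objects.
#' @param config a [heuristic_config()] (uses `U`, `w_r`, `w_b`, `w_p`).
#' @return A list with numeric vectors `score`, `rmsd` and integer vectors
#'   `n_aligned`, `n_bad` (one entry per chromosome).
#' @export
fitness <- function(V, target, model, config) {
  if (is.null(dim(V))) V <- matrix(as.integer(V), 1L)
  storage.mode(V) <- "integer"
  if (ncol(V) != target$n) stop("chromosome length must equal target size")
  for (q in seq_len(nrow(V)))
    if (!is_admissible(V[q, ], model$n))
      stop("inadmissible chromosome at row ", q)
  cpp_chrom_fitness(target$p, target$r, target$b, target$p_present,
                    model$p, model$r, model$b, model$p_present,
                    V, config$U, config$bad_pair_cutoff,
                    config$w_r, config$w_b, config$w_p)
}

#' Two-point crossover with duplicate and monotonicity repair
#'
#' Draws cut points x < y; positions x..y come from `parent_i`, the rest
#' from `parent_j`. Duplicated nonzero values are repaired by zeroing one of
#' each duplicate pair at random; any entry then breaking the strictly
#' increasing order is zeroed in a scan whose direction is drawn at random
#' per call (a fixed direction would systematically favor fragments at one
#' chain end). The child of two identical parents is that parent.
#'
#' @param parent_i,parent_j admissible chromosomes of equal length.
#' @return An admissible child chromosome.
#' @export
crossover <- function(parent_i, parent_j) {
  if (length(parent_i) != length(parent_j))
    stop("parents must have equal length")
  cpp_crossover(as.integer(parent_i), as.integer(parent_j))
}

#' Mutate a chromosome
#'
#' Draws a point count k in 1..4 with the configured probabilities (defaults
#' .65/.15/.10/.10) and applies k independent point mutations, each of a type
#' drawn uniformly among: (i) unassign an assigned target residue;
#' (ii) assign a still-available model residue to an unassigned target
#' residue; (iii) re-assign an already assigned target residue; (iv) swap the
#' assignments of two target residues. Every choice is restricted to options
#' preserving admissibility (and the correspondence rule in
#' sequence-dependent mode); a point mutation with no legal option is
#' skipped.
#'
#' @param v admissible chromosome.
#' @param m number of model residues.
#' @param corr optional sequence-dependent correspondence vector.
#' @param point_probs probabilities of 1-, 2-, 3-, 4-point mutations.
#' @return The mutated admissible chromosome, with attribute `points` (the
#'   drawn point count).
#' @export
mutate <- function(v, m, corr = NULL,
                   point_probs = c(0.65, 0.15, 0.10, 0.10)) {
  stopifnot(length(point_probs) == 4L, abs(sum(point_probs) - 1) < 1e-8)
  res <- cpp_mutate(as.integer(v), m, corr_arg(corr), point_probs)
  out <- res$v
  attr(out, "points") <- res$points
  out
}

chromosome_to_pairs <- function(v) {
  i <- which(v > 0L)
  cbind(i, v[i])
}

#' Evolve GENS alignments
#'
#' Generational loop: individuals are scored with [fitness()]; the top
#' `elite_fraction` (default 15%) seed the next generation, which is filled
#' by mutation of a random elite (probability `p_mut`), crossover of two
#' random individuals of the current population (`p_cross`), or a fresh
#' random chromosome (`p_seed`), with the incumbent best individual copied
#' through unchanged. The loop halts on full coverage, the wall-clock cap,
#' `cg` stagnant generations, or the no-improvement time buffer.
#'
#' Multiple solutions are found by iterative peeling: after a run converges,
#' the residues used by its best alignment are removed and the search
#' reruns on the remainder, so each successive solution covers a disjoint
#' similar fragment — this is how structures sharing several fragments that
#' superpose only under different rigid transforms yield several disjoint
#' alignments. The collected solutions (plus low-overlap alternatives seen
#' along the way) are ranked by the preference order and filtered so that
#' each reported alignment shares less than `overlap_filter` of its pairs
#' with any better one.
#'
#' @param target,model [coarse_structure] objects.
#' @param config a [heuristic_config()].
#' @return A list of `rna_alignment` objects (best first; at most
#'   `config$max_solutions`), with attribute `diagnostics`.
#' @export
evolve <- function(target, model, config = heuristic_config()) {
  stopifnot(is_coarse_structure(target), is_coarse_structure(model))
  if (!is.null(config$seed)) set.seed(config$seed)
  pred <- candidate_pairs(target, model, config$mode)

  # iterative peeling: after each converged run, the residues used by its
  # best alignment are removed and the GA reruns on the remainder, so each
  # successive solution covers a disjoint similar fragment
  archive <- list()
  diag <- NULL
  t_left <- seq_len(target$n)
  m_left <- seq_len(model$n)
  for (peel in seq_len(config$max_solutions)) {
    if (length(t_left) < 1L || length(m_left) < 1L) break
    corr_sub <- remap_corr(pred$corr, t_left, m_left)
    if (!is.null(corr_sub) && all(is.na(corr_sub))) break
    run <- evolve_run(subset_structure(target, t_left),
                      subset_structure(model, m_left), corr_sub, config)
    if (is.null(diag)) diag <- attr(run, "diagnostics")
    run <- lapply(run, function(a) {
      if (a$n_pairs == 0L) return(a)
      new_alignment(target, model,
                    cbind(t_left[a$pairs[, 1L]], m_left[a$pairs[, 2L]]),
                    config$mode, "gens")
    })
    best <- run[[1L]]
    if (best$n_pairs == 0L) break
    archive <- c(archive, run)
    t_left <- setdiff(t_left, best$pairs[, 1L])
    m_left <- setdiff(m_left, best$pairs[, 2L])
  }
  if (length(archive) == 0L)
    archive <- list(empty_alignment(target, model, config$mode, "gens"))
  archive <- archive[rank_alignments(archive, config$U)]
  # diversity filter: each reported solution shares < overlap_filter of its
  # pairs with every better one
  kept <- list()
  for (a in archive) {
    if (length(kept) >= config$max_solutions) break
    pk <- paste(a$pairs[, 1L], a$pairs[, 2L])
    ok <- TRUE
    for (b in kept) {
      bk <- paste(b$pairs[, 1L], b$pairs[, 2L])
      if (a$n_pairs == 0L ||
          sum(pk %in% bk) / a$n_pairs >= config$overlap_filter) {
        ok <- FALSE
        break
      }
    }
    if (ok || length(kept) == 0L) kept[[length(kept) + 1L]] <- a
  }
  attr(kept, "diagnostics") <- diag
  kept
}

# correspondence vector restricted to the remaining target/model residues
remap_corr <- function(corr, t_left, m_left) {
  if (is.null(corr)) return(NULL)
  out <- match(corr[t_left], m_left)
  as.integer(out)
}

# one GA run on (sub)structures; returns alignments ranked best-first
evolve_run <- function(target, model, corr, config) {
  n <- target$n
  m <- model$n
  csize <- config$c
  ctrl <- stop_controller(config)
  best_ali <- empty_alignment(target, model, config$mode, "gens")
  ctrl$best <- best_ali
  archive <- list()
  archive_keys <- character(0)

  pop <- init_population(n, m, csize, corr)
  fit <- fitness_raw(pop, target, model, config)
  n_elite <- max(1L, ceiling(config$elite_fraction * csize))
  generation <- 0L
  full_n <- if (is.null(corr)) min(n, m) else sum(!is.na(corr))

  add_to_archive <- function(ali) {
    key <- pair_key(ali$pairs)
    if (!key %in% archive_keys) {
      archive[[length(archive) + 1L]] <<- ali
      archive_keys <<- c(archive_keys, key)
    }
  }

  note_best <- function(fit, pop) {
    # offer the fittest feasible chromosome of this generation as alignment
    feas <- which(fit$n_aligned > 0L & !is.na(fit$rmsd) & fit$rmsd <= config$U)
    if (length(feas) == 0L) return(FALSE)
    ordf <- feas[order(-fit$n_aligned[feas], fit$rmsd[feas], feas)]
    q <- ordf[1L]
    cand <- new_alignment(target, model, chromosome_to_pairs(pop[q, ]),
                          config$mode, "gens")
    improved <- sc_offer(ctrl, cand)
    if (improved) {
      best_ali <<- cand
      add_to_archive(cand)
    }
    # also track the best feasible chromosome sharing little of the current
    # best's pair set: the seed of an alternative (e.g. disjoint-fragment)
    # solution that plain elitism would otherwise forget
    if (best_ali$n_pairs > 0L) {
      bk <- paste(best_ali$pairs[, 1L], best_ali$pairs[, 2L])
      for (q2 in ordf) {
        pr <- chromosome_to_pairs(pop[q2, ])
        ov <- sum(paste(pr[, 1L], pr[, 2L]) %in% bk) / nrow(pr)
        if (ov < config$overlap_filter) {
          add_to_archive(new_alignment(target, model, pr, config$mode, "gens"))
          break
        }
      }
    }
    improved
  }
  note_best(fit, pop)

  repeat {
    complete <- best_ali$n_pairs >= full_n && best_ali$n_pairs > 0L
    if (stop_should_halt(ctrl, config, coverage_complete = complete,
                         use_generations = TRUE)) break
    if (generation >= config$max_generations) {
      ctrl$reason <- "budget"
      break
    }
    # elite = fittest *distinct* chromosomes (exact copies, e.g. children of
    # identical crossover parents, must not flood the seed pool, or drift
    # stalls on the first local optimum); incumbent best copied through
    pop <- cpp_generation(pop, fit$score, n_elite, m, corr_arg(corr),
                          config$p_mut, config$p_cross,
                          config$point_mut_probs)
    fit <- fitness_raw(pop, target, model, config)
    generation <- generation + 1L
    improved <- note_best(fit, pop)
    sc_note_generation(ctrl, improved)
  }

  # archive: best-so-far history plus distinct feasible final-population
  # alignments, deduplicated by pair set and ranked by preference
  feas <- which(fit$n_aligned > 0L & !is.na(fit$rmsd) & fit$rmsd <= config$U)
  for (q in feas) {
    key <- pair_key(chromosome_to_pairs(pop[q, ]))
    if (key %in% archive_keys) next
    archive[[length(archive) + 1L]] <-
      new_alignment(target, model, chromosome_to_pairs(pop[q, ]),
                    config$mode, "gens")
    archive_keys <- c(archive_keys, key)
  }
  if (length(archive) == 0L) archive <- list(best_ali)
  archive <- archive[rank_alignments(archive, config$U)]
  attr(archive, "diagnostics") <- list(generations = generation,
                                       stop_reason = ctrl$reason,
                                       elapsed = ctrl$now() - ctrl$t0)
  archive
}

# fitness without the per-row admissibility re-check (operators guarantee it;
# asserted in tests)
fitness_raw <- function(V, target, model, config) {
  storage.mode(V) <- "integer"
  cpp_chrom_fitness(target$p, target$r, target$b, target$p_present,
                    model$p, model$r, model$b, model$p_present,
                    V, config$U, config$bad_pair_cutoff,
                    config$w_r, config$w_b, config$w_p)
}

pair_key <- function(pairs) paste(t(pairs), collapse = ",")

rank_alignments <- function(alis, U) {
  feas <- vapply(alis, is_feasible, logical(1), U = U)
  len <- vapply(alis, function(a) a$n_pairs, integer(1))
  rmsd <- vapply(alis, function(a) if (is.na(a$rmsd)) Inf else a$rmsd,
                 numeric(1))
  created <- vapply(alis, function(a) a$created, integer(1))
  order(!feas, -len, rmsd, created)
}

#' Align two structures with the GENS heuristic
#'
#' Runs [evolve()] and returns the best alignment; the full ranked solution
#' archive is available as attribute `solutions`.
#'
#' @inheritParams evolve
#' @return The best `rna_alignment` (attributes `solutions`,
#'   `diagnostics`).
#' @examples
#' s <- make_structure(12, "helix", seed = 1)
#' cfg <- heuristic_config(mode = "seq_dep", seed = 1, max_generations = 50)
#' gens_align(s, s, cfg)$coverage
#' @export
gens_align <- function(target, model, config = heuristic_config()) {
  sols <- evolve(target, model, config)
  best <- sols[[1L]]
  attr(best, "solutions") <- sols
  attr(best, "diagnostics") <- attr(sols, "diagnostics")
  best
}
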