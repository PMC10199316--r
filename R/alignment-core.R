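# Shared alignment data model: configuration, the Alignment object, the
# preference order, candidate-pair rules for the two modes, the stopping
# controller, and an exhaustive oracle for toy instances.

#' Heuristic configuration
#'
#' All thresholds, probabilities and budgets shared by GEOS and GENS.
#'
#' @param U final RMSD threshold in angstrom; every returned alignment
#'   satisfies `rmsd <= U`. Default 3.5, valid range (0, 20].
#' @param U2 RMSD gate for the two-pair kernel stage (default 0.65).
#' @param U3 RMSD gate for the three-pair kernel (default 1.0);
#'   `0 < U2 < U3 < U` is enforced.
#' @param c GENS population size (default 200).
#' @param cl wall-clock cap in seconds (default 300).
#' @param cg GENS stagnant-generation cap (default 300).
#' @param bi0 initial no-improvement time buffer in seconds (default 10).
#' @param delta_t buffer increment per improvement in seconds (default 1).
#' @param p_mut,p_cross,p_seed GENS operator probabilities (defaults .74, .25,
#'   .01; must sum to 1).
#' @param elite_fraction fraction of fittest individuals seeding the next
#'   generation (default 0.15).
#' @param point_mut_probs probabilities of 1-, 2-, 3- and 4-point mutations
#'   (defaults .65, .15, .10, .10; must sum to 1).
#' @param mode `"seq_indep"` (default) admits every residue pair;
#'   `"seq_dep"` admits only positionally corresponding pairs.
#' @param threads requested worker count (echoed in reports; this
#'   implementation executes sequentially, see the package vignette).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param w_r,w_b,w_p GENS fitness weights on RMSD, incorrectly aligned
#'   residues, and the over-threshold penalty (defaults 1, 1, 2).
#' @param bad_pair_cutoff per-pair bead distance (angstrom) above which an
#'   aligned pair counts as incorrectly aligned in the GENS fitness;
#'   `NULL` (default) uses `U2`, the threshold below which a nucleotide pair
#'   counts as well aligned.
#' @param pair_draws,ntc_redraws,nmc_draws GEOS kernel rejection-sampling
#'   budgets: model-pair draws for the two-pair stage, third-target-residue
#'   redraws, and model draws per third residue.
#' @param max_kernels optional cap on GEOS kernel expansions (default `Inf`,
#'   i.e. governed by the stop controller).
#' @param max_generations optional cap on GENS generations (default `Inf`).
#' @param refit_extension logical; when `TRUE` (default) GEOS re-superposes
#'   the growing alignment after every accepted pair and searches with the
#'   updated transform; when `FALSE` the kernel transform is kept throughout.
#' @param max_solutions maximum number of GENS alignments reported.
#' @param overlap_filter fraction in (0, 1]; a reported GENS solution may
#'   share at most this fraction of its pairs with any better reported
#'   solution (default 0.5, the alternative-alignment filter; 1 disables
#'   filtering).
#' @return A validated object of class `heuristic_config`.
#' @export
heuristic_config <- function(U = 3.5, U2 = 0.65, U3 = 1.0,
                             c = 200L, cl = 300, cg = 300L,
                             bi0 = 10, delta_t = 1,
                             p_mut = 0.74, p_cross = 0.25, p_seed = 0.01,
                             elite_fraction = 0.15,
                             point_mut_probs = c(0.65, 0.15, 0.10, 0.10),
                             mode = c("seq_indep", "seq_dep"),
                             threads = 1L, seed = NULL,
                             w_r = 1, w_b = 1, w_p = 2,
                             bad_pair_cutoff = NULL,
                             pair_draws = 5000L, ntc_redraws = 100L,
                             nmc_draws = 500L,
                             max_kernels = Inf, max_generations = Inf,
                             refit_extension = TRUE, max_solutions = 5L,
                             overlap_filter = 0.5) {
  mode <- match.arg(mode)
  cfg <- list(U = U, U2 = U2, U3 = U3, c = as.integer(c), cl = cl,
              cg = as.integer(cg), bi0 = bi0, delta_t = delta_t,
              p_mut = p_mut, p_cross = p_cross, p_seed = p_seed,
              elite_fraction = elite_fraction,
              point_mut_probs = point_mut_probs, mode = mode,
              threads = as.integer(threads), seed = seed,
              w_r = w_r, w_b = w_b, w_p = w_p,
              bad_pair_cutoff = if (is.null(bad_pair_cutoff)) U2
                                else bad_pair_cutoff,
              pair_draws = as.integer(pair_draws),
              ntc_redraws = as.integer(ntc_redraws),
              nmc_draws = as.integer(nmc_draws),
              max_kernels = max_kernels, max_generations = max_generations,
              refit_extension = isTRUE(refit_extension),
              max_solutions = as.integer(max_solutions),
              overlap_filter = overlap_filter)
  validate_config(cfg)
  structure(cfg, class = "heuristic_config")
}

validate_config <- function(cfg) {
  if (!(cfg$U > 0 && cfg$U <= 20))
    stop("U must lie in (0, 20] angstrom, got ", cfg$U)
  if (!(cfg$U2 > 0 && cfg$U2 < cfg$U3 && cfg$U3 < cfg$U))
    stop("thresholds must satisfy 0 < U2 < U3 < U")
  if (abs(cfg$p_mut + cfg$p_cross + cfg$p_seed - 1) > 1e-8)
    stop("operator probabilities p_mut + p_cross + p_seed must sum to 1")
  if (length(cfg$point_mut_probs) != 4L ||
      abs(sum(cfg$point_mut_probs) - 1) > 1e-8)
    stop("point_mut_probs must be 4 probabilities summing to 1")
  if (!(cfg$elite_fraction > 0 && cfg$elite_fraction < 1))
    stop("elite_fraction must lie in (0, 1)")
  if (cfg$c < 2L) stop("population size c must be at least 2")
  if (cfg$threads < 1L) stop("threads must be a positive integer")
  if (!(cfg$overlap_filter > 0 && cfg$overlap_filter <= 1))
    stop("overlap_filter must lie in (0, 1]")
  invisible(cfg)
}

#' Read a heuristic configuration from a YAML file
#'
#' A flat key-value file whose keys mirror the arguments of
#' [heuristic_config()]; every key is optional and missing keys take the
#' defaults. Unknown keys are an error.
#'
#' @param path path to the YAML file.
#' @param ... overrides applied on top of the file values.
#' @return A `heuristic_config`.
#' @export
load_config <- function(path, ...) {
  vals <- if (is.null(path)) list() else yaml::yaml.load_file(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(heuristic_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  vals <- modifyList(vals, list(...))
  do.call(heuristic_config, vals)
}

# ---------------------------------------------------------------------------
# Alignment object

the_counter <- new.env(parent = emptyenv())
the_counter$i <- 0L

next_creation_index <- function() {
  the_counter$i <- the_counter$i + 1L
  the_counter$i
}

#' Construct an alignment between two coarse-grained structures
#'
#' An injective pairing of target residues to model residues together with
#' the rigid transform and actual RMSD realizing it (computed at
#' construction via [alignment_rmsd()]).
#'
#' @param target,model [coarse_structure] objects.
#' @param pairs two-column integer matrix of (target, model) residue indices;
#'   zero rows give the empty alignment (undefined RMSD).
#' @param mode `"seq_indep"` or `"seq_dep"`.
#' @param source which procedure produced it: `"geos"`, `"gens"` or
#'   `"oracle"`.
#' @return An object of class `rna_alignment` with fields `pairs`,
#'   `rotation`, `translation`, `rmsd`, `n_pairs`, `coverage` (fraction of
#'   target residues aligned), `mode`, `source`, `created` (a monotone
#'   creation index used to break exact ties deterministically).
#' @export
new_alignment <- function(target, model, pairs,
                          mode = c("seq_indep", "seq_dep"),
                          source = c("geos", "gens", "oracle")) {
  mode <- match.arg(mode)
  source <- match.arg(source)
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0L) {
    fit <- list(rotation = diag(3), translation = numeric(3),
                rmsd = NA_real_, pair_dist = numeric(0))
  } else {
    fit <- alignment_rmsd(target, model, pairs)
  }
  structure(list(pairs = pairs, rotation = fit$rotation,
                 translation = fit$translation, rmsd = fit$rmsd,
                 pair_dist = fit$pair_dist,
                 n_pairs = nrow(pairs), n_target = target$n,
                 n_model = model$n,
                 coverage = nrow(pairs) / target$n,
                 mode = mode, source = source,
                 created = next_creation_index()),
            class = "rna_alignment")
}

empty_alignment <- function(target, model, mode = "seq_indep",
                            source = "geos") {
  new_alignment(target, model, matrix(integer(), 0L, 2L), mode, source)
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("<alignment [%s/%s]: %d pairs, coverage %.1f%%, RMSD %s>\n",
              x$source, x$mode, x$n_pairs, 100 * x$coverage,
              if (is.na(x$rmsd)) "undefined" else sprintf("%.4f", x$rmsd)))
  invisible(x)
}

is_feasible <- function(a, U) {
  a$n_pairs == 0L || (!is.na(a$rmsd) && a$rmsd <= U)
}

#' Preference order between two alignments
#'
#' Returns `TRUE` when `a` is preferred over `b`: feasibility (`rmsd <= U`)
#' dominates; among feasible alignments the longer wins; at equal length the
#' lower actual RMSD wins; at equal length and RMSD the earlier-created one
#' wins. The empty alignment counts as feasible with length zero.
#'
#' @param a,b `rna_alignment` objects (`b` may be `NULL`, in which case `a`
#'   is preferred).
#' @param U RMSD threshold in angstrom.
#' @return Logical scalar.
#' @export
is_better <- function(a, b, U) {
  if (is.null(b)) return(TRUE)
  if (is.null(a)) return(FALSE)
  fa <- is_feasible(a, U)
  fb <- is_feasible(b, U)
  if (fa != fb) return(fa)
  ra <- if (is.na(a$rmsd)) Inf else a$rmsd
  rb <- if (is.na(b$rmsd)) Inf else b$rmsd
  if (fa) { # both feasible: longest, then lowest rmsd, then first found
    if (a$n_pairs != b$n_pairs) return(a$n_pairs > b$n_pairs)
    if (ra != rb) return(ra < rb)
    return(a$created < b$created)
  }
  # both infeasible: closer to feasibility, then first found
  if (ra != rb) return(ra < rb)
  a$created < b$created
}

# ---------------------------------------------------------------------------
# Candidate pairs for the two modes

#' Candidate-pair rule for an alignment mode
#'
#' In sequence-independent mode every (target, model) residue pair is
#' admissible. In sequence-dependent mode residues must occupy corresponding
#' sequence positions: for equal-length structures position i pairs only with
#' position i; for unequal lengths the ungapped offset maximizing
#' base-identity matches defines the correspondence, and the mode errors if
#' the best offset matches less than 90% of the overlapping bases.
#'
#' @param target,model [coarse_structure] objects.
#' @param mode `"seq_indep"` or `"seq_dep"`.
#' @return An object of class `pair_predicate` with fields `mode`, `n`, `m`
#'   and (seq_dep only) `corr`, an integer vector mapping each target index
#'   to its admissible model index (`NA` where none exists).
#' @export
candidate_pairs <- function(target, model, mode = c("seq_indep", "seq_dep")) {
  mode <- match.arg(mode)
  stopifnot(is_coarse_structure(target), is_coarse_structure(model))
  n <- target$n
  m <- model$n
  corr <- NULL
  if (mode == "seq_dep") {
    if (n == m) {
      corr <- seq_len(n)
    } else {
      corr <- best_offset_correspondence(target$base, model$base)
    }
  }
  structure(list(mode = mode, n = n, m = m, corr = corr),
            class = "pair_predicate")
}

best_offset_correspondence <- function(tb, mb, min_identity = 0.9) {
  n <- length(tb)
  m <- length(mb)
  best <- NULL
  for (o in seq(-(n - 1L), m - 1L)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= m
    if (!any(ok)) next
    matches <- sum(tb[i[ok]] == mb[j[ok]])
    identity <- matches / sum(ok)
    cand <- list(o = o, matches = matches, identity = identity)
    if (is.null(best) || matches > best$matches ||
        (matches == best$matches && abs(o) < abs(best$o)) ||
        (matches == best$matches && abs(o) == abs(best$o) && o < best$o))
      best <- cand
  }
  if (is.null(best) || best$identity < min_identity)
    stop("sequence-dependent mode requires near-identical sequences: ",
         sprintf("best ungapped offset matches only %.0f%% of overlapping bases",
                 100 * if (is.null(best)) 0 else best$identity))
  corr <- seq_len(n) + best$o
  corr[corr < 1L | corr > m] <- NA_integer_
  corr
}

# Does the predicate admit pair (i, j)?  Vectorized over j.
admits_pair <- function(pred, i, j) {
  if (pred$mode == "seq_indep") rep(TRUE, length(j))
  else !is.na(pred$corr[i]) & j == pred$corr[i]
}

# Target indices having at least one admissible partner.
admissible_targets <- function(pred) {
  if (pred$mode == "seq_indep") seq_len(pred$n) else which(!is.na(pred$corr))
}

# ---------------------------------------------------------------------------
# Stop controller

#' Create a stopping controller
#'
#' Tracks the best-so-far record, the adaptive no-improvement time buffer,
#' and generation stagnation, implementing the four halting criteria shared
#' by both heuristics: (i) full target coverage, (ii) wall-clock cap `cl`,
#' (iii) `cg` stagnant generations (GENS only), (iv) no improvement within
#' the current time buffer, which starts at `bi0` and grows by `delta_t`
#' on every improvement.
#'
#' @param config a [heuristic_config()].
#' @param now a zero-argument function returning the current time in seconds
#'   (injectable for testing; defaults to `Sys.time`).
#' @return A mutable controller object (environment) for
#'   [stop_should_halt()].
#' @export
stop_controller <- function(config, now = function() as.numeric(Sys.time())) {
  ctrl <- new.env(parent = emptyenv())
  ctrl$now <- now
  ctrl$t0 <- now()
  ctrl$best <- NULL
  ctrl$n_improve <- 0L
  ctrl$last_improve <- ctrl$t0
  ctrl$stagnation <- 0L
  ctrl$reason <- NA_character_
  ctrl$config <- config
  class(ctrl) <- "stop_controller"
  ctrl
}

# Offer a candidate alignment; records an improvement (buffer extension,
# stagnation reset) when it beats the incumbent best under is_better().
sc_offer <- function(ctrl, alignment) {
  if (is_better(alignment, ctrl$best, ctrl$config$U)) {
    ctrl$best <- alignment
    ctrl$n_improve <- ctrl$n_improve + 1L
    ctrl$last_improve <- ctrl$now()
    ctrl$stagnation <- 0L
    TRUE
  } else {
    FALSE
  }
}

sc_note_generation <- function(ctrl, improved) {
  if (!improved) ctrl$stagnation <- ctrl$stagnation + 1L
  invisible(ctrl)
}

#' Should the current run halt?
#'
#' @param ctrl a [stop_controller()].
#' @param config a [heuristic_config()].
#' @param coverage_complete logical: have all target residues been aligned
#'   within the threshold?
#' @param use_generations logical: also apply the stagnant-generation
#'   criterion (GENS).
#' @return Logical; when `TRUE` the triggering criterion is recorded in
#'   `ctrl$reason` (`"coverage"`, `"time"`, `"stagnation"` or `"buffer"`).
#' @export
stop_should_halt <- function(ctrl, config = ctrl$config,
                             coverage_complete = FALSE,
                             use_generations = FALSE) {
  if (coverage_complete) {
    ctrl$reason <- "coverage"
    return(TRUE)
  }
  t <- ctrl$now()
  if (t - ctrl$t0 >= config$cl) {
    ctrl$reason <- "time"
    return(TRUE)
  }
  if (use_generations && ctrl$stagnation >= config$cg) {
    ctrl$reason <- "stagnation"
    return(TRUE)
  }
  bi <- config$bi0 + config$delta_t * ctrl$n_improve
  if (t - ctrl$last_improve >= bi) {
    ctrl$reason <- "buffer"
    return(TRUE)
  }
  FALSE
}

# ---------------------------------------------------------------------------
# Exhaustive oracle for toy instances

perm_all <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_all(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Exhaustive optimal alignment of toy instances
#'
#' Enumerates every injective pair set admitted by the mode (optionally only
#' chain-order monotone ones, the GENS search space), evaluates the actual
#' RMSD of each, and returns the optimum under the preference order of
#' [is_better()]. Only intended for instances with at most 8 residues per
#' structure; larger inputs are refused.
#'
#' @param target,model [coarse_structure] objects with at most 8 residues.
#' @param U RMSD threshold in angstrom.
#' @param mode `"seq_indep"` or `"seq_dep"`.
#' @param monotone logical; restrict to pair sets whose model indices
#'   increase with the target index (the admissible chromosome space of
#'   GENS).
#' @return An `rna_alignment` with `source = "oracle"` (empty when not even
#'   a single pair is feasible).
#' @export
oracle_align <- function(target, model, U, mode = c("seq_indep", "seq_dep"),
                         monotone = FALSE) {
  mode <- match.arg(mode)
  n <- target$n
  m <- model$n
  if (n > 8L || m > 8L)
    stop("oracle_align is exhaustive and limited to structures of <= 8 residues")
  pred <- candidate_pairs(target, model, mode)
  sets <- enumerate_pair_sets(pred, monotone)
  if (length(sets) == 0L) return(empty_alignment(target, model, mode, "oracle"))
  rmsds <- cpp_pairlist_rmsd(target$p, target$r, target$b, target$p_present,
                             model$p, model$r, model$b, model$p_present,
                             sets)
  sizes <- vapply(sets, nrow, integer(1))
  feasible <- rmsds <= U
  if (!any(feasible)) return(empty_alignment(target, model, mode, "oracle"))
  best <- which(feasible)
  best <- best[order(-sizes[best], rmsds[best], best)][1L]
  new_alignment(target, model, sets[[best]], mode, "oracle")
}

enumerate_pair_sets <- function(pred, monotone) {
  n <- pred$n
  m <- pred$m
  sets <- list()
  if (pred$mode == "seq_dep") {
    # subsets of the correspondence pairs (always monotone)
    idx <- which(!is.na(pred$corr))
    for (k in seq_along(idx)) {
      ch <- combn(idx, k)
      for (q in seq_len(ncol(ch))) {
        ti <- ch[, q]
        sets[[length(sets) + 1L]] <- cbind(ti, pred$corr[ti])
      }
    }
    return(sets)
  }
  for (k in seq_len(min(n, m))) {
    tsub <- combn(n, k)
    msub <- combn(m, k)
    perms <- if (monotone) matrix(seq_len(k), 1L) else perm_all(k)
    for (a in seq_len(ncol(tsub))) {
      for (b in seq_len(ncol(msub))) {
        for (p in seq_len(nrow(perms))) {
          sets[[length(sets) + 1L]] <-
            cbind(tsub[, a], msub[perms[p, ], b][seq_len(k)])
        }
      }
    }
  }
  sets
}
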