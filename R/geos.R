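# GEOS: geometric kernel search.  Sample 3-pair kernels that pass the U2/U3
# superposition gates, expand each greedily under the final threshold U,
# keep the best alignment found.

#' Sample one alignment kernel
#'
#' Rejection-samples a kernel of three residue pairs: two target residues and
#' candidate model partners are drawn until the two-pair superposed RMSD
#' falls below `U2`; a third pair is then drawn until the three-pair RMSD
#' falls below `U3`, re-drawing the third target residue after a bounded
#' number of failed model draws. Draw budgets come from the configuration
#' (`pair_draws`, `ntc_redraws`, `nmc_draws`).
#'
#' @param target,model [coarse_structure] objects with at least 3 residues.
#' @param config a [heuristic_config()].
#' @param pred optional precomputed [candidate_pairs()] predicate.
#' @return A list of class `geos_kernel` with fields `pairs` (3 x 2),
#'   `rmsd2`, `rmsd3` (the gate values), `rotation`, `translation` (the
#'   three-pair fit), or `NULL` if the attempt budget was exhausted.
#' @export
sample_kernel <- function(target, model, config, pred = NULL) {
  if (target$n < 3L || model$n < 3L)
    stop("kernel sampling requires at least 3 residues in each structure")
  if (is.null(pred)) pred <- candidate_pairs(target, model, config$mode)
  tpool <- admissible_targets(pred)
  if (length(tpool) < 3L)
    stop("fewer than 3 target residues have admissible partners")

  ab <- sample(tpool, 2L)
  nta <- ab[1L]
  ntb <- ab[2L]

  stage1 <- sample_kernel_stage1(target, model, config, pred, nta, ntb)
  if (is.null(stage1)) return(NULL)
  nma <- stage1$nma
  ntb <- stage1$ntb # unchanged; kept for clarity
  nmb <- stage1$nmb

  cpool <- setdiff(tpool, c(nta, ntb))
  for (redraw in seq_len(config$ntc_redraws)) {
    if (length(cpool) == 0L) break
    ntc <- cpool[sample.int(length(cpool), 1L)]
    mpool <- model_partners(pred, ntc)
    mpool <- setdiff(mpool, c(nma, nmb))
    if (length(mpool) == 0L) next
    ndraw <- min(config$nmc_draws, 4L * length(mpool))
    nmc <- mpool[sample.int(length(mpool), ndraw, replace = TRUE)]
    cand <- cbind(nta, nma, ntb, nmb, ntc, nmc)
    r3 <- cpp_pairs_rmsd_batch(target$p, target$r, target$b, target$p_present,
                               model$p, model$r, model$b, model$p_present,
                               cand)
    hit <- which(r3 < config$U3)
    if (length(hit) > 0L) {
      h <- hit[1L]
      pairs <- matrix(c(nta, nma, ntb, nmb, ntc, nmc[h]),
                      3L, 2L, byrow = TRUE)
      fit <- alignment_rmsd(target, model, pairs)
      return(structure(list(pairs = as_pair_matrix(pairs),
                            rmsd2 = stage1$rmsd2, rmsd3 = fit$rmsd,
                            rotation = fit$rotation,
                            translation = fit$translation),
                       class = "geos_kernel"))
    }
  }
  NULL
}

# Model indices admissible as partners of target residue i.
model_partners <- function(pred, i) {
  if (pred$mode == "seq_indep") seq_len(pred$m)
  else if (is.na(pred$corr[i])) integer(0) else pred$corr[i]
}

# Stage 1 of kernel sampling: find (NMA, NMB) with two-pair rmsd < U2.
sample_kernel_stage1 <- function(target, model, config, pred, nta, ntb) {
  pa <- model_partners(pred, nta)
  pb <- model_partners(pred, ntb)
  drawn <- 0L
  batch <- 256L
  while (drawn < config$pair_draws) {
    nb <- min(batch, config$pair_draws - drawn)
    nma <- pa[sample.int(length(pa), nb, replace = TRUE)]
    nmb <- pb[sample.int(length(pb), nb, replace = TRUE)]
    ok <- nma != nmb
    drawn <- drawn + nb
    if (!any(ok)) next
    cand <- cbind(nta, nma[ok], ntb, nmb[ok])
    r2 <- cpp_pairs_rmsd_batch(target$p, target$r, target$b, target$p_present,
                               model$p, model$r, model$b, model$p_present,
                               cand)
    hit <- which(r2 < config$U2)
    if (length(hit) > 0L) {
      h <- hit[1L]
      return(list(nma = cand[h, 2L], ntb = ntb, nmb = cand[h, 4L],
                  rmsd2 = r2[h]))
    }
  }
  NULL
}

#' Greedily extend a kernel into an alignment
#'
#' Starts from the kernel's three pairs and its rigid transform, then
#' repeatedly adds the admissible unused residue pair with the smallest
#' inter-bead Euclidean distance under the current transform, recomputing
#' the optimal superposition after every accepted pair. A pair is accepted
#' only if the RMSD of the grown alignment stays strictly below `U`, so the
#' returned alignment always satisfies the threshold. With
#' `config$refit_extension = FALSE` the kernel transform is kept for the
#' whole extension (nearest-pair search only; the reported RMSD is always
#' the optimal one).
#'
#' @param kernel a kernel from [sample_kernel()].
#' @param target,model [coarse_structure] objects.
#' @param config a [heuristic_config()].
#' @param pred optional precomputed [candidate_pairs()] predicate.
#' @return An `rna_alignment` with `source = "geos"`.
#' @export
extend_kernel <- function(kernel, target, model, config, pred = NULL) {
  stopifnot(inherits(kernel, "geos_kernel"))
  if (is.null(pred)) pred <- candidate_pairs(target, model, config$mode)
  pairs <- kernel$pairs
  rot <- kernel$rotation
  tra <- kernel$translation
  n <- target$n
  m <- model$n
  admissible <- admissible_matrix(pred)
  used_t <- rep(FALSE, n)
  used_m <- rep(FALSE, m)
  used_t[pairs[, 1L]] <- TRUE
  used_m[pairs[, 2L]] <- TRUE

  repeat {
    open <- admissible & !used_t & matrix(!used_m, n, m, byrow = TRUE)
    if (!any(open)) break
    D <- pair_distance_matrix(target, model, rot, tra)
    D[!open] <- Inf
    best <- arrayInd(which.min(D), dim(D))
    cand <- rbind(pairs, c(best[1L], best[2L]))
    fit <- alignment_rmsd(target, model, cand)
    if (fit$rmsd >= config$U) break
    pairs <- cand
    used_t[best[1L]] <- TRUE
    used_m[best[2L]] <- TRUE
    if (config$refit_extension) {
      rot <- fit$rotation
      tra <- fit$translation
    }
  }
  new_alignment(target, model, pairs, config$mode, "geos")
}

admissible_matrix <- function(pred) {
  if (pred$mode == "seq_indep") {
    matrix(TRUE, pred$n, pred$m)
  } else {
    A <- matrix(FALSE, pred$n, pred$m)
    ok <- which(!is.na(pred$corr))
    A[cbind(ok, pred$corr[ok])] <- TRUE
    A
  }
}

# Mean shared-bead Euclidean distance between every target residue and every
# model residue after transforming the model; n x m matrix.
pair_distance_matrix <- function(target, model, rotation, translation) {
  mp <- apply_transform(model$p, rotation, translation)
  mr <- apply_transform(model$r, rotation, translation)
  mb <- apply_transform(model$b, rotation, translation)
  dr <- cross_dist(target$r, mr)
  db <- cross_dist(target$b, mb)
  dp <- cross_dist(target$p, mp)
  shared_p <- outer(target$p_present, model$p_present, "&")
  dp[!shared_p] <- 0
  (dp + dr + db) / (2 + shared_p)
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Align two structures with the GEOS heuristic
#'
#' Samples kernels and expands each into an alignment, keeping the best
#' under the preference order (longest within the RMSD threshold, ties by
#' lower RMSD, then first found) until a stopping criterion fires: full
#' target coverage, the wall-clock cap, the adaptive no-improvement buffer,
#' or the optional kernel budget.
#'
#' @param target,model [coarse_structure] objects.
#' @param config a [heuristic_config()].
#' @return The best `rna_alignment` found (empty, with a diagnostic
#'   attribute, if no kernel was ever found). Attribute `diagnostics` lists
#'   kernels sampled/expanded, the stop reason, and the elapsed time.
#' @examples
#' s <- make_structure(20, "helix", seed = 1)
#' a <- geos_align(s, s, heuristic_config(seed = 1, max_kernels = 50))
#' a$coverage
#' @export
geos_align <- function(target, model, config = heuristic_config()) {
  stopifnot(is_coarse_structure(target), is_coarse_structure(model))
  if (!is.null(config$seed)) set.seed(config$seed)
  pred <- candidate_pairs(target, model, config$mode)
  ctrl <- stop_controller(config)
  best <- empty_alignment(target, model, config$mode, "geos")
  ctrl$best <- best
  seen <- new.env(parent = emptyenv())
  sampled <- 0L
  expanded <- 0L
  failed <- 0L
  full_n <- length(admissible_targets(pred))
  repeat {
    complete <- best$n_pairs >= full_n && best$n_pairs > 0L
    if (stop_should_halt(ctrl, config, coverage_complete = complete)) break
    if (expanded >= config$max_kernels) {
      ctrl$reason <- "budget"
      break
    }
    kernel <- sample_kernel(target, model, config, pred)
    sampled <- sampled + 1L
    if (is.null(kernel)) {
      failed <- failed + 1L
      next
    }
    key <- paste(t(kernel$pairs[order(kernel$pairs[, 1L]), ]), collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    ali <- extend_kernel(kernel, target, model, config, pred)
    expanded <- expanded + 1L
    if (sc_offer(ctrl, ali)) best <- ali
  }
  diag <- list(kernels_sampled = sampled, kernels_expanded = expanded,
               kernels_failed = failed, stop_reason = ctrl$reason,
               elapsed = ctrl$now() - ctrl$t0)
  if (best$n_pairs == 0L)
    diag$note <- "no kernel passed the U2/U3 gates; structures may be geometrically incongruent at these thresholds"
  attr(best, "diagnostics") <- diag
  best
}
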