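# Deterministic synthetic structures and perturbation fixtures.  Generated
# directly at the coarse-grained (bead) level; expand_to_atoms() writes a
# matching synthetic full-atom representation for end-to-end I/O tests.

#' Generate a deterministic toy structure
#'
#' `"helix"` places residues on an A-form-like helical curve (rise 2.8
#' angstrom, twist 32.7 degrees per residue, radius 9.4 angstrom) with the
#' three beads at fixed offsets in the local helical frame; the base bead
#' sits at a base-dependent distance from the axis, reflecting the size
#' difference between purines and pyrimidines, so the helix is not
#' self-similar under register shifts. `"random_coil"` grows a self-avoiding
#' random walk with 6 angstrom steps and a 3 angstrom minimum inter-residue
#' distance. The 5'-terminal residue carries no phosphate bead, as in real
#' chains. Bases cycle through ACGU unless overridden.
#'
#' @param n residue count (at least 3).
#' @param geometry `"helix"` or `"random_coil"`.
#' @param seed integer seed; the output is a pure function of `(n, geometry,
#'   seed, bases)`.
#' @param bases optional character vector of base letters, recycled to
#'   length `n`.
#' @param name structure identifier.
#' @return A [coarse_structure].
#' @export
make_structure <- function(n, geometry = c("helix", "random_coil"),
                           seed = 1L, bases = NULL, name = NULL) {
  geometry <- match.arg(geometry)
  if (n < 3L) stop("n must be at least 3")
  if (is.null(bases)) bases <- c("A", "C", "G", "U")
  base <- rep_len(toupper(bases), n)
  if (is.null(name)) name <- sprintf("%s_%d_seed%d", geometry, n, seed)
  with_seed(seed, {
    if (geometry == "helix") helix_beads(n, base, name)
    else coil_beads(n, base, name)
  })
}

# base-bead distance from the helix axis (angstrom): purines reach further
BASE_REACH <- c(A = 4.9, G = 5.1, C = 3.6, U = 3.4, T = 3.5, N = 4.2)

helix_beads <- function(n, base, name, wobble = 0.5) {
  radius <- 9.4
  rise <- 2.8
  twist <- 32.7 * pi / 180
  i <- seq_len(n) - 1L
  theta <- i * twist
  z <- i * rise
  ring <- function(rad, dth, dz)
    cbind(rad * cos(theta + dth), rad * sin(theta + dth), z + dz)
  r <- ring(radius, 0, 0)
  p <- ring(radius + 1.6, -0.30, 1.4)
  reach <- radius - unname(BASE_REACH[base])
  b <- cbind(reach * cos(theta + 0.20), reach * sin(theta + 0.20), z + 0.2)
  # deterministic per-residue distortion: a mathematically perfect helix is
  # invariant under register shifts, so the identity self-correspondence
  # would not be identifiable by RMSD — real molecules are never that regular
  r <- r + matrix(rnorm(3L * n, sd = wobble), n, 3L)
  p <- p + matrix(rnorm(3L * n, sd = wobble), n, 3L)
  b <- b + matrix(rnorm(3L * n, sd = wobble), n, 3L)
  p[1L, ] <- NA_real_ # 5' terminus has no phosphate
  coarse_structure(r_bead = r, b_bead = b, p_bead = p, base = base,
                   name = name)
}

coil_beads <- function(n, base, name) {
  step <- 6
  min_sep <- 3
  r <- matrix(0, n, 3L)
  for (i in 2:n) {
    repeat {
      dir <- rnorm(3L)
      cand <- r[i - 1L, ] + step * dir / sqrt(sum(dir^2))
      d <- sqrt(rowSums((r[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 3L, byrow = TRUE))^2))
      if (all(d >= min_sep)) break
    }
    r[i, ] <- cand
  }
  u <- matrix(rnorm(3L * n), n, 3L)
  u <- u / sqrt(rowSums(u^2))
  b <- r + 4.0 * u
  p <- (r + rbind(r[1L, ], r[-n, , drop = FALSE])) / 2 + 1.0
  p[1L, ] <- NA_real_
  coarse_structure(r_bead = r, b_bead = b, p_bead = p, base = base,
                   name = name)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle rotation angle in radians.
#' @return A 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Perturb a structure into a test fixture
#'
#' Applies, in order: a rigid transform, isotropic Gaussian bead noise,
#' teleportation of chosen outlier residues, and optional embedding of the
#' first `embed$motif_length` residues among random-coil decoys in shuffled
#' order. The ground-truth correspondence (target index, perturbed index) is
#' attached as attribute `ground_truth` for recovery scoring.
#'
#' @param structure a [coarse_structure].
#' @param rigid optional list with `axis`, `angle` (radians) and
#'   `translation` (length-3, angstrom).
#' @param noise_sigma standard deviation of the isotropic Gaussian noise
#'   added to every bead coordinate (angstrom, >= 0).
#' @param outliers optional two-column matrix or data frame of (residue
#'   index, displacement in angstrom); each listed residue is moved rigidly
#'   by that distance in a random direction.
#' @param embed optional list with `motif_length` and `decoy_count`: keeps
#'   the first `motif_length` residues, appends `decoy_count` random-coil
#'   decoys, and shuffles the residue order.
#' @param seed integer seed making the perturbation reproducible.
#' @return A [coarse_structure] with attribute `ground_truth`.
#' @export
perturb <- function(structure, rigid = NULL, noise_sigma = 0,
                    outliers = NULL, embed = NULL, seed = 1L) {
  stopifnot(is_coarse_structure(structure), noise_sigma >= 0)
  s <- structure
  with_seed(seed, {
    if (!is.null(rigid)) {
      R <- rotation_about_axis(rigid$axis, rigid$angle)
      s <- transform_structure(s, R, rigid$translation)
    }
    if (noise_sigma > 0) {
      s$p[s$p_present, ] <- s$p[s$p_present, , drop = FALSE] +
        matrix(rnorm(3L * sum(s$p_present), sd = noise_sigma),
               sum(s$p_present), 3L)
      s$r <- s$r + matrix(rnorm(3L * s$n, sd = noise_sigma), s$n, 3L)
      s$b <- s$b + matrix(rnorm(3L * s$n, sd = noise_sigma), s$n, 3L)
    }
    if (!is.null(outliers)) {
      outliers <- as.matrix(outliers)
      if (any(outliers[, 1L] < 1L) || any(outliers[, 1L] > s$n))
        stop("outlier residue index out of range")
      for (q in seq_len(nrow(outliers))) {
        i <- outliers[q, 1L]
        dir <- rnorm(3L)
        shift <- outliers[q, 2L] * dir / sqrt(sum(dir^2))
        if (s$p_present[i]) s$p[i, ] <- s$p[i, ] + shift
        s$r[i, ] <- s$r[i, ] + shift
        s$b[i, ] <- s$b[i, ] + shift
      }
    }
    gt <- cbind(target = seq_len(s$n), model = seq_len(s$n))
    if (!is.null(embed)) {
      k <- embed$motif_length
      if (k > s$n) stop("motif_length exceeds structure size")
      decoys <- coil_beads(max(3L, embed$decoy_count),
                           rep_len(c("A", "C", "G", "U"), max(3L, embed$decoy_count)),
                           "decoys")
      decoys <- transform_structure(decoys, diag(3L),
                                    apply(s$r, 2L, max) + c(15, 15, 15))
      keep <- seq_len(k)
      total <- k + embed$decoy_count
      ord <- sample.int(total)
      pos <- order(ord) # new position of each concatenated residue
      comb <- concat_structures(subset_structure(s, keep),
                                subset_structure(decoys,
                                                 seq_len(embed$decoy_count)),
                                name = paste0(s$name, "_embedded"))
      s <- subset_structure(comb, ord)
      gt <- cbind(target = keep, model = pos[keep])
    }
    attr(s, "ground_truth") <- gt
    s
  })
}

subset_structure <- function(s, idx) {
  coarse_structure(r_bead = s$r[idx, , drop = FALSE],
                   b_bead = s$b[idx, , drop = FALSE],
                   p_bead = ifelse(matrix(s$p_present[idx], length(idx), 3L),
                                   s$p[idx, , drop = FALSE], NA_real_),
                   base = s$base[idx],
                   residue_id = s$residue_id[idx, , drop = FALSE],
                   name = s$name)
}

concat_structures <- function(a, b, name = "concat") {
  pa <- a$p; pa[!a$p_present, ] <- NA_real_
  pb <- b$p; pb[!b$p_present, ] <- NA_real_
  rid <- rbind(a$residue_id, b$residue_id)
  rid$number <- seq_len(nrow(rid))
  coarse_structure(r_bead = rbind(a$r, b$r), b_bead = rbind(a$b, b$b),
                   p_bead = rbind(pa, pb), base = c(a$base, b$base),
                   residue_id = rid, name = name)
}

#' Fraction of ground-truth pairs recovered by an alignment
#'
#' @param alignment an `rna_alignment` (or a two-column pair matrix).
#' @param ground_truth the `ground_truth` attribute produced by [perturb()].
#' @return Fraction in \[0, 1\] of ground-truth pairs present in the
#'   alignment.
#' @export
recovery_score <- function(alignment, ground_truth) {
  pairs <- if (inherits(alignment, "rna_alignment")) alignment$pairs
           else as_pair_matrix(alignment)
  gt <- as.matrix(ground_truth)
  if (nrow(gt) == 0L) stop("empty ground truth")
  have <- paste(pairs[, 1L], pairs[, 2L])
  want <- paste(gt[, 1L], gt[, 2L])
  mean(want %in% have)
}

#' Expand a coarse-grained structure to a synthetic full-atom structure
#'
#' Produces a minimal atom set per residue (three atoms per bead group,
#' placed symmetrically around each bead so their geometric center recovers
#' the bead exactly). Used to exercise the PDB/mmCIF readers and the
#' coarse-graining end to end without real depositions; the atoms are
#' synthetic, not stereochemically realistic.
#'
#' @param structure a [coarse_structure].
#' @param id structure identifier for the output.
#' @return A `raw_structure` suitable for [write_structure()].
#' @export
expand_to_atoms <- function(structure, id = structure$name) {
  stopifnot(is_coarse_structure(structure))
  rows <- list()
  resname <- c(A = "A", C = "C", G = "G", U = "U", T = "DT", N = "N")
  for (i in seq_len(structure$n)) {
    base <- structure$base[i]
    n1 <- if (base %in% c("C", "U", "T")) "N1" else "N9"
    at <- list()
    if (structure$p_present[i]) {
      p <- structure$p[i, ]
      at <- c(at, list(c("P", "P", p), c("OP1", "O", p + c(0.8, 0, 0)),
                       c("OP2", "O", p - c(0.8, 0, 0))))
    }
    r <- structure$r[i, ]
    b <- structure$b[i, ]
    at <- c(at, list(c("C1'", "C", r + c(0, 0.7, 0)),
                     c("C4'", "C", r - c(0, 0.7, 0)),
                     c("O4'", "O", r),
                     c(n1, "N", b),
                     c("C2", "C", b + c(0, 0, 0.6)),
                     c("C6", "C", b - c(0, 0, 0.6))))
    for (a in at) {
      rows[[length(rows) + 1L]] <- data.frame(
        atom_name = a[1L], element = a[2L],
        x = as.numeric(a[3L]), y = as.numeric(a[4L]), z = as.numeric(a[5L]),
        residue_name = unname(resname[base]),
        residue_number = structure$residue_id$number[i],
        icode = structure$residue_id$icode[i],
        chain = structure$residue_id$chain[i],
        altloc = "", occupancy = 1.0,
        stringsAsFactors = FALSE)
    }
  }
  new_raw_structure(do.call(rbind, rows), format = "pdb", id = id)
}
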