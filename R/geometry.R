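#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via SVD of the covariance matrix with determinant
#' correction so that reflections are excluded.
#'
#' @param fixed k x 3 matrix of reference coordinates (angstrom).
#' @param moving k x 3 matrix of coordinates to transform; row i corresponds
#'   to row i of `fixed`.
#' @return A list with components `rotation` (3 x 3, det +1), `translation`
#'   (length-3 vector) and `rmsd` (angstrom). Transformed coordinates are
#'   `moving %*% t(rotation) + translation` (rows).
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' superpose(x, x)$rmsd
#' @export
superpose <- function(fixed, moving) {
  fixed <- as_coord_matrix(fixed)
  moving <- as_coord_matrix(moving)
  if (nrow(fixed) == 0L) stop("superpose: empty input")
  if (nrow(fixed) != nrow(moving))
    stop("superpose: 'fixed' and 'moving' must have the same number of rows")
  fit <- cpp_kabsch(fixed, moving)
  fit$translation <- as.numeric(fit$translation)
  fit
}

#' Fixed-frame RMSD (no superposition)
#'
#' Root mean square of the row-wise Euclidean distances between two coordinate
#' sets, in the frame they are given in.
#'
#' @inheritParams superpose
#' @param a,b k x 3 coordinate matrices of equal shape.
#' @return RMSD in angstrom.
#' @export
rmsd_fixed <- function(a, b) {
  a <- as_coord_matrix(a)
  b <- as_coord_matrix(b)
  if (!all(dim(a) == dim(b))) stop("rmsd_fixed: shape mismatch")
  if (nrow(a) == 0L) stop("rmsd_fixed: empty input")
  cpp_rmsd_rows(a, b)
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  if (any(!is.finite(x))) stop("coordinates must be finite")
  x
}

#' Actual RMSD of an alignment
#'
#' The optimal-superposition RMSD over the beads of all aligned residue pairs.
#' For each pair only beads present in both residues enter (the phosphate bead
#' may be absent on 5'-terminal residues); the ribose and base beads always
#' do. This single definition is the "actual RMSD" used everywhere: by GEOS,
#' by GENS fitness, by the oracle, and in all reports.
#'
#' @param target,model [coarse_structure] objects.
#' @param pairs two-column integer matrix of (target index, model index)
#'   residue pairs, 1-based, injective in both columns.
#' @return A list with `rotation`, `translation`, `rmsd` and `pair_dist`, the
#'   mean bead distance of each pair after the fit.
#' @seealso [superpose()], [oracle_align()]
#' @export
alignment_rmsd <- function(target, model, pairs) {
  stopifnot(is_coarse_structure(target), is_coarse_structure(model))
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0L) stop("alignment_rmsd: empty pair list")
  if (anyDuplicated(pairs[, 1L]) || anyDuplicated(pairs[, 2L]))
    stop("invalid alignment: duplicate target or model residue in pair list")
  if (any(pairs[, 1L] < 1L) || any(pairs[, 1L] > target$n) ||
      any(pairs[, 2L] < 1L) || any(pairs[, 2L] > model$n))
    stop("alignment_rmsd: residue index out of range")
  fit <- cpp_alignment_fit(target$p, target$r, target$b, target$p_present,
                           model$p, model$r, model$b, model$p_present,
                           pairs[, 1L], pairs[, 2L])
  fit$translation <- as.numeric(fit$translation)
  fit
}

as_pair_matrix <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) pairs <- matrix(integer(), 0L, 2L)
  if (ncol(pairs) != 2L) stop("pairs must be a two-column (target, model) matrix")
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(NULL, c("target", "model"))
  pairs
}

# Apply a rigid transform to an n x 3 coordinate matrix (rows).
apply_transform <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2L, translation, "+")
}
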