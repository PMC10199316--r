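# 3-bead coarse-grained model: each nucleotide reduced to the geometric
# centers of its phosphate, ribose, and base atom groups.

PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")
RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'",
                  "O2'", "O3'", "O4'", "O5'")

#' Construct a coarse-grained structure from bead coordinates
#'
#' Container used by every alignment operation. Residues are held in chain
#' order (5' to 3', chains concatenated in file order) and indexed 1..n.
#'
#' @param r_bead,b_bead n x 3 matrices of ribose and base bead coordinates
#'   (angstrom); always present.
#' @param p_bead n x 3 matrix of phosphate bead coordinates; rows may be `NA`
#'   for residues lacking a phosphate (5'-terminal residues).
#' @param base character vector of one-letter base identities
#'   (A, C, G, U, T or N).
#' @param residue_id optional data frame with columns `chain`, `number`,
#'   `icode` identifying each residue in the source file.
#' @param name structure identifier.
#' @return An object of class `coarse_structure` with fields `n`, `base`,
#'   `p`, `r`, `b`, `p_present`, `residue_id`, `name`.
#' @export
coarse_structure <- function(r_bead, b_bead, p_bead = NULL, base = NULL,
                             residue_id = NULL, name = "structure") {
  r_bead <- as_coord_matrix_na(r_bead)
  b_bead <- as_coord_matrix_na(b_bead)
  n <- nrow(r_bead)
  if (n < 1L) stop("empty structure: no residues")
  if (nrow(b_bead) != n) stop("r_bead and b_bead row counts differ")
  if (any(is.na(r_bead)) || any(is.na(b_bead)))
    stop("ribose and base beads must be present for every residue")
  if (is.null(p_bead)) p_bead <- matrix(NA_real_, n, 3L)
  p_bead <- as_coord_matrix_na(p_bead)
  if (nrow(p_bead) != n) stop("p_bead row count differs")
  p_present <- stats::complete.cases(p_bead)
  p_bead[!p_present, ] <- 0 # never read where absent
  if (is.null(base)) base <- rep("N", n)
  base <- toupper(as.character(base))
  base[!base %in% c("A", "C", "G", "U", "T")] <- "N"
  if (is.null(residue_id))
    residue_id <- data.frame(chain = "A", number = seq_len(n), icode = "",
                             stringsAsFactors = FALSE)
  structure(list(name = name, n = n, base = base,
                 p = p_bead, r = r_bead, b = b_bead,
                 p_present = p_present, residue_id = residue_id),
            class = "coarse_structure")
}

as_coord_matrix_na <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  bad <- is.infinite(x) | is.nan(x)
  if (any(bad)) stop("coordinates must be finite")
  x
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat(sprintf("<coarse_structure '%s': %d residues, %d with phosphate bead>\n",
              x$name, x$n, sum(x$p_present)))
  cat(" bases:", paste(head(x$base, 40L), collapse = ""),
      if (x$n > 40L) "..." else "", "\n")
  invisible(x)
}

is_coarse_structure <- function(x) inherits(x, "coarse_structure")

#' Reduce a parsed structure to the 3-bead coarse-grained model
#'
#' Each nucleotide becomes three pseudoatoms placed at the unweighted
#' geometric center of its phosphate group (P, OP1, OP2, OP3), its ribose
#' group (C1'-C5', O2'-O5') and its base (all remaining heavy atoms).
#' Hydrogens never enter a bead. A residue with no phosphate atoms (typically
#' the 5' terminus) keeps only its ribose and base beads; a residue with no
#' base atoms is dropped with a warning.
#'
#' @param structure a `raw_structure` from [parse_structure()].
#' @return A [coarse_structure].
#' @export
coarse_grain <- function(structure) {
  stopifnot(inherits(structure, "raw_structure"))
  at <- structure$atoms
  if (nrow(at) == 0L) stop("empty structure: no atoms")
  at <- at[!is_hydrogen(at$atom_name, at$element), , drop = FALSE]
  key <- residue_key(at)
  keys <- unique(key) # file order
  n <- length(keys)
  p <- matrix(NA_real_, n, 3L)
  r <- matrix(NA_real_, n, 3L)
  b <- matrix(NA_real_, n, 3L)
  base <- character(n)
  rid <- data.frame(chain = character(n), number = integer(n),
                    icode = character(n), stringsAsFactors = FALSE)
  keep <- logical(n)
  for (i in seq_len(n)) {
    res <- at[key == keys[i], , drop = FALSE]
    nm <- normalize_atom_name(res$atom_name)
    xyz <- cbind(res$x, res$y, res$z)
    in_p <- nm %in% PHOSPHATE_ATOMS
    in_r <- nm %in% RIBOSE_ATOMS
    in_b <- !in_p & !in_r
    if (any(in_p)) p[i, ] <- colMeans(xyz[in_p, , drop = FALSE])
    if (any(in_r)) r[i, ] <- colMeans(xyz[in_r, , drop = FALSE])
    if (any(in_b)) b[i, ] <- colMeans(xyz[in_b, , drop = FALSE])
    base[i] <- base_letter(res$residue_name[1L])
    rid$chain[i] <- res$chain[1L]
    rid$number[i] <- res$residue_number[1L]
    rid$icode[i] <- res$icode[1L]
    keep[i] <- any(in_r) && any(in_b)
    if (!keep[i])
      warning(sprintf("dropping residue %s%s%s: missing %s atoms",
                      rid$chain[i], rid$number[i], rid$icode[i],
                      if (any(in_r)) "base" else "ribose"),
              call. = FALSE)
  }
  if (!any(keep)) stop("empty structure: no residue has both ribose and base atoms")
  coarse_structure(r_bead = r[keep, , drop = FALSE],
                   b_bead = b[keep, , drop = FALSE],
                   p_bead = p[keep, , drop = FALSE],
                   base = base[keep], residue_id = rid[keep, , drop = FALSE],
                   name = structure$id)
}

# old-style PDB primes written as '*' (e.g. C1*)
normalize_atom_name <- function(nm) gsub("*", "'", toupper(trimws(nm)), fixed = TRUE)

is_hydrogen <- function(atom_name, element = NULL) {
  el <- toupper(trimws(if (is.null(element)) "" else element))
  nm <- toupper(trimws(atom_name))
  el == "H" | el == "D" | (el == "" & grepl("^[0-9]*[HD]", nm))
}

BASE_LETTERS <- c(A = "A", C = "C", G = "G", U = "U", T = "T",
                  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
                  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U",
                  THY = "T", I = "N", DI = "N",
                  # common modified residues mapped to the parent base
                  `1MA` = "A", `2MA` = "A", `6MA` = "A", `M2G` = "G",
                  `1MG` = "G", `2MG` = "G", `7MG` = "G", OMG = "G",
                  `5MC` = "C", OMC = "C", `4SU` = "U", PSU = "U",
                  `5MU` = "T", H2U = "U", DHU = "U")

base_letter <- function(residue_name) {
  r <- toupper(trimws(residue_name))
  out <- unname(BASE_LETTERS[r])
  if (is.na(out)) "N" else out
}

#' Bead coordinate matrix for selected residues
#'
#' Stacks the beads of the selected residues into one matrix, in the fixed
#' order phosphate (when present), ribose, base within each residue, residues
#' in the order given. All RMSD computations in the package are defined over
#' matrices of this layout.
#'
#' @param structure a [coarse_structure].
#' @param selection integer vector of residue indices (1-based, distinct).
#' @return A k x 3 numeric matrix (0 x 3 for an empty selection).
#' @export
bead_matrix <- function(structure, selection) {
  stopifnot(is_coarse_structure(structure))
  selection <- as.integer(selection)
  if (anyDuplicated(selection)) stop("selection indices must be distinct")
  if (length(selection) == 0L) return(matrix(numeric(), 0L, 3L))
  if (any(selection < 1L) || any(selection > structure$n))
    stop("selection index out of range")
  rows <- lapply(selection, function(i) {
    m <- rbind(if (structure$p_present[i]) structure$p[i, ],
               structure$r[i, ], structure$b[i, ])
    m
  })
  do.call(rbind, rows)
}

# Rigidly transform every bead of a coarse structure.
transform_structure <- function(structure, rotation, translation) {
  structure$p[structure$p_present, ] <-
    apply_transform(structure$p[structure$p_present, , drop = FALSE],
                    rotation, translation)
  structure$r <- apply_transform(structure$r, rotation, translation)
  structure$b <- apply_transform(structure$b, rotation, translation)
  structure
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$residue_number, atoms$icode, sep = "\r")
}
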