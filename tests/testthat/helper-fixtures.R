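# Shared fixtures and independent oracles used across the test files.

# A toy instance: target and model are subsets of one random coil, the model
# rigidly moved and noised, so a non-trivial common substructure exists.
toy_instance <- function(q, nmax = 6, noise = 0.15) {
  set.seed(q)
  n <- sample(4:nmax, 1L)
  m <- sample(4:nmax, 1L)
  base <- make_structure(max(n, m), "random_coil", seed = q)
  target <- flexalign:::subset_structure(base, seq_len(n))
  model <- flexalign:::subset_structure(
    perturb(base,
            rigid = list(axis = rnorm(3L), angle = runif(1L, 0, pi),
                         translation = rnorm(3L, 0, 8)),
            noise_sigma = noise, seed = q + 999L),
    seq_len(m))
  list(target = target, model = model, n = n, m = m)
}

# Two 20-residue fragments that each superpose exactly, but under different
# rigid transforms, so no joint alignment below a few angstrom exists.
two_fragment_fixture <- function(seed = 7) {
  target <- make_structure(40, "helix", seed = seed)
  model <- target
  R2 <- rotation_about_axis(c(0, 1, 0), 1.2)
  shift <- c(25, -10, 5)
  idx <- 21:40
  for (f in c("p", "r", "b"))
    model[[f]][idx, ] <- sweep(model[[f]][idx, ] %*% t(R2), 2L, shift, "+")
  list(target = target, model = model)
}

# Independent admissibility checker (kept separate from the package code on
# purpose: plain vector arithmetic, no shared helpers).
check_admissible <- function(v, m, corr = NULL) {
  if (any(v < 0) || any(v > m)) return(FALSE)
  nz <- v[v != 0]
  if (any(duplicated(nz))) return(FALSE)
  if (length(nz) >= 2 && !all(diff(nz) > 0)) return(FALSE)
  if (!is.null(corr)) {
    at <- which(v != 0)
    if (length(at) > 0 && (any(is.na(corr[at])) || !all(v[at] == corr[at])))
      return(FALSE)
  }
  TRUE
}

# Brute-force superposition oracle: minimize RMSD over a ZYZ Euler-angle
# grid with iterative refinement; translation handled by centroiding.
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3L, 3L)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3L, 3L)
  rz(a) %*% ry(b) %*% rz(g)
}

grid_superpose_rmsd <- function(fixed, moving, iters = 16L) {
  X <- sweep(fixed, 2L, colMeans(fixed))
  Y <- sweep(moving, 2L, colMeans(moving))
  k <- nrow(X)
  evalr <- function(a, b, g) {
    Yt <- Y %*% t(euler_rotation(a, b, g))
    sqrt(sum((Yt - X)^2) / k)
  }
  best <- c(0, 0, 0)
  best_r <- evalr(0, 0, 0)
  step <- pi / 9 # 20 degrees
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step, by = step)) {
        r <- evalr(a, b, g)
        if (r < best_r) { best_r <- r; best <- c(a, b, g) }
      }
  for (it in seq_len(iters)) {
    repeat { # full local descent at this resolution before refining
      moved <- FALSE
      for (da in c(-1, 0, 1)) for (db in c(-1, 0, 1)) for (dg in c(-1, 0, 1)) {
        cand <- best + step * c(da, db, dg)
        r <- evalr(cand[1L], cand[2L], cand[3L])
        if (r < best_r - 1e-15) { best_r <- r; best <- cand; moved <- TRUE }
      }
      if (!moved) break
    }
    step <- step / 2
  }
  best_r
}

# Small hand-rolled PDB text fixture: three RNA residues (plus optional extra
# records), fixed-column format.
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = "", icode = "", element = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resno, icode, x, y, z, occ, 0, element)
}

three_residue_pdb <- function(path) {
  lines <- character(0)
  serial <- 0L
  for (i in 1:3) {
    for (at in list(c("P", "P"), c("C1'", "C"), c("O4'", "O"), c("N9", "N"))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, at[1L], "A", "A", i,
                                      i * 10 + serial * 0.25, i * 2, 1.5,
                                      element = at[2L]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
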