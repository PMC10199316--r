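# PDB/mmCIF reading, format policies, and alignment output files.

test_that("a hand-written PDB fixture reads back in file order", {
  suppressWarnings({
    path <- three_residue_pdb(tempfile(fileext = ".pdb"))
    s <- parse_structure(path)
    key <- unique(flexalign:::residue_key(s$atoms))
    expect_length(key, 3L)
    expect_equal(unique(s$atoms$residue_number), 1:3)
    expect_equal(s$format, "pdb")
  })
})

test_that("PDB and mmCIF serializations parse identically", {
  suppressWarnings({
    s <- make_structure(8, "helix", seed = 21)
    raw <- expand_to_atoms(s)
    pp <- tempfile(fileext = ".pdb")
    cp <- tempfile(fileext = ".cif")
    write_structure(raw, pp, "pdb")
    write_structure(raw, cp, "mmcif")
    a <- parse_structure(pp)
    b <- parse_structure(cp)
    expect_equal(nrow(a$atoms), nrow(b$atoms))
    expect_equal(a$atoms$atom_name, b$atoms$atom_name)
    expect_equal(a$atoms$residue_number, b$atoms$residue_number)
    expect_equal(a$atoms[, c("x", "y", "z")], b$atoms[, c("x", "y", "z")],
                 tolerance = 1e-9)
    # format auto-detection by content
    sniff <- tempfile()
    file.copy(cp, sniff)
    expect_equal(parse_structure(sniff)$format, "mmcif")
  })
})

test_that("round trip preserves residues and coordinates to PDB precision", {
  suppressWarnings({
    s <- make_structure(10, "random_coil", seed = 3)
    raw <- expand_to_atoms(s)
    p1 <- tempfile(fileext = ".pdb")
    write_structure(raw, p1)
    r1 <- parse_structure(p1)
    p2 <- tempfile(fileext = ".pdb")
    write_structure(r1, p2)
    r2 <- parse_structure(p2)
    expect_equal(nrow(r1$atoms), nrow(raw$atoms))
    expect_equal(r1$atoms$residue_number, raw$atoms$residue_number)
    expect_equal(as.matrix(r2$atoms[, c("x", "y", "z")]),
                 as.matrix(r1$atoms[, c("x", "y", "z")]), tolerance = 1e-3,
                 ignore_attr = TRUE)
  })
})

test_that("water and other non-nucleotides are excluded", {
  suppressWarnings({
    path <- three_residue_pdb(tempfile(fileext = ".pdb"))
    lines <- readLines(path)
    extra <- c(
      "HETATM  900  O   HOH A 900      11.000  12.000  13.000  1.00  0.00           O",
      "HETATM  901 MG    MG A 901       1.000   2.000   3.000  1.00  0.00          MG",
      "ATOM    902  CA  ALA A 902       0.000   0.000   0.000  1.00  0.00           C")
    writeLines(c(head(lines, -1), extra, "END"), path)
    s <- parse_structure(path)
    expect_equal(sort(unique(s$atoms$residue_name)), "A")
    expect_length(unique(flexalign:::residue_key(s$atoms)), 3L)
  })
})

test_that("alt-locs resolve to highest occupancy, ties alphabetically", {
  suppressWarnings({
    lines <- c(
      pdb_atom_line(1, "C1'", "A", "A", 1, 1, 1, 1),
      pdb_atom_line(2, "O4'", "A", "A", 1, 2, 1, 1),
      pdb_atom_line(3, "N9", "A", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
      pdb_atom_line(4, "N9", "A", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
      # tie on occupancy: alphabetically first code wins
      pdb_atom_line(5, "C2", "A", "A", 1, 5, 5, 5, occ = 0.5, alt = "B"),
      pdb_atom_line(6, "C2", "A", "A", 1, 7, 7, 7, occ = 0.5, alt = "A"),
      "END")
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    s <- parse_structure(path)
    n9 <- s$atoms[s$atoms$atom_name == "N9", ]
    expect_equal(nrow(n9), 1L)
    expect_equal(n9$x, 9) # occupancy 0.6 wins
    c2 <- s$atoms[s$atoms$atom_name == "C2", ]
    expect_equal(c2$x, 7) # alt A wins the tie
  })
})

test_that("multi-model files yield the first model only", {
  suppressWarnings({
    body1 <- c(pdb_atom_line(1, "C1'", "A", "A", 1, 1, 1, 1),
               pdb_atom_line(2, "O4'", "A", "A", 1, 2, 1, 1),
               pdb_atom_line(3, "N9", "A", "A", 1, 3, 1, 1))
    body2 <- c(pdb_atom_line(1, "C1'", "A", "A", 1, 51, 1, 1),
               pdb_atom_line(2, "O4'", "A", "A", 1, 52, 1, 1),
               pdb_atom_line(3, "N9", "A", "A", 1, 53, 1, 1))
    path <- tempfile(fileext = ".pdb")
    writeLines(c("MODEL     1", body1, "ENDMDL", "MODEL     2", body2,
                 "ENDMDL", "END"), path)
    s <- parse_structure(path)
    expect_equal(nrow(s$atoms), 3L)
    expect_equal(s$atoms$x, c(1, 2, 3))
  })
})

test_that("parse errors are informative", {
  expect_error(parse_structure(tempfile()), "not found")
  suppressWarnings({
    empty <- tempfile(fileext = ".pdb")
    writeLines(c(
      "HETATM  900  O   HOH A 900      11.000  12.000  13.000  1.00  0.00           O",
      "END"), empty)
    expect_error(parse_structure(empty), "no nucleotide")
  })
})

test_that("write_alignment_output writes transform, pair table and summary", {
  suppressWarnings({
    s <- make_structure(6, "helix", seed = 31)
    raw <- expand_to_atoms(s)
    cs <- coarse_grain(raw)
    out <- file.path(tempfile(), "res")

    # identity alignment: written model equals input to PDB precision,
    # in-memory transform is identity to 1e-6
    ali <- new_alignment(cs, cs, cbind(1:6, 1:6), "seq_indep", "oracle")
    expect_equal(ali$rotation, diag(3), tolerance = 1e-6)
    expect_equal(ali$translation, rep(0, 3), tolerance = 1e-6)
    paths <- write_alignment_output(ali, raw, raw, out)
    moved <- parse_structure(paths[["model"]])
    expect_equal(as.matrix(moved$atoms[, c("x", "y", "z")]),
                 as.matrix(raw$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    tab <- read.delim(paths[["pairs"]])
    expect_equal(nrow(tab), 6L)
    expect_true(all(tab$distance < 1e-3))
    expect_match(readLines(paths[["summary"]])[3], "0.0000")

    # 3-pair alignment: table distances match recomputed Euclidean means
    m <- perturb(s, rigid = list(axis = c(1, 0, 2), angle = 0.9,
                                 translation = c(6, -2, 3)),
                 noise_sigma = 0.1, seed = 5)
    rawm <- expand_to_atoms(m)
    ali3 <- new_alignment(cs, coarse_grain(rawm), cbind(c(1, 3, 5), c(1, 3, 5)),
                          "seq_indep", "oracle")
    paths3 <- write_alignment_output(ali3, raw, rawm, file.path(out, "b"))
    tab3 <- read.delim(paths3[["pairs"]])
    cm <- coarse_grain(rawm)
    for (k in 1:3) {
      ti <- c(1, 3, 5)[k]
      tb <- bead_matrix(cs, ti)
      mb <- bead_matrix(cm, ti)
      mb <- sweep(mb %*% t(ali3$rotation), 2L, ali3$translation, "+")
      d <- mean(sqrt(rowSums((tb - mb)^2)))
      expect_equal(tab3$distance[k], d, tolerance = 1e-3)
    }

    # empty alignment: zero-row table, undefined RMSD
    ali0 <- new_alignment(cs, cs, matrix(integer(), 0, 2), "seq_indep",
                          "oracle")
    paths0 <- write_alignment_output(ali0, raw, raw, file.path(out, "c"))
    expect_equal(nrow(read.delim(paths0[["pairs"]])), 0L)
    expect_match(paste(readLines(paths0[["summary"]]), collapse = " "),
                 "undefined")
  })
})
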