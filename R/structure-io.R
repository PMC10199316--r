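# Reading nucleic-acid structures from PDB/mmCIF and writing alignment
# results.  Parsing is delegated to bio3d (read.pdb / read.cif); this module
# adds nucleotide filtering, alt-loc and first-model policies, and writers.

NUCLEOTIDE_WHITELIST <- c("A", "C", "G", "U", "T",
                          "DA", "DC", "DG", "DT", "DU", "I", "DI")

new_raw_structure <- function(atoms, format, id) {
  needed <- c("atom_name", "element", "x", "y", "z", "residue_name",
              "residue_number", "icode", "chain", "altloc", "occupancy")
  stopifnot(all(needed %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  structure(list(atoms = atoms, format = format, id = id),
            class = "raw_structure")
}

#' @export
print.raw_structure <- function(x, ...) {
  nres <- length(unique(residue_key(x$atoms)))
  cat(sprintf("<raw_structure '%s' [%s]: %d atoms, %d residues>\n",
              x$id, x$format, nrow(x$atoms), nres))
  invisible(x)
}

#' Parse a nucleic-acid structure from a PDB or mmCIF file
#'
#' Reads all nucleotide residues of the first model, in file order (5' to 3'
#' within each chain, chains concatenated in file order). Non-nucleotide
#' residues — water, ions, amino acids, ligands — are excluded; a residue
#' counts as a nucleotide when its name is on the standard whitelist
#' (A, C, G, U, T, DA, DC, DG, DT, ...) or when it carries the ribose/base
#' marker atoms C1', O4' and N9 or N1 (so modified nucleotides pass).
#' Alternate locations are resolved to the highest occupancy, ties to the
#' alphabetically first alt-loc code.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect from the extension,
#'   falling back to content sniffing).
#' @return A `raw_structure` (atom table plus format tag and identifier).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") format <- detect_format(path)
  atoms <- tryCatch(
    if (format == "pdb") read_pdb_atoms(path) else read_cif_atoms(path),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- first_model(atoms)
  atoms <- resolve_altloc(atoms)
  atoms <- keep_nucleotides(atoms)
  if (nrow(atoms) == 0L)
    stop("empty structure: no nucleotide residues in ", path)
  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  new_raw_structure(atoms, format, id)
}

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_|_atom_site\\.", head_lines))) "mmcif" else "pdb"
}

strip_quotes <- function(x) {
  x <- sub("^\"(.*)\"$", "\\1", x)
  sub("^'(.*)'$", "\\1", x)
}

bio3d_to_atoms <- function(atom) {
  data.frame(atom_name = strip_quotes(trimws(atom$elety)),
             element = trimws(ifelse(is.na(atom$elesy), "", atom$elesy)),
             x = atom$x, y = atom$y, z = atom$z,
             residue_name = trimws(atom$resid),
             residue_number = atom$resno,
             icode = ifelse(is.na(atom$insert), "", trimws(atom$insert)),
             chain = ifelse(is.na(atom$chain), "", trimws(atom$chain)),
             altloc = ifelse(is.na(atom$alt), "", trimws(atom$alt)),
             occupancy = ifelse(is.na(atom$o), 1, atom$o),
             stringsAsFactors = FALSE)
}

read_pdb_atoms <- function(path) {
  # keep only the first model: truncate at the first ENDMDL record
  lines <- readLines(path, warn = FALSE)
  end <- grep("^ENDMDL", lines)
  if (length(end) > 0L) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(lines[seq_len(end[1L])], tmp)
    path <- tmp
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  bio3d_to_atoms(pdb$atom)
}

read_cif_atoms <- function(path) {
  cif <- bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
  bio3d_to_atoms(cif$atom)
}

# First-model policy for files where the reader returns several models:
# drop any atom repeating an already-seen (residue, atom, altloc) identity.
first_model <- function(atoms) {
  key <- paste(residue_key(atoms), atoms$atom_name, atoms$altloc)
  atoms[!duplicated(key), , drop = FALSE]
}

# Highest occupancy wins; ties go to the alphabetically first alt-loc code
# (the blank code sorts first).
resolve_altloc <- function(atoms) {
  key <- paste(residue_key(atoms), atoms$atom_name)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  # restore file order
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

keep_nucleotides <- function(atoms) {
  key <- residue_key(atoms)
  keep_res <- vapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                     function(idx) {
                       res <- atoms[idx, , drop = FALSE]
                       nm <- normalize_atom_name(res$atom_name)
                       toupper(res$residue_name[1L]) %in% NUCLEOTIDE_WHITELIST ||
                         (("C1'" %in% nm) && ("O4'" %in% nm) &&
                            any(c("N9", "N1") %in% nm))
                     }, logical(1))
  atoms[keep_res[match(key, unique(key))], , drop = FALSE]
}

#' Write a structure to a PDB or mmCIF file
#'
#' @param structure a `raw_structure`.
#' @param path output file path.
#' @param format `"pdb"`, `"mmcif"`, or `NULL` to reuse the structure's own
#'   format tag.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path, format = NULL) {
  stopifnot(inherits(structure, "raw_structure"))
  if (is.null(format)) format <- structure$format
  at <- structure$atoms
  if (format == "pdb") {
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(cbind(at$x, at$y, at$z))),
                     resno = at$residue_number,
                     resid = at$residue_name,
                     eleno = seq_len(nrow(at)),
                     elety = at$atom_name,
                     chain = ifelse(at$chain == "", " ", at$chain),
                     insert = ifelse(at$icode == "", "", at$icode),
                     alt = ifelse(at$altloc == "", "", at$altloc),
                     o = at$occupancy, b = rep(0, nrow(at)),
                     elesy = at$element)
  } else {
    write_mmcif(structure, path)
  }
  invisible(path)
}

# Minimal mmCIF writer: one atom_site loop in the canonical PDBx column
# order (readers commonly rely on it).
write_mmcif <- function(structure, path) {
  at <- structure$atoms
  dot <- function(x) ifelse(is.na(x) | x == "", ".", x)
  quo <- function(x) ifelse(grepl("'", x), sprintf("\"%s\"", x), x)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$id)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf(
      "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      seq_len(nrow(at)), dot(at$element), quo(at$atom_name),
      dot(at$altloc), at$residue_name, dot(at$chain),
      at$residue_number, dot(at$icode),
      at$x, at$y, at$z, at$occupancy, 0,
      at$residue_number, at$residue_name, dot(at$chain), quo(at$atom_name)),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Write the result files of an alignment
#'
#' Writes three files to `out_dir`: the model coordinates after applying the
#' alignment's rigid transform (`model_aligned.pdb` or `.cif`, matching the
#' input model's format); a tab-separated pair table (`pairs.tsv`) with one
#' row per aligned pair — target and model residue identifiers, base
#' identities, and the mean pseudoatom distance of the pair in angstrom; and
#' a summary block (`summary.txt`) with the aligned residue count, target
#' coverage, and actual RMSD (reported as "undefined" for an empty
#' alignment, for which the model is written untransformed).
#'
#' @param alignment an `rna_alignment`.
#' @param target,model `raw_structure` objects the alignment refers to.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_alignment_output <- function(alignment, target, model, out_dir = ".") {
  stopifnot(inherits(alignment, "rna_alignment"),
            inherits(target, "raw_structure"),
            inherits(model, "raw_structure"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  ct <- coarse_grain(target)
  cm <- coarse_grain(model)
  if (alignment$n_pairs > 0L &&
      (max(alignment$pairs[, 1L]) > ct$n || max(alignment$pairs[, 2L]) > cm$n))
    stop("alignment refers to residues not present in target/model")

  # (a) transformed model coordinates
  moved <- model
  if (alignment$n_pairs > 0L) {
    xyz <- apply_transform(cbind(model$atoms$x, model$atoms$y, model$atoms$z),
                           alignment$rotation, alignment$translation)
    moved$atoms$x <- xyz[, 1L]
    moved$atoms$y <- xyz[, 2L]
    moved$atoms$z <- xyz[, 3L]
  }
  ext <- if (model$format == "pdb") "pdb" else "cif"
  model_path <- file.path(out_dir, paste0("model_aligned.", ext))
  write_structure(moved, model_path)

  # (b) pair table
  fmt_res <- function(cs, i)
    sprintf("%s:%d%s", cs$residue_id$chain[i], cs$residue_id$number[i],
            cs$residue_id$icode[i])
  pairs_path <- file.path(out_dir, "pairs.tsv")
  tab <- data.frame(
    target_residue = character(0), model_residue = character(0),
    target_base = character(0), model_base = character(0),
    distance = numeric(0), stringsAsFactors = FALSE)
  if (alignment$n_pairs > 0L) {
    ti <- alignment$pairs[, 1L]
    mi <- alignment$pairs[, 2L]
    tab <- data.frame(
      target_residue = fmt_res(ct, ti), model_residue = fmt_res(cm, mi),
      target_base = ct$base[ti], model_base = cm$base[mi],
      distance = round(alignment$pair_dist, 4L), stringsAsFactors = FALSE)
  }
  utils::write.table(tab, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # (c) summary
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(c(
    sprintf("aligned_residues: %d", alignment$n_pairs),
    sprintf("target_coverage_pct: %.2f", 100 * alignment$n_pairs / ct$n),
    sprintf("actual_rmsd: %s",
            if (is.na(alignment$rmsd)) "undefined"
            else sprintf("%.4f", alignment$rmsd))),
    summary_path)
  invisible(c(model = model_path, pairs = pairs_path, summary = summary_path))
}
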