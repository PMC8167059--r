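.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")
.nuc3 <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")
.water3 <- c("HOH", "WAT")
.nuc_backbone <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O3'", "O4'", "O5'", "P")

#' Classify a residue name into a scoring category
#'
#' The category decides which atoms enter the per-residue score: `protein`
#' for the 20 standard amino acids plus selenomethionine (MSE), `nucleic`
#' for the standard ribo- and deoxyribonucleotides, `water` for HOH/WAT, and
#' `ligand` for everything else (including metal ions such as ZN, which are
#' scored over all their atoms).
#'
#' @param residue_name character vector of 3-letter (or ligand) codes.
#' @return character vector: "protein", "nucleic", "water" or "ligand".
#' @export
classify_residue <- function(residue_name) {
  nm <- toupper(trimws(residue_name))
  out <- rep("ligand", length(nm))
  out[nm %in% .aa3] <- "protein"
  out[nm %in% .nuc3] <- "nucleic"
  out[nm %in% .water3] <- "water"
  out
}

# category with the modified-nucleotide fallback: a residue classified as
# ligand by name is treated as nucleic when its atom names cover at least 5
# of the 9 nucleic backbone atoms
.residue_category <- function(residue_name, atom_names) {
  cat <- classify_residue(residue_name[1L])
  if (cat == "ligand" &&
      sum(.nuc_backbone %in% atom_names) >= 5L) cat <- "nucleic"
  cat
}

.is_hydrogen <- function(elety, elesy) {
  sy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  nm <- toupper(trimws(elety))
  sy %in% c("H", "D") | (sy == "" & grepl("^[0-9]*[HD]", nm))
}

.res_key <- function(chain, resno, insert) {
  paste(chain, resno, insert, sep = "|")
}

.detect_model_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("cif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_|_atom_site\\.", head))) "cif" else "pdb"
}

#' Read an atomic model from PDB or mmCIF
#'
#' The format is auto-detected from the extension, then from the content.
#' Residue order within each chain is preserved from the file. Alternate
#' locations are collapsed to the highest-occupancy conformer (ties: first
#' in file). Hydrogens are retained but flagged (`is_h`) and never scored.
#'
#' @param path path to a .pdb/.ent or .cif/.mmcif file.
#' @return an object of class `atomic_model`: a list with `atoms` (one row
#'   per atom: chain, resno, insert, resid, elety, elesy, alt, x, y, z, occ,
#'   b, is_h, res_key) and `format` ("pdb" or "cif").
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- .detect_model_format(path)
  parsed <- if (fmt == "cif") suppressWarnings(bio3d::read.cif(path))
            else bio3d::read.pdb(path)
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model: ", path, call. = FALSE)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = toupper(trimws(a$resid)),
    elety = gsub("\\*", "'", trimws(a$elety)),   # C1* -> C1'
    elesy = ifelse(is.na(a$elesy), "", trimws(a$elesy)),
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE
  )
  if (!all(is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite atom coordinates in ", path, call. = FALSE)
  atoms$is_h <- .is_hydrogen(atoms$elety, atoms$elesy)
  atoms$res_key <- .res_key(atoms$chain, atoms$resno, atoms$insert)

  # collapse altlocs: keep the highest-occupancy conformer per atom name
  # within each residue (ties -> first in file)
  akey <- paste(atoms$res_key, atoms$elety)
  if (anyDuplicated(akey)) {
    keep <- rep(TRUE, nrow(atoms))
    for (g in split(seq_len(nrow(atoms)), akey)) {
      if (length(g) > 1L) {
        best <- g[which.max(atoms$occ[g])]
        keep[setdiff(g, best)] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  structure(list(atoms = atoms, format = fmt), class = "atomic_model")
}

#' Build an `atomic_model` from an atom table
#'
#' @param atoms data.frame with at least chain, resno, insert, resid, elety,
#'   x, y, z; missing occ/b/elesy/alt columns are filled with defaults.
#' @param format "pdb" or "cif" (used when the model is written back).
#' @return an `atomic_model`.
#' @export
as_atomic_model <- function(atoms, format = "pdb") {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(atoms$elesy)) atoms$elesy <- sub("^([A-Za-z]).*", "\\1", atoms$elety)
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$is_h <- .is_hydrogen(atoms$elety, atoms$elesy)
  atoms$res_key <- .res_key(atoms$chain, atoms$resno, atoms$insert)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, format = format), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<atomic_model> %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(x$atoms), nrow(rt), length(unique(rt$chain)), x$format))
  invisible(x)
}

#' Residues of a model, in file order
#'
#' @param model an `atomic_model`.
#' @return data.frame with one row per residue: chain, resno, insert, resid,
#'   category, res_key, in file order.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  first <- !duplicated(a$res_key)
  rt <- a[first, c("chain", "resno", "insert", "resid", "res_key")]
  rt$category <- vapply(rt$res_key, function(k) {
    sel <- a$res_key == k
    .residue_category(a$resid[sel], a$elety[sel])
  }, character(1))
  rownames(rt) <- NULL
  rt
}

#' Select the atoms of a residue that enter its score
#'
#' In `backbone` mode: protein residues contribute N, CA and C (the backbone
#' carbonyl oxygen is excluded because its density is weak at resolutions
#' worse than ~3 A); nucleic residues contribute the sugar-phosphate
#' backbone C1', C2', C3', C4', C5', O3', O4', O5' and P; ligands and waters
#' contribute all their atoms. In `ca_only` mode (for CA-trace models):
#' protein CA, nucleic C1', ligands/waters all atoms. Hydrogens are always
#' excluded; atoms absent from the residue are silently omitted.
#'
#' @param residue_atoms data.frame of the residue's atoms (rows of
#'   `model$atoms` for one residue).
#' @param mode "backbone" (default) or "ca_only".
#' @return the selected rows of `residue_atoms` (possibly zero rows).
#' @export
select_score_atoms <- function(residue_atoms, mode = c("backbone", "ca_only")) {
  mode <- match.arg(mode)
  a <- residue_atoms[!residue_atoms$is_h, , drop = FALSE]
  if (nrow(a) == 0L) return(a)
  cat <- .residue_category(a$resid, a$elety)
  want <- switch(cat,
    protein = if (mode == "backbone") c("N", "CA", "C") else "CA",
    nucleic = if (mode == "backbone") .nuc_backbone else "C1'",
    NULL)                                   # ligand / water: all non-H atoms
  if (is.null(want)) a else a[a$elety %in% want, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Writers

.write_pdb_model <- function(atoms, path) {
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(atoms)),
    resno = atoms$resno, resid = atoms$resid,
    chain = ifelse(atoms$chain == "", " ", atoms$chain),
    insert = ifelse(atoms$insert == "", "", atoms$insert),
    elety = atoms$elety, o = atoms$occ, b = atoms$b,
    elesy = atoms$elesy
  )
  invisible(path)
}

.cif_quote <- function(x) ifelse(x == "" | is.na(x), ".", x)

.write_cif_model <- function(atoms, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "data_fdrmap",
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
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    "ATOM", seq_len(nrow(atoms)),
    .cif_quote(atoms$elesy), .cif_quote(atoms$elety), .cif_quote(atoms$alt),
    atoms$resid, .cif_quote(atoms$chain), atoms$resno,
    ifelse(atoms$insert == "", "?", atoms$insert),
    atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
    atoms$resno, atoms$resid, .cif_quote(atoms$chain), .cif_quote(atoms$elety))
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}

#' Write an atomic model to disk
#'
#' @param model an `atomic_model`.
#' @param path output path.
#' @param format "pdb" or "cif"; default mirrors the format the model was
#'   read from.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = model$format) {
  stopifnot(inherits(model, "atomic_model"))
  if (format == "cif") .write_cif_model(model$atoms, path)
  else .write_pdb_model(model$atoms, path)
  invisible(path)
}

#' Write a model with confidence scores in the B-factor column
#'
#' Every atom's B-factor is replaced by its residue's aggregate confidence
#' score (rounded to 2 decimals, the PDB column precision); residues without
#' a score get 0.0. Useful for colouring the model by confidence in
#' molecular graphics programs.
#'
#' @param model an `atomic_model`.
#' @param scores a `residue_scores` table from [score_model()].
#' @param path output path.
#' @param format "pdb" or "cif"; default mirrors the input format.
#' @return `path`, invisibly.
#' @export
write_model_with_scores <- function(model, scores, path, format = model$format) {
  stopifnot(inherits(model, "atomic_model"))
  s <- stats::setNames(scores$score, scores$res_key)
  b <- s[model$atoms$res_key]
  b[is.na(b)] <- 0
  out <- model
  out$atoms$b <- round(b, 2L)
  write_model(out, path, format = format)
}
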