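# Protein structure input/output and per-residue solvent accessibility.

#' Three-letter codes of the 20 standard amino acids
#'
#' Ordered alphabetically; the position of a code in this vector (0-based)
#' is its integer token. Any residue name not in this vector maps to the
#' unknown token 20.
#' @export
AA_CODES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL")

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# van der Waals radii (Angstrom) by element, default 1.70 for unknowns
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Map residue names to amino-acid tokens
#'
#' @param resname character vector of 3-letter residue names.
#' @return integer vector of tokens in `[0, 20]`; 20 is the unknown token
#'   used for any non-standard residue.
#' @export
aa_token <- function(resname) {
  idx <- match(toupper(resname), AA_CODES)
  idx[is.na(idx)] <- 21L
  idx - 1L
}

make_reskey <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

atom_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Build a protein_structure from an atom data.frame with columns:
# record ("ATOM"/"HETATM"), serial, name, resname, chain, resno, insert,
# x, y, z, occ, b, element.
ATOM_COLS <- c("record", "serial", "name", "resname", "chain", "resno",
               "insert", "x", "y", "z", "occ", "b", "element")

structure_from_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms), all(ATOM_COLS %in% names(atoms)))
  atoms <- atoms[, ATOM_COLS, drop = FALSE]
  atoms$record_kind <- ifelse(atoms$record == "HETATM", "hetero", "polymer")
  atoms$reskey <- make_reskey(atoms$chain, atoms$resno, atoms$insert)
  rownames(atoms) <- NULL

  pol <- atoms[atoms$record_kind == "polymer", , drop = FALSE]
  residues <- NULL
  if (nrow(pol) > 0) {
    first_idx <- which(!duplicated(pol$reskey))
    keys <- pol$reskey[first_idx]
    ca_row <- vapply(keys, function(k) {
      hit <- which(pol$reskey == k & pol$name == "CA")
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, integer(1))
    keep <- !is.na(ca_row)
    # map back to row indices in `atoms`
    pol_rows <- which(atoms$record_kind == "polymer")
    residues <- data.frame(
      chain = pol$chain[first_idx][keep],
      resno = pol$resno[first_idx][keep],
      reskey = keys[keep],
      resname = pol$resname[first_idx][keep],
      token = aa_token(pol$resname[first_idx][keep]),
      ca_idx = pol_rows[ca_row[keep]],
      stringsAsFactors = FALSE
    )
    rownames(residues) <- NULL
  } else {
    residues <- data.frame(chain = character(), resno = integer(),
                           reskey = character(), resname = character(),
                           token = integer(), ca_idx = integer(),
                           stringsAsFactors = FALSE)
  }

  het <- which(atoms$record_kind == "hetero" &
                 !(toupper(atoms$resname) %in% WATER_NAMES))
  ligands <- list()
  if (length(het) > 0) {
    grp <- paste0(atoms$resname[het], "_", atoms$reskey[het])
    ligands <- split(het, factor(grp, levels = unique(grp)))
  }

  structure(list(atoms = atoms, residues = residues, ligands = ligands),
            class = "protein_structure")
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations to
#' the highest-occupancy conformer (ties keep the first in file), classifies
#' HETATM groups as ligands unless they are water, and indexes polymer
#' residues by their C-alpha atom. Residues without a C-alpha are kept in
#' `atoms` but excluded from `residues`.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based model to read from a multi-model file.
#' @return an object of class `protein_structure`: a list with elements
#'   `atoms` (data.frame), `residues` (data.frame with one C-alpha per row)
#'   and `ligands` (named list of atom row indices, one entry per bound
#'   hetero group, water excluded).
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model_index > 1,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (!any(at$type == "ATOM")) {
    stop("no ATOM records in '", path, "': empty structure")
  }
  xyz <- cbind(at$x, at$y, at$z)
  if (model_index > 1) {
    if (nrow(pdb$xyz) < model_index) {
      stop("model ", model_index, " not present (file has ",
           nrow(pdb$xyz), ")")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  }
  element <- at$elesy
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- gsub("[^A-Za-z].*$", "", at$elety[bad])
  atoms <- data.frame(
    record = at$type, serial = at$eleno, name = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid, chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    element = toupper(element), stringsAsFactors = FALSE
  )
  if (!all(is.finite(xyz))) stop("non-finite coordinates in '", path, "'")

  # resolve altlocs: within (chain, resno, insert, atom name) keep the
  # highest occupancy record; ties keep the first in file order
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name,
                 sep = "\r")
    ord <- order(factor(key, levels = unique(key)), -atoms$occ,
                 seq_len(nrow(atoms)))
    atoms <- atoms[ord[!duplicated(key[ord])], , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  structure_from_atoms(atoms)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues (with C-alpha),",
      length(x$ligands), "ligand group(s)\n")
  invisible(x)
}

#' Remove all hetero atoms from a structure
#'
#' Returns a polymer-only copy, the state in which geometric pocket
#' detection and SASA are run (waters and bound ligands removed first).
#'
#' @param s a `protein_structure`.
#' @return a `protein_structure` containing only polymer atoms.
#' @export
strip_for_detection <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  structure_from_atoms(s$atoms[s$atoms$record_kind == "polymer",
                               , drop = FALSE])
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a 1.4-Angstrom probe over the polymer heavy atoms using the
#' Shrake-Rupley sphere-point method and sums atomic areas per residue.
#' Hydrogens, waters and ligands never enter the calculation.
#'
#' @param s a `protein_structure` with at least one polymer atom.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere test points per atom (>= 100; per-residue
#'   discretization error falls roughly as `1/sqrt(n_points)` — about 2%
#'   at the default, below 1% from ~4000 points).
#' @return named numeric vector (class `sasa_table`) of SASA in
#'   square Angstrom, one entry per polymer residue keyed `chain:resno`.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 512L) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  sel <- a$record_kind == "polymer" & a$element != "H"
  if (!any(sel)) stop("structure has no polymer heavy atoms")
  a <- a[sel, , drop = FALSE]
  xyz <- cbind(a$x, a$y, a$z)
  rad <- atom_radius(a$element) + probe
  n <- nrow(a)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbor candidates: anything within r_i + max radius
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & d2 > 1e-12)
    p <- pts * rad[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 > rad[j]^2)
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  keys <- make_reskey(a$chain, a$resno, a$insert)
  out <- tapply(area, factor(keys, levels = unique(keys)), sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  class(res) <- "sasa_table"
  res
}

fmt_atom_name <- function(name) {
  name <- substr(name, 1, 4)
  ifelse(nchar(name) >= 4, name, sprintf(" %-3s", name))
}

#' Write a structure to a PDB file
#'
#' Optionally writes a per-atom scalar (e.g. a predicted pocket score) into
#' the B-factor column, clipped to `[0, 999.99]`; atoms not covered by the
#' map get 0. This supports score visualization in standard molecular
#' viewers.
#'
#' @param s a `protein_structure`.
#' @param path output file path.
#' @param per_atom_scalar optional numeric vector; either of length
#'   `nrow(s$atoms)` or named by atom row index for a subset of atoms.
#' @return invisibly, the path written.
#' @export
write_structure <- function(s, path, per_atom_scalar = NULL) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  b <- rep(0, nrow(a))
  if (!is.null(per_atom_scalar)) {
    if (is.null(names(per_atom_scalar))) {
      stopifnot(length(per_atom_scalar) == nrow(a))
      b <- as.numeric(per_atom_scalar)
    } else {
      idx <- as.integer(names(per_atom_scalar))
      stopifnot(all(idx >= 1 & idx <= nrow(a)))
      b[idx] <- as.numeric(per_atom_scalar)
    }
  }
  b <- pmin(pmax(b, 0), 999.99)
  lines <- sprintf("%-6s%5d %4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$record, a$serial %% 100000, fmt_atom_name(a$name), " ",
                   substr(a$resname, 1, 4), a$chain, a$resno %% 10000,
                   ifelse(a$insert == "", " ", a$insert),
                   a$x, a$y, a$z, a$occ, b, a$element)
  ok <- tryCatch({
    writeLines(c(lines, "END"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write PDB file: ", path)
  invisible(path)
}
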