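# Synthetic fixtures: toy protein-like chains with planted positive and
# negative pockets. Geometry is fake but every labeling rule of the real
# pipeline holds by construction: positive pockets have a ligand whose
# nearest atom is 0.5-3.5 Angstrom from the pocket barycenter (DCA < 4),
# negative pockets keep every ligand > 4.5 Angstrom away. The learnable
# signal is the amino-acid composition of the pocket lining: positive
# linings are drawn from a "binding" palette with probability
# `signal_strength`, so the label is predictable from the model's primary
# node feature, not from a coordinate artifact.

# positive linings are enriched in these residues; the background palette
# is all 20 amino acids (real background composition includes aromatic and
# sulfur residues, so negatives carry the binding residues at base rate)
BINDING_PALETTE <- c("TRP", "TYR", "PHE", "HIS", "MET", "CYS")
BACKGROUND_PALETTE <- AA_CODES

#' Synthetic dataset specification
#'
#' @param n_proteins number of chains to generate.
#' @param residues_per_protein residues per chain (>= 20).
#' @param pockets_per_protein planted pocket candidates per chain.
#' @param positive_fraction probability that a planted pocket is positive.
#' @param signal_strength probability that a positive pocket's lining
#'   residue is drawn from the binding palette instead of the background
#'   palette; 0 means no label signal in the features.
#' @param rng_seed root seed; regeneration under the same seed is
#'   bitwise identical.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 10L, residues_per_protein = 60L,
                         pockets_per_protein = 6L, positive_fraction = 0.07,
                         signal_strength = 0.9, rng_seed = 1L) {
  stopifnot(positive_fraction > 0, positive_fraction < 1,
            residues_per_protein >= 20, signal_strength >= 0,
            signal_strength <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 residues_per_protein = as.integer(residues_per_protein),
                 pockets_per_protein = as.integer(pockets_per_protein),
                 positive_fraction = positive_fraction,
                 signal_strength = signal_strength,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a random protein-like chain
#'
#' Self-avoiding random walk of C-alpha positions with 3.8 Angstrom steps
#' and at least 3.5 Angstrom clearance between any C-alpha pair, decorated
#' with 1-4 pseudo side-chain atoms per residue. Residue names are drawn
#' from the background palette (pocket planting re-palettes linings).
#'
#' @param n_residues chain length (>= 2).
#' @param chain_id chain identifier.
#' @return a `protein_structure`.
#' @export
make_chain <- function(n_residues, chain_id = "A") {
  stopifnot(n_residues >= 2)
  for (restart in 1:30) {
    ca <- matrix(NA_real_, n_residues, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- rand_unit()
    ok <- TRUE
    for (i in 2:n_residues) {
      placed <- FALSE
      for (try in 1:60) {
        nd <- dir * 0.6 + rand_unit()
        nd <- nd / sqrt(sum(nd^2))
        cand <- ca[i - 1, ] + 3.8 * nd
        if (i > 2) {
          d2 <- colSums((t(ca[1:(i - 2), , drop = FALSE]) - cand)^2)
          if (min(d2) < 3.5^2) next
        }
        ca[i, ] <- cand
        dir <- nd
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
    if (restart == 30) stop("chain generation failed after bounded retries")
  }
  side_names <- c("CB", "CG", "CD", "CE")
  side_elem <- c("C", "C", "C", "O")
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    resname <- sample(BACKGROUND_PALETTE, 1)
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      record = "ATOM", serial = serial, name = "CA", resname = resname,
      chain = chain_id, resno = i, insert = "", x = ca[i, 1], y = ca[i, 2],
      z = ca[i, 3], occ = 1, b = 0, element = "C",
      stringsAsFactors = FALSE)
    nside <- sample(1:4, 1)
    pos <- ca[i, ]
    for (k in seq_len(nside)) {
      pos <- pos + 1.5 * rand_unit()
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        record = "ATOM", serial = serial, name = side_names[k],
        resname = resname, chain = chain_id, resno = i, insert = "",
        x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0,
        element = side_elem[k], stringsAsFactors = FALSE)
    }
  }
  structure_from_atoms(do.call(rbind, rows))
}

append_ligand <- function(s, coords, lig_no) {
  n0 <- max(s$atoms$serial)
  rows <- data.frame(
    record = "HETATM", serial = n0 + seq_len(nrow(coords)),
    name = paste0("C", seq_len(nrow(coords))), resname = "LIG",
    chain = "B", resno = lig_no, insert = "", x = coords[, 1],
    y = coords[, 2], z = coords[, 3], occ = 1, b = 0, element = "C",
    stringsAsFactors = FALSE)
  structure_from_atoms(rbind(s$atoms[, ATOM_COLS, drop = FALSE], rows))
}

# all ligand atoms currently in s, as one matrix (possibly 0 rows)
all_ligand_atoms <- function(s) {
  lc <- ligand_coords(s)
  if (length(lc) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lc)
}

#' Plant one pocket candidate on a structure
#'
#' Picks a surface locus (a C-alpha pushed outward from the centroid),
#' emits 5-20 alpha-sphere-like vertices in a 3 Angstrom ball around it,
#' and, for a positive pocket, places a 5-15 atom ligand whose nearest
#' atom sits at a uniform 0.5-3.5 Angstrom from the vertex barycenter.
#' For a negative pocket the barycenter is guaranteed to stay more than
#' 4.5 Angstrom from every ligand already present in the structure.
#'
#' @param s a `protein_structure` (ligands of previously planted positive
#'   pockets included).
#' @param positive logical: plant a true binding site?
#' @param spec a `fixture_spec`.
#' @param avoid matrix of previously used loci to keep >= `min_sep` away
#'   from (or `NULL`).
#' @param avoid_cross matrix of loci of the opposite label; kept at least
#'   `cross_sep` away so opposite-label pocket linings stay disjoint (the
#'   lining reaches ~13 Angstrom from a locus; shared lining residues
#'   would contaminate the composition signal).
#' @param min_sep minimum same-label locus separation in Angstrom.
#' @param cross_sep minimum opposite-label locus separation in Angstrom.
#' @return list with `candidate` (a `pocket_candidate`), `ligand`
#'   (coordinate matrix or `NULL`) and `locus`.
#' @export
plant_pocket <- function(s, positive, spec, avoid = NULL,
                         avoid_cross = NULL, min_sep = 6, cross_sep = 26) {
  ca_idx <- s$residues$ca_idx
  ca <- cbind(s$atoms$x[ca_idx], s$atoms$y[ca_idx], s$atoms$z[ca_idx])
  centroid <- colMeans(ca)
  ligs <- all_ligand_atoms(s)
  for (relax in c(1, 0.8, 0.6)) {
    for (try in 1:200) {
      i <- sample.int(nrow(ca), 1)
      out_dir <- ca[i, ] - centroid
      nrm <- sqrt(sum(out_dir^2))
      out_dir <- if (nrm < 1e-6) rand_unit() else out_dir / nrm
      locus <- ca[i, ] + 4.0 * out_dir
      if (!is.null(avoid) && nrow(avoid) > 0) {
        if (min(colSums((t(avoid) - locus)^2)) < (min_sep * relax)^2) next
      }
      if (!is.null(avoid_cross) && nrow(avoid_cross) > 0) {
        if (min(colSums((t(avoid_cross) - locus)^2)) <
              (cross_sep * relax)^2) next
      }
      nv <- sample(5:20, 1)
      r <- 3 * stats::runif(nv)^(1 / 3)
      u <- matrix(stats::rnorm(3 * nv), nv)
      u <- u / sqrt(rowSums(u^2))
      vertices <- sweep(u * r, 2, locus, "+")
      bary <- colMeans(vertices)
      if (!positive) {
        if (nrow(ligs) > 0 &&
            min(colSums((t(ligs) - bary)^2)) <= 4.5^2) next
        return(list(candidate = pocket_candidate("tmp", vertices),
                    ligand = NULL, locus = locus))
      }
      # positive: ligand with nearest atom at u0 from the barycenter
      u0 <- stats::runif(1, 0.5, 3.5)
      dir0 <- rand_unit()
      first <- bary + u0 * dir0
      nl <- sample(5:15, 1)
      lig <- matrix(NA_real_, nl, 3)
      lig[1, ] <- first
      ok <- TRUE
      if (nl > 1) {
        for (k in 2:nl) {
          placed <- FALSE
          for (t2 in 1:50) {
            cand <- first + 2.5 * stats::runif(1)^(1 / 3) * rand_unit()
            if (sum((cand - bary)^2) >= u0^2) {
              lig[k, ] <- cand
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      return(list(candidate = pocket_candidate("tmp", vertices),
                  ligand = lig, locus = locus))
    }
  }
  stop("could not plant pocket under distance constraints")
}

write_pqr_vertices <- function(vertices, path, pocket_no) {
  lines <- sprintf(
    "ATOM  %5d APOL STP %5d    %11.4f %11.4f %11.4f %9.4f %9.4f",
    seq_len(nrow(vertices)), pocket_no, vertices[, 1], vertices[, 2],
    vertices[, 3], 0, 1.5)
  writeLines(c(lines, "TER", "END"), path)
}

#' Generate a full labeled synthetic dataset
#'
#' Generates `n_proteins` chains, plants pockets with the requested
#' positive fraction, re-palettes pocket linings according to
#' `signal_strength`, computes SASA, builds the labeled pocket graphs,
#' and (optionally) writes every input dialect the pipeline reads: PDB
#' files, Fpocket-layout vertex files, vertex CSVs, a labels CSV and the
#' graph archive. Proteins that happen to receive no positive pocket get
#' one far-away decoy ligand so that DCA labels remain computable (and
#' false) for all their pockets.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if missing), or `NULL` for an
#'   in-memory dataset only.
#' @param build_graphs set `FALSE` to skip SASA/graph construction (fast
#'   geometry-only generation, used for planting statistics).
#' @return list with `graphs`, `structures`, `candidates` (per protein,
#'   with `dca`/`label` populated), `labels` (data.frame), `spec`.
#' @export
make_dataset <- function(spec, dir = NULL, build_graphs = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed)
  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  structures <- list()
  candidates <- list()
  graphs <- list()
  labels <- data.frame()
  for (p in seq_len(spec$n_proteins)) {
    pid <- sprintf("prot%03d", p)
    s <- make_chain(spec$residues_per_protein)
    planned <- stats::runif(spec$pockets_per_protein) < spec$positive_fraction
    # plant positives first (their ligands constrain the negatives)
    order_slots <- c(which(planned), which(!planned))
    loci <- matrix(numeric(0), 0, 3)
    pos_loci <- matrix(numeric(0), 0, 3)
    cands <- vector("list", spec$pockets_per_protein)
    lig_no <- 0L
    for (slot in order_slots) {
      pl <- plant_pocket(s, planned[slot], spec, avoid = loci,
                         avoid_cross = if (planned[slot]) NULL else pos_loci)
      loci <- rbind(loci, pl$locus)
      if (planned[slot]) pos_loci <- rbind(pos_loci, pl$locus)
      cands[[slot]] <- pl$candidate
      if (!is.null(pl$ligand)) {
        lig_no <- lig_no + 1L
        s <- append_ligand(s, pl$ligand, lig_no)
      }
    }
    if (lig_no == 0L) {
      # decoy ligand far outside every pocket so labels stay computable
      ca_idx <- s$residues$ca_idx
      ca <- cbind(s$atoms$x[ca_idx], s$atoms$y[ca_idx], s$atoms$z[ca_idx])
      far <- colMeans(ca) + (max(stats::dist(rbind(colMeans(ca), ca))) + 20) *
        rand_unit()
      s <- append_ligand(s, rbind(far, far + c(1.4, 0, 0),
                                  far + c(0, 1.4, 0)), 1L)
    }
    # re-palette linings: negatives first so positive signal wins overlaps
    atoms <- s$atoms
    for (slot in order(planned)) {
      keys <- tryCatch(select_pocket_residues(s, cands[[slot]], radius = 10),
                       error = function(e) character(0))
      if (length(keys) == 0) next
      for (key in keys) {
        newname <- if (planned[slot] &&
                       stats::runif(1) < spec$signal_strength) {
          sample(BINDING_PALETTE, 1)
        } else {
          sample(BACKGROUND_PALETTE, 1)
        }
        atoms$resname[atoms$record == "ATOM" &
                        make_reskey(atoms$chain, atoms$resno,
                                    atoms$insert) == key] <- newname
      }
    }
    s <- structure_from_atoms(atoms)
    ligs <- ligand_coords(s)
    sasa <- if (build_graphs) compute_sasa(s) else NULL
    for (k in seq_len(spec$pockets_per_protein)) {
      cand <- cands[[k]]
      cand$pocket_id <- sprintf("pocket%d", k)
      cand <- assign_label(cand, ligs)
      cands[[k]] <- cand
      labels <- rbind(labels, data.frame(
        protein_id = pid, pocket_id = cand$pocket_id, label = cand$label,
        dca = cand$dca, stringsAsFactors = FALSE))
      if (build_graphs) {
        keys <- select_pocket_residues(s, cand, radius = 10)
        graphs[[length(graphs) + 1L]] <-
          build_graph(s, keys, sasa, cutoff = 25, label = cand$label,
                      pocket_id = cand$pocket_id, protein_id = pid)
      }
    }
    structures[[pid]] <- s
    candidates[[pid]] <- cands
    if (!is.null(dir)) {
      write_structure(s, file.path(dir, paste0(pid, ".pdb")))
      pdir <- file.path(dir, paste0(pid, "_out"), "pockets")
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      csv <- data.frame()
      for (k in seq_len(spec$pockets_per_protein)) {
        v <- cands[[k]]$vertices
        write_pqr_vertices(v, file.path(pdir,
                                        sprintf("pocket%d_vert.pqr", k)), k)
        csv <- rbind(csv, data.frame(pocket_id = sprintf("pocket%d", k),
                                     x = v[, 1], y = v[, 2], z = v[, 3]))
      }
      utils::write.csv(csv, file.path(dir, paste0(pid, "_vertices.csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(dir)) {
    utils::write.csv(labels, file.path(dir, "labels.csv"),
                     row.names = FALSE)
    if (build_graphs) {
      write_graph_archive(graphs, file.path(dir, "graphs.rds"))
    }
  }
  list(graphs = graphs, structures = structures, candidates = candidates,
       labels = labels, spec = spec)
}
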