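# Pocket candidate ingestion, barycenters and DCA-based truth labels.

#' Construct a pocket candidate
#'
#' A candidate is a set of alpha-sphere vertex coordinates (e.g. from
#' Fpocket) plus its barycenter. The barycenter is always the arithmetic
#' mean of the vertices.
#'
#' @param pocket_id identifier string.
#' @param vertices numeric matrix `[n, 3]` of vertex coordinates (Angstrom).
#' @param dca optional distance from the barycenter to the closest ligand
#'   atom (Angstrom).
#' @param label optional logical truth label; must equal `dca < 4`.
#' @return object of class `pocket_candidate`.
#' @export
pocket_candidate <- function(pocket_id, vertices, dca = NULL, label = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  stopifnot(nrow(vertices) >= 1, all(is.finite(vertices)))
  if (!is.null(label)) {
    stopifnot(!is.null(dca), identical(label, dca < 4.0))
  }
  structure(list(pocket_id = as.character(pocket_id), vertices = vertices,
                 barycenter = colMeans(vertices), dca = dca, label = label),
            class = "pocket_candidate")
}

#' @export
print.pocket_candidate <- function(x, ...) {
  cat("pocket_candidate", x$pocket_id, ":", nrow(x$vertices), "vertices",
      if (!is.null(x$dca)) sprintf("| DCA %.2f A", x$dca) else "",
      if (!is.null(x$label)) sprintf("| label %s", x$label) else "", "\n")
  invisible(x)
}

parse_pqr_vertices <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  lines <- lines[rec]
  if (length(lines) == 0) return(NULL)
  coords <- matrix(NA_real_, length(lines), 3)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # PQR: recname serial name resname [chain] resno x y z charge radius;
    # x,y,z are the 3rd..5th fields from the end
    n <- length(f)
    v <- suppressWarnings(as.numeric(f[(n - 4):(n - 2)]))
    if (n < 7 || any(is.na(v))) {
      # fixed-column PDB-like dialect
      v <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    }
    coords[i, ] <- v
  }
  if (any(is.na(coords))) return(NULL)
  coords
}

#' Read pocket candidates from an Fpocket output directory
#'
#' Expects the Fpocket v4 layout `<dir>/pockets/pocket<N>_vert.pqr`; one
#' candidate is created per vertex file, ordered by `N` ascending (Fpocket's
#' own rank order). Only the x, y, z fields of each ATOM/HETATM record are
#' consumed.
#'
#' @param dir an Fpocket output directory (the one containing `pockets/`).
#' @return list of `pocket_candidate`.
#' @export
read_fpocket_output <- function(dir) {
  pdir <- file.path(dir, "pockets")
  if (!dir.exists(pdir)) {
    stop("not an Fpocket output directory (no 'pockets/' in '", dir, "')")
  }
  files <- list.files(pdir, pattern = "^pocket[0-9]+_vert\\.pqr$")
  ns <- as.integer(sub("^pocket([0-9]+)_vert\\.pqr$", "\\1", files))
  files <- files[order(ns)]
  out <- list()
  for (f in files) {
    coords <- parse_pqr_vertices(file.path(pdir, f))
    if (is.null(coords)) {
      warning("skipping vertex file with no coordinate records: ", f)
      next
    }
    out[[length(out) + 1L]] <- pocket_candidate(sub("\\.pqr$", "", f), coords)
  }
  out
}

#' Read pocket candidates from a vertex CSV
#'
#' CSV with header `pocket_id,x,y,z`, one vertex per row; candidates appear
#' in first-occurrence order of `pocket_id`.
#'
#' @param path CSV file path.
#' @return list of `pocket_candidate`.
#' @export
read_vertex_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pocket_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("vertex CSV must have columns pocket_id,x,y,z")
  }
  ids <- unique(df$pocket_id)
  lapply(ids, function(id) {
    sub <- df[df$pocket_id == id, , drop = FALSE]
    pocket_candidate(id, as.matrix(sub[, c("x", "y", "z")]))
  })
}

#' Built-in geometric cavity detector
#'
#' A simple grid-based stand-in for an external alpha-sphere detector:
#' grid points inside the bounding box that keep >= 3 Angstrom clearance
#' from every heavy atom yet are buried (>= `min_buried` heavy atoms within
#' 6 Angstrom) are clustered by single linkage at `2 * grid_spacing`;
#' each cluster of at least `min_cluster` points becomes one candidate.
#' Candidates are ordered by cluster size, largest first.
#'
#' @param s polymer-only `protein_structure`.
#' @param grid_spacing grid step in Angstrom.
#' @param min_cluster minimum cluster size to report.
#' @param clearance minimum distance to any heavy atom (Angstrom).
#' @param burial_radius,min_buried burial test: at least `min_buried` heavy
#'   atoms within `burial_radius` Angstrom.
#' @return list of `pocket_candidate` (possibly empty).
#' @export
fallback_detect <- function(s, grid_spacing = 1.0, min_cluster = 5L,
                            clearance = 3.0, burial_radius = 6.0,
                            min_buried = 12L) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms[s$atoms$record_kind == "polymer" & s$atoms$element != "H",
               , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: no polymer heavy atoms")
  xyz <- cbind(a$x, a$y, a$z)
  lo <- apply(xyz, 2, min)
  hi <- apply(xyz, 2, max)
  gx <- seq(lo[1], hi[1], by = grid_spacing)
  gy <- seq(lo[2], hi[2], by = grid_spacing)
  gz <- seq(lo[3], hi[3], by = grid_spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  keep <- matrix(NA_real_, 0, 3)
  chunk <- 4000L
  for (s0 in seq(1, nrow(grid), by = chunk)) {
    g <- grid[s0:min(s0 + chunk - 1L, nrow(grid)), , drop = FALSE]
    d2 <- outer(rowSums(g^2), rowSums(xyz^2), "+") - 2 * g %*% t(xyz)
    mind2 <- apply(d2, 1, min)
    nbur <- rowSums(d2 <= burial_radius^2)
    ok <- mind2 >= clearance^2 & nbur >= min_buried
    if (any(ok)) keep <- rbind(keep, g[ok, , drop = FALSE])
  }
  if (nrow(keep) == 0) return(list())
  if (nrow(keep) == 1) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(keep), method = "single")
    cl <- stats::cutree(hc, h = 2 * grid_spacing)
  }
  sizes <- table(cl)
  ids <- names(sizes)[sizes >= min_cluster]
  ids <- ids[order(-sizes[ids])]
  out <- list()
  for (k in seq_along(ids)) {
    out[[k]] <- pocket_candidate(paste0("cavity", k),
                                 keep[cl == as.integer(ids[k]), , drop = FALSE])
  }
  out
}

as_ligand_matrix <- function(ligand_atoms) {
  if (is.list(ligand_atoms) && !is.matrix(ligand_atoms)) {
    ligand_atoms <- do.call(rbind, lapply(ligand_atoms, function(m) {
      matrix(as.numeric(m), ncol = 3)
    }))
  }
  m <- matrix(as.numeric(ligand_atoms), ncol = 3)
  if (nrow(m) == 0) stop("empty ligand atom set")
  m
}

#' Distance from pocket barycenter to the closest ligand atom (DCA)
#'
#' @param p a `pocket_candidate`.
#' @param ligand_atoms numeric matrix `[m, 3]` of ligand atom coordinates,
#'   or a list of such matrices (multiple ligand groups; the minimum over
#'   all of them is taken).
#' @return DCA in Angstrom.
#' @export
compute_dca <- function(p, ligand_atoms) {
  stopifnot(inherits(p, "pocket_candidate"))
  m <- as_ligand_matrix(ligand_atoms)
  sqrt(min(colSums((t(m) - p$barycenter)^2)))
}

#' Assign the DCA truth label to a pocket candidate
#'
#' A candidate is a true binding site iff its DCA is strictly less than
#' 4 Angstrom (a DCA of exactly 4 labels false).
#'
#' @inheritParams compute_dca
#' @return the candidate with `dca` and `label` populated.
#' @export
assign_label <- function(p, ligand_atoms) {
  d <- compute_dca(p, ligand_atoms)
  p$dca <- d
  p$label <- d < 4.0
  p
}

#' Extract ligand atom coordinates from a structure
#'
#' @param s a `protein_structure`.
#' @return list of numeric matrices `[m, 3]`, one per ligand group
#'   (waters excluded); empty list if the structure has no ligands.
#' @export
ligand_coords <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  lapply(s$ligands, function(idx) {
    cbind(s$atoms$x[idx], s$atoms$y[idx], s$atoms$z[idx])
  })
}
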