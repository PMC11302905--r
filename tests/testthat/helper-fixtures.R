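# Shared in-code fixtures: tiny PDB text, random graphs, rigid motions.

# three polymer residues (ALA, GLY with altlocs, SER), one LIG group,
# two waters
tiny_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1      12.824   7.021  -5.041  1.00  0.00           C",
    "ATOM      4  N   GLY A   2      10.960   5.107  -4.215  1.00  0.00           N",
    "ATOM      5  CA AGLY A   2      11.361   5.009  -2.801  0.40  0.00           C",
    "ATOM      6  CA BGLY A   2      11.461   5.109  -2.901  0.60  0.00           C",
    "ATOM      7  N   SER A   3       9.000   4.000  -2.000  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       8.500   3.500  -0.800  1.00  0.00           C",
    "ATOM      9  OG  SER A   3       7.100   3.600  -0.700  1.00  0.00           O",
    "HETATM   10  C1  LIG B 101       2.000   2.000   2.000  1.00  0.00           C",
    "HETATM   11  C2  LIG B 101       3.100   2.000   2.000  1.00  0.00           C",
    "HETATM   12  O   HOH A 201      20.000  20.000  20.000  1.00  0.00           O",
    "HETATM   13  O   HOH A 202      21.000  20.000  20.000  1.00  0.00           O",
    "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines(), path)
  path
}

# random labeled pocket graph (uses the current RNG state)
rand_pocket_graph <- function(n = 10, spread = 8, cutoff = 25) {
  pocket_graph(aa_token = sample(0:20, n, replace = TRUE),
               sasa = stats::runif(n, 0, 320),
               coords = matrix(stats::rnorm(n * 3, sd = spread), n),
               cutoff = cutoff, label = stats::runif(1) < 0.5,
               residue_keys = paste0("A:", seq_len(n)),
               pocket_id = "p", protein_id = "x")
}

# random proper rotation (or improper if reflect = TRUE) plus translation
rand_rigid <- function(reflect = FALSE) {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q <- Q[, c(2, 1, 3)]
  if (reflect) Q <- Q %*% diag(c(-1, 1, 1))
  list(R = Q, t = stats::rnorm(3, sd = 30))
}

apply_rigid <- function(coords, m) {
  sweep(coords %*% m$R, 2, m$t, "+")
}

# rebuild a graph after moving its coordinates rigidly
transform_graph <- function(g, m) {
  pocket_graph(aa_token = g$aa_token, sasa = g$sasa,
               coords = apply_rigid(g$coords, m), cutoff = g$cutoff,
               label = g$label, pocket_id = g$pocket_id,
               protein_id = g$protein_id)
}

# hollow atom box (dense walls, one interior cavity); the walls span the
# full bounding box, so the only clear-and-buried region is the cavity
cage_structure <- function(half = 7, spacing = 1.4) {
  g <- seq(-half, half, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  on_wall <- rowSums(abs(abs(pts) - half) < 1e-9) > 0
  xyz <- pts[on_wall, , drop = FALSE]
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(nrow(xyz)), name = "CA",
    resname = "GLY", chain = "A", resno = seq_len(nrow(xyz)), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
    element = "C", stringsAsFactors = FALSE)
  pocketgt:::structure_from_atoms(atoms)
}

# reduced configuration for smoke-level training tests: tiny model plus a
# faster peak learning rate than the production recipe so a separable toy
# set is learnable in a couple dozen epochs
small_train_cfg <- function(balance = TRUE, noise = TRUE, epochs = 6,
                            d = 16, L = 1, H = 4) {
  train_config(
    model = model_config(L = L, d = d, H = H, use_sasa = TRUE),
    augment = augment_config(balance = balance, noise = noise),
    max_lr = 1e-3,
    total_epochs = epochs, warmup_epochs = min(3, epochs - 1),
    batch_size = 64, n_folds = 2, seed = 1)
}
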