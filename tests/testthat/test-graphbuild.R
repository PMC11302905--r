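# a line of residues spaced `step` Angstrom apart along x
line_structure <- function(n, step) {
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n), name = "CA", resname = "ALA",
    chain = "A", resno = seq_len(n), insert = "",
    x = (seq_len(n) - 1) * step, y = 0, z = 0, occ = 1, b = 0,
    element = "C", stringsAsFactors = FALSE)
  pocketgt:::structure_from_atoms(atoms)
}

test_that("residue selection uses an inclusive 10-Angstrom boundary", {
  s <- line_structure(3, 9.99)   # residues at 0, 9.99, 19.98
  p <- pocket_candidate("p", matrix(0, 1, 3))
  expect_equal(select_pocket_residues(s, p, radius = 10),
               c("A:1", "A:2"))
  s2 <- line_structure(2, 10.01)
  expect_equal(select_pocket_residues(s2, p, radius = 10), "A:1")
  # no residue in range -> empty-pocket error
  far <- pocket_candidate("p", matrix(c(500, 0, 0), 1))
  expect_error(select_pocket_residues(s, far), "empty pocket")
})

test_that("residue selection matches the brute-force double loop", {
  set.seed(21)
  s <- make_chain(100)
  for (rep in 1:5) {
    v <- matrix(rnorm(15, sd = 15), 5)
    p <- pocket_candidate("p", v)
    got <- tryCatch(select_pocket_residues(s, p, radius = 10),
                    error = function(e) character(0))
    ca <- cbind(s$atoms$x[s$residues$ca_idx], s$atoms$y[s$residues$ca_idx],
                s$atoms$z[s$residues$ca_idx])
    want <- s$residues$reskey[sapply(seq_len(nrow(ca)), function(i) {
      any(sqrt(colSums((t(v) - ca[i, ])^2)) <= 10)
    })]
    expect_identical(got, want)
  }
})

test_that("graph edges obey the inclusive 25-Angstrom cutoff", {
  s <- line_structure(2, 24)
  g <- build_graph(s, c("A:1", "A:2"), sasa = NULL)
  expect_equal(nrow(g$edges), 2)   # one undirected edge, both arcs
  s2 <- line_structure(2, 26)
  g2 <- build_graph(s2, c("A:1", "A:2"), sasa = NULL)
  expect_equal(nrow(g2$edges), 0)
})

test_that("edge sets equal the brute-force all-pairs threshold", {
  set.seed(31)
  coords <- matrix(rnorm(150, sd = 12), 50)
  g <- pocket_graph(aa_token = rep(0L, 50), sasa = rep(0, 50),
                    coords = coords, cutoff = 25)
  want <- matrix(integer(0), 0, 2)
  for (i in 1:50) for (j in 1:50) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 25) {
      want <- rbind(want, c(i, j))
    }
  }
  got <- g$edges[order(g$edges[, 1], g$edges[, 2]), ]
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
  # symmetry and no self loops
  expect_true(all(g$edges[, 1] != g$edges[, 2]))
  key <- paste(g$edges[, 1], g$edges[, 2])
  rev <- paste(g$edges[, 2], g$edges[, 1])
  expect_true(all(rev %in% key))
})

test_that("missing SASA values fall back to zero with a warning", {
  s <- line_structure(2, 5)
  sasa <- c("A:1" = 50)
  class(sasa) <- "sasa_table"
  expect_warning(g <- build_graph(s, c("A:1", "A:2"), sasa), "no SASA")
  expect_equal(g$sasa, c(50, 0))
})

test_that("RBF embedding matches the scalar formula", {
  # center hit is exactly 1
  v <- rbf_embed(3, c(3, 25), 8)
  expect_equal(v[1, 1], 1.0)
  expect_true(all(v > 0 & v <= 1))
  # midpoint between adjacent centers gives equal components
  mu <- seq(3, 25, length.out = 8)
  mid <- (mu[3] + mu[4]) / 2
  vm <- rbf_embed(mid, c(3, 25), 8)
  expect_equal(vm[1, 3], vm[1, 4])
  # elementwise agreement with the direct evaluation
  gamma <- 1 / (2 * (mu[2] - mu[1])^2)
  expect_equal(as.numeric(rbf_embed(12.7, c(3, 25), 8, gamma)),
               brute_rbf(12.7, c(3, 25), 8, gamma), tolerance = 1e-12)
  # default gamma is the smooth-overlap choice
  expect_equal(as.numeric(rbf_embed(12.7, c(3, 25), 8)),
               brute_rbf(12.7, c(3, 25), 8, gamma), tolerance = 1e-12)
})

test_that("node features one-hot encode tokens and append the SASA RBF", {
  cfg <- feature_config(d = 16, use_sasa = FALSE)
  g <- pocket_graph(aa_token = c(0L, 20L), sasa = c(0, 10),
                    coords = matrix(0:5, 2), cutoff = 25)
  nf <- node_features(g, cfg)
  expect_equal(dim(nf), c(2, 21))
  expect_equal(nf[1, ], c(1, rep(0, 20)))        # alanine
  expect_equal(nf[2, ], c(rep(0, 20), 1))        # unknown token
  cfgs <- feature_config(d = 16, use_sasa = TRUE)
  nfs <- node_features(g, cfgs)
  expect_equal(dim(nfs), c(2, 21 + 16))
  expect_equal(nfs[1, 22:37],
               as.numeric(rbf_embed(0, cfgs$sasa_range, 16,
                                    cfgs$gamma_sasa)))
  expect_equal(aa_token("XYZ"), 20L)
})

test_that("edge features are symmetric and match the formula", {
  cfg <- feature_config(d = 8, use_sasa = TRUE)
  s <- line_structure(2, 3)   # edge length 3 = first distance center
  g <- build_graph(s, c("A:1", "A:2"), sasa = NULL)
  ef <- edge_features(g, cfg)
  expect_equal(ef[1, 1], 1.0)
  expect_equal(ef[1, ], ef[2, ])
  set.seed(41)
  g2 <- rand_pocket_graph(12)
  ef2 <- edge_features(g2, cfg)
  for (e in sample(nrow(g2$edges), 5)) {
    d <- sqrt(sum((g2$coords[g2$edges[e, 1], ] -
                     g2$coords[g2$edges[e, 2], ])^2))
    expect_equal(ef2[e, ], brute_rbf(d, cfg$dist_range, 8, cfg$gamma_dist),
                 tolerance = 1e-12)
  }
})

test_that("features are invariant under rigid motions of the graph", {
  set.seed(51)
  cfg <- feature_config(d = 12, use_sasa = TRUE)
  g <- rand_pocket_graph(15)
  g2 <- transform_graph(g, rand_rigid(reflect = TRUE))
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_equal(node_features(g2, cfg), node_features(g, cfg))
  expect_equal(edge_features(g2, cfg), edge_features(g, cfg),
               tolerance = 1e-9)
})

test_that("graph archives round-trip with their JSON sidecar", {
  set.seed(61)
  graphs <- lapply(1:3, function(i) rand_pocket_graph(6))
  p <- tempfile(fileext = ".rds")
  write_graph_archive(graphs, p)
  expect_true(file.exists(paste0(p, ".json")))
  back <- read_graph_archive(p)
  expect_equal(back, graphs)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_length(meta, 3)
  expect_equal(meta[[1]]$n_nodes, 6)
})
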