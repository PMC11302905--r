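# Pocket residue selection, C-alpha graph construction and input features.

#' Feature configuration
#'
#' Radial-basis-function (RBF) embeddings for the two continuous inputs:
#' per-residue SASA (centers equally spaced on 0-350 square Angstrom) and
#' C-alpha pair distance (centers equally spaced on 3-25 Angstrom). The
#' widths default to `gamma = 1 / (2 * delta^2)` with `delta` the center
#' spacing, so adjacent basis functions overlap smoothly.
#'
#' @param d hidden width; also the default number of RBF centers.
#' @param use_sasa include the SASA feature block.
#' @param sasa_range,dist_range numeric length-2 center ranges.
#' @param n_rbf_sasa,n_rbf_dist number of centers for each embedding.
#' @param gamma_sasa,gamma_dist RBF widths; `NULL` means the default above.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(d = 128L, use_sasa = TRUE,
                           sasa_range = c(0, 350), dist_range = c(3, 25),
                           n_rbf_sasa = d, n_rbf_dist = d,
                           gamma_sasa = NULL, gamma_dist = NULL) {
  stopifnot(n_rbf_sasa >= 2, n_rbf_dist >= 2)
  if (is.null(gamma_sasa)) {
    gamma_sasa <- 1 / (2 * (diff(sasa_range) / (n_rbf_sasa - 1))^2)
  }
  if (is.null(gamma_dist)) {
    gamma_dist <- 1 / (2 * (diff(dist_range) / (n_rbf_dist - 1))^2)
  }
  stopifnot(gamma_sasa > 0, gamma_dist > 0)
  structure(list(d = as.integer(d), use_sasa = isTRUE(use_sasa),
                 sasa_range = sasa_range, dist_range = dist_range,
                 n_rbf_sasa = as.integer(n_rbf_sasa),
                 n_rbf_dist = as.integer(n_rbf_dist),
                 gamma_sasa = gamma_sasa, gamma_dist = gamma_dist),
            class = "feature_config")
}

#' Radial basis function embedding of a scalar
#'
#' Component `k` is `exp(-gamma * (x - mu_k)^2)` with centers `mu_k`
#' equally spaced over `range` (first center at the range start, last at
#' the range end). No normalization; values outside the range simply decay
#' toward zero.
#'
#' @param x numeric vector of scalars to embed.
#' @param range numeric length-2 center range.
#' @param n number of centers (>= 2).
#' @param gamma width; `NULL` uses `1 / (2 * spacing^2)`.
#' @return numeric matrix `[length(x), n]`, each entry in `(0, 1]`.
#' @export
rbf_embed <- function(x, range, n, gamma = NULL) {
  stopifnot(n >= 2)
  mu <- seq(range[1], range[2], length.out = n)
  if (is.null(gamma)) gamma <- 1 / (2 * (mu[2] - mu[1])^2)
  stopifnot(gamma > 0)
  exp(-gamma * outer(x, mu, "-")^2)
}

#' Select the residues lining a pocket candidate
#'
#' Returns the keys of residues whose C-alpha lies within `radius` of ANY
#' pocket vertex (boundary inclusive), in structure order without
#' duplicates.
#'
#' @param s a `protein_structure` with at least one indexed residue.
#' @param p a `pocket_candidate`.
#' @param radius selection radius in Angstrom.
#' @return character vector of residue keys (`chain:resno`).
#' @export
select_pocket_residues <- function(s, p, radius = 10) {
  stopifnot(inherits(s, "protein_structure"), inherits(p, "pocket_candidate"))
  if (nrow(s$residues) == 0) stop("structure has no residues with C-alpha")
  ca <- cbind(s$atoms$x[s$residues$ca_idx], s$atoms$y[s$residues$ca_idx],
              s$atoms$z[s$residues$ca_idx])
  v <- p$vertices
  d2 <- outer(rowSums(ca^2), rowSums(v^2), "+") - 2 * ca %*% t(v)
  hit <- apply(d2, 1, min) <= radius^2 + 1e-9
  keys <- s$residues$reskey[hit]
  if (length(keys) == 0) {
    stop("empty pocket: no residue C-alpha within ", radius,
         " A of any vertex")
  }
  keys
}

# symmetric directed edge list for all pairs within cutoff
edges_from_coords <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2) {
    return(list(edges = matrix(integer(0), 0, 2), dist = numeric(0)))
  }
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff + 1e-9
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  list(edges = unname(cbind(idx[, 1], idx[, 2])), dist = d[idx])
}

#' Build the per-pocket C-alpha graph
#'
#' One node per selected residue (amino-acid token, SASA, C-alpha
#' coordinates); undirected edges between every C-alpha pair within
#' `cutoff` Angstrom (stored as both directed arcs). Residues missing from
#' the SASA table get SASA 0 with a warning.
#'
#' @param s a `protein_structure`.
#' @param residue_keys keys from [select_pocket_residues()].
#' @param sasa a `sasa_table` from [compute_sasa()], or `NULL` to set all
#'   SASA to 0 (SASA-free models).
#' @param cutoff edge distance cutoff in Angstrom.
#' @param label optional logical truth label carried on the graph.
#' @param pocket_id,protein_id optional identifiers carried on the graph.
#' @return object of class `pocket_graph`: list with `aa_token` (integers
#'   in `[0, 20]`), `sasa`, `coords` `[N, 3]`, `edges` `[E, 2]` directed
#'   index pairs, `dist` edge lengths, `residue_keys`, `cutoff`, `label`.
#' @export
build_graph <- function(s, residue_keys, sasa = NULL, cutoff = 25,
                        label = NULL, pocket_id = NULL, protein_id = NULL) {
  stopifnot(length(residue_keys) >= 1)
  ri <- match(residue_keys, s$residues$reskey)
  if (any(is.na(ri))) {
    stop("unknown residue keys: ", paste(residue_keys[is.na(ri)],
                                         collapse = ", "))
  }
  coords <- cbind(s$atoms$x[s$residues$ca_idx[ri]],
                  s$atoms$y[s$residues$ca_idx[ri]],
                  s$atoms$z[s$residues$ca_idx[ri]])
  sv <- rep(0, length(ri))
  if (!is.null(sasa)) {
    m <- match(residue_keys, names(sasa))
    if (any(is.na(m))) {
      warning("no SASA for residue(s) ",
              paste(residue_keys[is.na(m)], collapse = ", "),
              "; using 0")
    }
    sv[!is.na(m)] <- as.numeric(sasa)[m[!is.na(m)]]
  }
  e <- edges_from_coords(coords, cutoff)
  pocket_graph(aa_token = s$residues$token[ri], sasa = sv, coords = coords,
               edges = e$edges, dist = e$dist, residue_keys = residue_keys,
               cutoff = cutoff, label = label, pocket_id = pocket_id,
               protein_id = protein_id)
}

#' Low-level pocket-graph constructor
#'
#' @param aa_token integer tokens in `[0, 20]`.
#' @param sasa per-node SASA (square Angstrom, >= 0).
#' @param coords numeric matrix `[N, 3]`.
#' @param edges integer matrix `[E, 2]` of directed arcs (both directions
#'   present, no self loops); `NULL` to rebuild from `coords` and `cutoff`.
#' @param dist edge lengths matching `edges`.
#' @param residue_keys,cutoff,label,pocket_id,protein_id see [build_graph()].
#' @return object of class `pocket_graph`.
#' @export
pocket_graph <- function(aa_token, sasa, coords, edges = NULL, dist = NULL,
                         residue_keys = NULL, cutoff = 25, label = NULL,
                         pocket_id = NULL, protein_id = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  stopifnot(n >= 1, length(aa_token) == n, length(sasa) == n,
            all(aa_token >= 0 & aa_token <= 20), all(sasa >= 0))
  if (is.null(edges)) {
    e <- edges_from_coords(coords, cutoff)
    edges <- e$edges
    dist <- e$dist
  }
  storage.mode(edges) <- "integer"
  structure(list(aa_token = as.integer(aa_token), sasa = as.numeric(sasa),
                 coords = coords, edges = edges, dist = as.numeric(dist),
                 residue_keys = residue_keys, cutoff = cutoff, label = label,
                 pocket_id = pocket_id, protein_id = protein_id),
            class = "pocket_graph")
}

#' @export
print.pocket_graph <- function(x, ...) {
  cat("pocket_graph:", nrow(x$coords), "nodes,", nrow(x$edges) / 2,
      "undirected edges",
      if (!is.null(x$label)) sprintf("| label %s", x$label) else "", "\n")
  invisible(x)
}

#' Node input features of a pocket graph
#'
#' Emits the raw input blocks consumed by the model's input embedding:
#' the 21-way amino-acid one-hot block, and (when SASA is enabled) the
#' SASA RBF block appended to it.
#'
#' @param g a `pocket_graph`.
#' @param cfg a `feature_config`.
#' @return numeric matrix `[N, 21]` or `[N, 21 + n_rbf_sasa]`.
#' @export
node_features <- function(g, cfg) {
  stopifnot(inherits(g, "pocket_graph"), inherits(cfg, "feature_config"))
  if (any(g$aa_token < 0 | g$aa_token > 20)) {
    stop("amino-acid token outside [0, 20]")
  }
  oh <- matrix(0, length(g$aa_token), 21)
  oh[cbind(seq_along(g$aa_token), g$aa_token + 1L)] <- 1
  if (!cfg$use_sasa) return(oh)
  cbind(oh, rbf_embed(g$sasa, cfg$sasa_range, cfg$n_rbf_sasa,
                      cfg$gamma_sasa))
}

#' Edge input features of a pocket graph
#'
#' Distance RBF vector per directed arc; the two arcs of an undirected
#' edge get identical vectors since only the pair distance enters.
#'
#' @param g a `pocket_graph`.
#' @param cfg a `feature_config`.
#' @return numeric matrix `[E, n_rbf_dist]`.
#' @export
edge_features <- function(g, cfg) {
  stopifnot(inherits(g, "pocket_graph"), inherits(cfg, "feature_config"))
  if (nrow(g$edges) == 0) {
    return(matrix(numeric(0), 0, cfg$n_rbf_dist))
  }
  rbf_embed(g$dist, cfg$dist_range, cfg$n_rbf_dist, cfg$gamma_dist)
}

#' Write a list of pocket graphs to an archive
#'
#' Stores the numeric arrays in a compressed RDS container with a JSON
#' sidecar (`<path>.json`) carrying pocket/protein identifiers, labels and
#' residue keys for inspection without loading R.
#'
#' @param graphs list of `pocket_graph`.
#' @param path output path (conventionally `.rds`).
#' @return invisibly, `path`.
#' @export
write_graph_archive <- function(graphs, path) {
  stopifnot(all(vapply(graphs, inherits, logical(1), "pocket_graph")))
  saveRDS(graphs, path, compress = "gzip")
  meta <- lapply(graphs, function(g) {
    list(protein_id = g$protein_id, pocket_id = g$pocket_id,
         n_nodes = nrow(g$coords), n_edges = nrow(g$edges) / 2,
         label = g$label, residue_keys = g$residue_keys)
  })
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pocket-graph archive written by [write_graph_archive()]
#'
#' @param path archive path.
#' @return list of `pocket_graph`.
#' @export
read_graph_archive <- function(path) {
  graphs <- readRDS(path)
  stopifnot(all(vapply(graphs, inherits, logical(1), "pocket_graph")))
  graphs
}
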