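# Label balancing and on-the-fly training-time augmentation. All
# randomness flows through R's global RNG; callers seed it (the training
# loop derives one seed per epoch from the run seed).

#' Augmentation configuration
#'
#' Defaults are the tuned noise magnitudes: positional noise 0.5 Angstrom,
#' node resampling fraction 0.03, multiplicative SASA noise 0.3. Balancing
#' and noise apply to the training partition only; validation and test
#' data are never augmented.
#'
#' @param sigma_pos standard deviation (Angstrom) of the isotropic
#'   Gaussian added to every coordinate component.
#' @param sigma_node fraction of nodes dropped by the bootstrap resample:
#'   `round((1 - sigma_node) * N)` nodes are drawn with replacement.
#' @param sigma_sasa relative standard deviation of the multiplicative
#'   SASA noise.
#' @param balance oversample true-label pockets to match the false count.
#' @param noise master switch for the three noise operators.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(sigma_pos = 0.5, sigma_node = 0.03,
                           sigma_sasa = 0.3, balance = TRUE, noise = TRUE) {
  stopifnot(sigma_pos >= 0, sigma_node >= 0, sigma_node < 1,
            sigma_sasa >= 0)
  structure(list(sigma_pos = sigma_pos, sigma_node = sigma_node,
                 sigma_sasa = sigma_sasa, balance = isTRUE(balance),
                 noise = isTRUE(noise)),
            class = "augment_config")
}

#' Epoch index multiset with balanced labels
#'
#' Every false-label sample appears exactly once; true-label samples are
#' resampled uniformly with replacement up to the false count, so the
#' returned multiset has exactly equal label counts (size
#' `2 * n_false`). The order is shuffled.
#'
#' @param labels logical vector of pocket labels.
#' @return integer vector of indices into `labels`.
#' @export
balance_labels <- function(labels) {
  labels <- as.logical(labels)
  pos <- which(labels)
  neg <- which(!labels)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("balancing needs at least one true and one false sample")
  }
  idx <- c(neg, pos[sample.int(length(pos), length(neg), replace = TRUE)])
  idx[sample.int(length(idx))]
}

#' Additive Gaussian positional noise
#'
#' @param coords numeric matrix `[N, 3]`.
#' @param sigma_pos noise scale in Angstrom.
#' @return perturbed copy of `coords`.
#' @export
positional_noise <- function(coords, sigma_pos) {
  stopifnot(sigma_pos >= 0)
  if (sigma_pos == 0) return(coords)
  coords + sigma_pos * matrix(stats::rnorm(length(coords)), nrow(coords))
}

#' Multiplicative Gaussian SASA noise
#'
#' `s := s * (1 + sigma_sasa * eps)` with `eps ~ N(0, 1)`, floored at 0.
#'
#' @param sasa_values non-negative numeric vector.
#' @param sigma_sasa relative noise scale.
#' @return perturbed copy of `sasa_values`.
#' @export
sasa_noise <- function(sasa_values, sigma_sasa) {
  stopifnot(sigma_sasa >= 0)
  if (sigma_sasa == 0) return(sasa_values)
  pmax(sasa_values * (1 + sigma_sasa * stats::rnorm(length(sasa_values))), 0)
}

#' Bootstrap node resampling (node dropping/duplication)
#'
#' Draws `round((1 - sigma_node) * N)` node indices uniformly with
#' replacement; duplicated draws become distinct node identities. Edges
#' are rebuilt by the graph's distance cutoff on the resampled node set
#' (self pairs by new index excluded, so duplicate nodes at identical
#' coordinates are connected by a zero-length edge).
#'
#' @param g a `pocket_graph` with at least 2 nodes.
#' @param sigma_node dropped fraction in `[0, 1)`.
#' @return resampled `pocket_graph`.
#' @export
node_resample <- function(g, sigma_node) {
  stopifnot(inherits(g, "pocket_graph"), nrow(g$coords) >= 2,
            sigma_node >= 0, sigma_node < 1)
  n <- nrow(g$coords)
  m <- round((1 - sigma_node) * n)
  if (m < 1) {
    warning("resampled node count < 1; clamping to 1")
    m <- 1L
  }
  idx <- sample.int(n, m, replace = TRUE)
  pocket_graph(aa_token = g$aa_token[idx], sasa = g$sasa[idx],
               coords = g$coords[idx, , drop = FALSE],
               residue_keys = g$residue_keys[idx], cutoff = g$cutoff,
               label = g$label, pocket_id = g$pocket_id,
               protein_id = g$protein_id)
}

#' Apply the full augmentation stack to one pocket graph
#'
#' Node resampling, then positional noise, then SASA noise; the edge set
#' and edge distances are rebuilt from the noised coordinates so the
#' distance features stay consistent. Label and identifiers are preserved.
#'
#' @param g a `pocket_graph`.
#' @param cfg an `augment_config`.
#' @return augmented `pocket_graph`.
#' @export
augment_pocket <- function(g, cfg) {
  stopifnot(inherits(g, "pocket_graph"), inherits(cfg, "augment_config"))
  if (!cfg$noise) return(g)
  if (nrow(g$coords) >= 2) g <- node_resample(g, cfg$sigma_node)
  coords <- positional_noise(g$coords, cfg$sigma_pos)
  sasa <- sasa_noise(g$sasa, cfg$sigma_sasa)
  pocket_graph(aa_token = g$aa_token, sasa = sasa, coords = coords,
               residue_keys = g$residue_keys, cutoff = g$cutoff,
               label = g$label, pocket_id = g$pocket_id,
               protein_id = g$protein_id)
}
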