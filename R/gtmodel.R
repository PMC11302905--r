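# Graph transformer classifier: edge-biased multi-head attention over the
# pocket graph, sum pooling, MLP head, sigmoid score. Forward and backward
# passes are written out explicitly; all operations depend on coordinates
# only through pairwise distances, so the score is E(3) invariant.

#' Model configuration
#'
#' @param L number of stacked graph transformer layers.
#' @param d hidden width.
#' @param H number of attention heads; must divide `d` (head width
#'   `d_head = d / H`).
#' @param ffn_hidden feed-forward hidden width (default `2 * d`).
#' @param dropout_rate dropout probability applied inside each layer during
#'   training.
#' @param clamp_bound attention logits are clamped to
#'   `[-clamp_bound, clamp_bound]` before the softmax for numerical
#'   stability.
#' @param use_sasa include the SASA feature block in the input embedding.
#' @param feature_cfg a [feature_config()]; defaults to one matching `d`.
#' @return object of class `model_config`.
#' @export
model_config <- function(L = 8L, d = 128L, H = 8L, ffn_hidden = 2L * d,
                         dropout_rate = 0.1, clamp_bound = 5,
                         use_sasa = TRUE, feature_cfg = NULL) {
  if (d %% H != 0) stop("d (", d, ") must be divisible by H (", H, ")")
  stopifnot(clamp_bound > 0, dropout_rate >= 0, dropout_rate < 1, L >= 1)
  if (is.null(feature_cfg)) {
    feature_cfg <- feature_config(d = d, use_sasa = use_sasa)
  }
  structure(list(L = as.integer(L), d = as.integer(d), H = as.integer(H),
                 d_head = as.integer(d / H),
                 ffn_hidden = as.integer(ffn_hidden),
                 dropout_rate = dropout_rate, clamp_bound = clamp_bound,
                 use_sasa = isTRUE(use_sasa), feature_cfg = feature_cfg),
            class = "model_config")
}

unif_init <- function(nin, nout = NULL) {
  a <- 1 / sqrt(nin)
  if (is.null(nout)) {
    stats::runif(nin, -a, a)
  } else {
    matrix(stats::runif(nin * nout, -a, a), nin, nout)
  }
}

linear_init <- function(nin, nout) {
  list(W = unif_init(nin, nout), b = stats::runif(nout, -1 / sqrt(nin),
                                                  1 / sqrt(nin)))
}

#' Initialize model parameters
#'
#' Uniform fan-in-scaled initialization (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' for weights and biases), layer-norm gains 1 and offsets 0. Reproducible:
#' the same seed always yields bitwise-identical parameters.
#'
#' @param cfg a `model_config`.
#' @param seed integer RNG seed.
#' @return nested list of parameter arrays (class `model_parameters`).
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(seed)
  d <- cfg$d
  p <- list(E_aa = unif_init(21L, d))
  if (cfg$use_sasa) {
    nin <- d + cfg$feature_cfg$n_rbf_sasa
    li <- linear_init(nin, d)
    p$W_in <- li$W
    p$b_in <- li$b
  }
  p$layers <- lapply(seq_len(cfg$L), function(l) {
    q <- linear_init(d, d); k <- linear_init(d, d); v <- linear_init(d, d)
    e <- linear_init(cfg$feature_cfg$n_rbf_dist, d)
    o <- linear_init(d, d)
    f1 <- linear_init(d, cfg$ffn_hidden)
    f2 <- linear_init(cfg$ffn_hidden, d)
    list(Wq = q$W, bq = q$b, Wk = k$W, bk = k$b, Wv = v$W, bv = v$b,
         We = e$W, be = e$b, Wo = o$W, bo = o$b,
         g1 = rep(1, d), o1 = rep(0, d),
         W1 = f1$W, b1 = f1$b, W2 = f2$W, b2 = f2$b,
         g2 = rep(1, d), o2 = rep(0, d))
  })
  m1 <- linear_init(d, d)
  m2 <- linear_init(d, 1L)
  p$Wm1 <- m1$W; p$bm1 <- m1$b; p$Wm2 <- m2$W; p$bm2 <- m2$b
  class(p) <- "model_parameters"
  p
}

#' Total trainable parameter count
#'
#' @param params a `model_parameters` object.
#' @return integer scalar: number of trainable scalars.
#' @export
count_parameters <- function(params) {
  length(unlist(params, use.names = FALSE))
}

# ---- flatten / unflatten ---------------------------------------------------

par_flatten <- function(p) unlist(p, use.names = FALSE)

par_unflatten <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(sk) {
    if (is.list(sk)) {
      out <- lapply(sk, fill)
      attributes(out) <- attributes(sk)
      return(out)
    }
    n <- length(sk)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(sk))) dim(v) <- dim(sk)
    v
  }
  out <- fill(skeleton)
  stopifnot(pos == length(flat))
  out
}

zero_like <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, zero_like)
    attributes(out) <- attributes(p)
    return(out)
  }
  array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

rowadd <- function(x, b) x + rep(b, each = nrow(x))
colscale <- function(x, g) x * rep(g, each = nrow(x))

# scatter-sum rows of x by integer group into an n-row matrix
scatter_rowsum <- function(x, group, n) {
  rs <- rowsum(x, group)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(rs)), ] <- rs
  out
}


layernorm_fwd <- function(x, g, o, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = rowadd(colscale(xhat, g), o), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dy)
  dxhat <- colscale(dy, g)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), do = colSums(dy))
}

#' Edge-biased attention logit for a single pair
#'
#' The pre-softmax attention logit is the elementwise triple product of the
#' query, key and projected edge vectors summed over the head dimension,
#' scaled by `1/sqrt(d_head)`, then clamped to
#' `[-clamp_bound, clamp_bound]`. With an all-ones edge vector it reduces
#' to the ordinary scaled dot product.
#'
#' @param q,k,b numeric vectors of equal length `d_head`.
#' @param clamp_bound clamp bound (> 0).
#' @return scalar logit in `[-clamp_bound, clamp_bound]`.
#' @export
attention_logits <- function(q, k, b, clamp_bound = 5) {
  if (length(q) != length(k) || length(q) != length(b)) {
    stop("q, k, b must have equal length")
  }
  z <- sum(q * k * b) / sqrt(length(q))
  min(max(z, -clamp_bound), clamp_bound)
}

# forward through one graph transformer layer, with cache for backprop
layer_fwd <- function(f, efeat, edges, lp, cfg, training = FALSE) {
  n <- nrow(f)
  d <- cfg$d
  p <- cfg$dropout_rate
  drop1 <- drop2 <- NULL

  q <- rowadd(f %*% lp$Wq, lp$bq)
  k <- rowadd(f %*% lp$Wk, lp$bk)
  v <- rowadd(f %*% lp$Wv, lp$bv)
  if (nrow(edges) > 0) {
    src <- edges[, 1]
    dst <- edges[, 2]
    B <- rowadd(efeat %*% lp$We, lp$be)
    att <- edge_attention_fwd_cpp(q, k, v, B, src, dst, cfg$H,
                                  cfg$clamp_bound)
    zraw <- att$zraw
    a <- att$a
    O <- att$O
  } else {
    src <- dst <- integer(0)
    B <- zraw <- a <- NULL
    O <- matrix(0, n, d)
  }
  if (training && p > 0) {
    drop1 <- matrix((stats::runif(n * d) >= p) / (1 - p), n, d)
    Od <- O * drop1
  } else {
    Od <- O
  }
  attn <- rowadd(Od %*% lp$Wo, lp$bo)
  res1 <- attn + f
  ln1 <- layernorm_fwd(res1, lp$g1, lp$o1)
  fh <- ln1$y
  h1pre <- rowadd(fh %*% lp$W1, lp$b1)
  h1 <- pmax(h1pre, 0)
  if (training && p > 0) {
    drop2 <- matrix((stats::runif(n * cfg$ffn_hidden) >= p) / (1 - p),
                    n, cfg$ffn_hidden)
    h1d <- h1 * drop2
  } else {
    h1d <- h1
  }
  f2 <- rowadd(h1d %*% lp$W2, lp$b2)
  res2 <- f2 + fh
  ln2 <- layernorm_fwd(res2, lp$g2, lp$o2)
  list(out = ln2$y,
       cache = list(f = f, q = q, k = k, v = v, B = B, zraw = zraw, a = a,
                    src = src, dst = dst, O = O, Od = Od, drop1 = drop1,
                    ln1 = ln1, fh = fh, h1pre = h1pre, h1 = h1,
                    drop2 = drop2, h1d = h1d, efeat = efeat, ln2 = ln2))
}

layer_bwd <- function(dout, cache, lp, cfg) {
  n <- nrow(dout)
  g <- list()

  lb2 <- layernorm_bwd(dout, cache$ln2, lp$g2)
  g$g2 <- lb2$dg; g$o2 <- lb2$do
  dres2 <- lb2$dx
  df2 <- dres2
  g$W2 <- crossprod(cache$h1d, df2)
  g$b2 <- colSums(df2)
  dh1d <- tcrossprod(df2, lp$W2)
  dh1 <- if (is.null(cache$drop2)) dh1d else dh1d * cache$drop2
  dh1pre <- dh1 * (cache$h1pre > 0)
  g$W1 <- crossprod(cache$fh, dh1pre)
  g$b1 <- colSums(dh1pre)
  dfh <- tcrossprod(dh1pre, lp$W1) + dres2

  lb1 <- layernorm_bwd(dfh, cache$ln1, lp$g1)
  g$g1 <- lb1$dg; g$o1 <- lb1$do
  dres1 <- lb1$dx
  dattn <- dres1
  g$Wo <- crossprod(cache$Od, dattn)
  g$bo <- colSums(dattn)
  dOd <- tcrossprod(dattn, lp$Wo)
  dO <- if (is.null(cache$drop1)) dOd else dOd * cache$drop1
  df <- dres1

  if (length(cache$src) > 0) {
    ab <- edge_attention_bwd_cpp(dO, cache$a, cache$zraw, cache$q,
                                 cache$k, cache$v, cache$B, cache$src,
                                 cache$dst, cfg$H, cfg$clamp_bound)
    dq <- ab$dq
    dk <- ab$dk
    dv <- ab$dv
    g$We <- crossprod(cache$efeat, ab$dB)
    g$be <- colSums(ab$dB)
  } else {
    d <- cfg$d
    dq <- dk <- dv <- matrix(0, n, d)
    g$We <- matrix(0, cfg$feature_cfg$n_rbf_dist, d)
    g$be <- rep(0, d)
  }
  g$Wq <- crossprod(cache$f, dq); g$bq <- colSums(dq)
  g$Wk <- crossprod(cache$f, dk); g$bk <- colSums(dk)
  g$Wv <- crossprod(cache$f, dv); g$bv <- colSums(dv)
  df <- df + tcrossprod(dq, lp$Wq) + tcrossprod(dk, lp$Wk) +
    tcrossprod(dv, lp$Wv)
  list(df = df, grads = g[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "We", "be",
                            "Wo", "bo", "g1", "o1", "W1", "b1", "W2", "b2",
                            "g2", "o2")])
}

#' One graph transformer layer (functional form)
#'
#' Runs edge-biased multi-head attention restricted to the graph's edges
#' (per-head softmax over each node's neighbor set, clamped logits),
#' output projection, dropout, residual and layer normalization, then the
#' feed-forward block with its own residual and normalization. Nodes with
#' no neighbors get a zero attention output and survive through the
#' residual path. Edge features are read, never updated.
#'
#' @param node_feats numeric matrix `[N, d]`.
#' @param edge_feats numeric matrix `[E, n_rbf_dist]` aligned with `edges`.
#' @param edges integer matrix `[E, 2]` of directed arcs.
#' @param layer_params one element of `params$layers`.
#' @param cfg a `model_config`.
#' @param training enable dropout.
#' @return numeric matrix `[N, d]` of updated node features.
#' @export
gt_layer <- function(node_feats, edge_feats, edges, layer_params, cfg,
                     training = FALSE) {
  layer_fwd(node_feats, edge_feats, edges, layer_params, cfg, training)$out
}

embed_fwd <- function(nf, params, cfg) {
  oh <- nf[, 1:21, drop = FALSE]
  aa <- oh %*% params$E_aa
  if (!cfg$use_sasa) {
    return(list(f0 = aa, oh = oh, X = NULL))
  }
  X <- cbind(aa, nf[, -(1:21), drop = FALSE])
  list(f0 = rowadd(X %*% params$W_in, params$b_in), oh = oh, X = X)
}

forward_cached <- function(g, params, cfg, training = FALSE) {
  stopifnot(inherits(g, "pocket_graph"))
  nf <- node_features(g, cfg$feature_cfg)
  ef <- edge_features(g, cfg$feature_cfg)
  emb <- embed_fwd(nf, params, cfg)
  f <- emb$f0
  caches <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    step <- layer_fwd(f, ef, g$edges, params$layers[[l]], cfg, training)
    f <- step$out
    caches[[l]] <- step$cache
  }
  hvec <- colSums(f)
  m1 <- as.numeric(hvec %*% params$Wm1) + params$bm1
  r1 <- pmax(m1, 0)
  logit <- sum(r1 * params$Wm2[, 1]) + params$bm2[1]
  list(score = 1 / (1 + exp(-logit)), logit = logit, fL = f, hvec = hvec,
       m1 = m1, r1 = r1, emb = emb, caches = caches, nrow = nrow(f))
}

#' Score a pocket graph
#'
#' Embeds the node inputs, applies the stacked graph transformer layers,
#' sum-pools the node features, and maps the pooled vector through a
#' two-layer ReLU MLP and a sigmoid. Dropout is active only when
#' `training = TRUE`.
#'
#' @param g a `pocket_graph`.
#' @param params `model_parameters` from [init_model()].
#' @param cfg the matching `model_config`.
#' @param training enable dropout.
#' @return scalar score strictly inside `(0, 1)`.
#' @export
forward <- function(g, params, cfg, training = FALSE) {
  forward_cached(g, params, cfg, training)$score
}

#' Binary cross-entropy loss
#'
#' `-y* log(y) - (1 - y*) log(1 - y)`; scores are nudged away from 0/1 by
#' machine epsilon so the loss stays finite.
#'
#' @param y predicted score in `(0, 1)`.
#' @param y_star truth label, 0 or 1 (logicals accepted).
#' @return non-negative scalar.
#' @export
bce_loss <- function(y, y_star) {
  y_star <- as.numeric(y_star)
  y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
  -y_star * log(y) - (1 - y_star) * log1p(-y)
}

# numerically stable BCE straight from the pre-sigmoid logit
bce_loss_logit <- function(z, y_star) {
  y_star <- as.numeric(y_star)
  pmax(z, 0) - z * y_star + log1p(exp(-abs(z)))
}

#' Loss and parameter gradients for one labeled graph
#'
#' Full forward pass plus hand-derived reverse-mode gradients of the
#' binary cross-entropy with respect to every trainable array. The loss is
#' computed from the pre-sigmoid logit in log-sum-exp form, so it is
#' finite for any parameter values.
#'
#' @param g a labeled `pocket_graph` (or pass `y_star`).
#' @param params,cfg model parameters and configuration.
#' @param y_star truth label; defaults to `g$label`.
#' @param training enable dropout during the pass.
#' @return list with `loss`, `score` and `grads` (same shape as `params`).
#' @export
model_grad <- function(g, params, cfg, y_star = NULL, training = FALSE) {
  if (is.null(y_star)) y_star <- g$label
  stopifnot(!is.null(y_star))
  fc <- forward_cached(g, params, cfg, training)
  loss <- bce_loss_logit(fc$logit, y_star)
  dlogit <- fc$score - as.numeric(y_star)

  gr <- list()
  gr$Wm2 <- matrix(fc$r1 * dlogit, ncol = 1)
  gr$bm2 <- dlogit
  dr1 <- params$Wm2[, 1] * dlogit
  dm1 <- dr1 * (fc$m1 > 0)
  gr$Wm1 <- outer(fc$hvec, dm1)
  gr$bm1 <- dm1
  dhvec <- as.numeric(params$Wm1 %*% dm1)
  df <- matrix(dhvec, fc$nrow, cfg$d, byrow = TRUE)

  glayers <- vector("list", cfg$L)
  for (l in rev(seq_len(cfg$L))) {
    lb <- layer_bwd(df, fc$caches[[l]], params$layers[[l]], cfg)
    df <- lb$df
    glayers[[l]] <- lb$grads
  }

  emb <- fc$emb
  if (cfg$use_sasa) {
    gr$W_in <- t(emb$X) %*% df
    gr$b_in <- colSums(df)
    dX <- df %*% t(params$W_in)
    gr$E_aa <- t(emb$oh) %*% dX[, 1:cfg$d, drop = FALSE]
  } else {
    gr$E_aa <- t(emb$oh) %*% df
  }
  out <- list(E_aa = gr$E_aa)
  if (cfg$use_sasa) {
    out$W_in <- gr$W_in
    out$b_in <- gr$b_in
  }
  out$layers <- glayers
  out$Wm1 <- gr$Wm1; out$bm1 <- gr$bm1; out$Wm2 <- gr$Wm2; out$bm2 <- gr$bm2
  list(loss = loss, score = fc$score, grads = out)
}

# ---- packed batches --------------------------------------------------------
# A batch of graphs is packed into one disjoint block-graph (node arrays
# concatenated, edge indices offset). Every per-layer operation is local
# to nodes and edges, so the single-graph layer code runs unchanged on
# the pack; only pooling and the MLP head are graph-aware.

pack_graphs <- function(graphs, fcfg) {
  nf <- lapply(graphs, node_features, cfg = fcfg)
  ef <- lapply(graphs, edge_features, cfg = fcfg)
  nn <- vapply(graphs, function(g) nrow(g$coords), integer(1))
  off <- cumsum(c(0L, nn[-length(nn)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0) return(matrix(integer(0), 0, 2))
    e + off[i]
  }))
  list(nf = do.call(rbind, nf), ef = do.call(rbind, ef), edges = edges,
       graph_id = rep(seq_along(graphs), nn), n_graphs = length(graphs))
}

batch_forward_cached <- function(pack, params, cfg, training = FALSE) {
  emb <- embed_fwd(pack$nf, params, cfg)
  f <- emb$f0
  caches <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    step <- layer_fwd(f, pack$ef, pack$edges, params$layers[[l]], cfg,
                      training)
    f <- step$out
    caches[[l]] <- step$cache
  }
  hmat <- rowsum(f, pack$graph_id)
  M1 <- rowadd(hmat %*% params$Wm1, params$bm1)
  R1 <- pmax(M1, 0)
  logits <- as.numeric(R1 %*% params$Wm2) + params$bm2[1]
  list(scores = 1 / (1 + exp(-logits)), logits = logits, fL = f,
       hmat = hmat, M1 = M1, R1 = R1, emb = emb, caches = caches)
}

# scores for a list of graphs via one packed pass (no dropout)
batch_scores <- function(graphs, params, cfg, pack = NULL) {
  if (is.null(pack)) pack <- pack_graphs(graphs, cfg$feature_cfg)
  batch_forward_cached(pack, params, cfg, training = FALSE)$scores
}

# mean-BCE loss and gradients over a packed batch
batch_grad <- function(pack, params, cfg, y_star, training = TRUE) {
  fc <- batch_forward_cached(pack, params, cfg, training)
  y <- as.numeric(y_star)
  B <- pack$n_graphs
  loss <- mean(bce_loss_logit(fc$logits, y))
  dlogit <- (fc$scores - y) / B

  gr <- list()
  gr$Wm2 <- crossprod(fc$R1, matrix(dlogit))
  gr$bm2 <- sum(dlogit)
  dR1 <- outer(dlogit, params$Wm2[, 1])
  dM1 <- dR1 * (fc$M1 > 0)
  gr$Wm1 <- crossprod(fc$hmat, dM1)
  gr$bm1 <- colSums(dM1)
  dh <- tcrossprod(dM1, params$Wm1)
  df <- dh[pack$graph_id, , drop = FALSE]

  glayers <- vector("list", cfg$L)
  for (l in rev(seq_len(cfg$L))) {
    lb <- layer_bwd(df, fc$caches[[l]], params$layers[[l]], cfg)
    df <- lb$df
    glayers[[l]] <- lb$grads
  }
  emb <- fc$emb
  if (cfg$use_sasa) {
    gr$W_in <- crossprod(emb$X, df)
    gr$b_in <- colSums(df)
    dX <- tcrossprod(df, params$W_in)
    gr$E_aa <- crossprod(emb$oh, dX[, 1:cfg$d, drop = FALSE])
  } else {
    gr$E_aa <- crossprod(emb$oh, df)
  }
  out <- list(E_aa = gr$E_aa)
  if (cfg$use_sasa) {
    out$W_in <- gr$W_in
    out$b_in <- gr$b_in
  }
  out$layers <- glayers
  out$Wm1 <- gr$Wm1; out$bm1 <- gr$bm1; out$Wm2 <- gr$Wm2
  out$bm2 <- gr$bm2
  list(loss = loss, scores = fc$scores, grads = out)
}

# ---- checkpoints -----------------------------------------------------------

serialize_config <- function(cfg) {
  out <- unclass(cfg)
  out$feature_cfg <- unclass(out$feature_cfg)
  out
}

deserialize_config <- function(lst) {
  fc <- lst$feature_cfg
  feature_cfg <- feature_config(d = fc$d, use_sasa = fc$use_sasa,
                                sasa_range = as.numeric(fc$sasa_range),
                                dist_range = as.numeric(fc$dist_range),
                                n_rbf_sasa = fc$n_rbf_sasa,
                                n_rbf_dist = fc$n_rbf_dist,
                                gamma_sasa = fc$gamma_sasa,
                                gamma_dist = fc$gamma_dist)
  model_config(L = lst$L, d = lst$d, H = lst$H, ffn_hidden = lst$ffn_hidden,
               dropout_rate = lst$dropout_rate,
               clamp_bound = lst$clamp_bound, use_sasa = lst$use_sasa,
               feature_cfg = feature_cfg)
}

#' Save model parameters (or a cross-validation ensemble) to JSON
#'
#' @param params a `model_parameters` object, or a list of them (ensemble).
#' @param cfg the shared `model_config`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(params, cfg, path) {
  members <- if (inherits(params, "model_parameters")) list(params) else params
  stopifnot(all(vapply(members, inherits, logical(1), "model_parameters")))
  obj <- list(format_version = 1L, config = serialize_config(cfg),
              n_members = length(members),
              members = lapply(members, par_flatten))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return list with `config` (a `model_config`) and `members` (list of
#'   `model_parameters`; length 1 for a single model).
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported checkpoint format version")
  }
  cfg <- deserialize_config(obj$config)
  skeleton <- init_model(cfg, seed = 0L)
  flats <- obj$members
  if (is.matrix(flats)) flats <- lapply(seq_len(nrow(flats)),
                                        function(i) flats[i, ])
  members <- lapply(flats, function(fl) {
    p <- par_unflatten(as.numeric(fl), skeleton)
    class(p) <- "model_parameters"
    p
  })
  list(config = cfg, members = members)
}
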