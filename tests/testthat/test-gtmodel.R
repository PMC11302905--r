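test_that("configuration constraints are enforced", {
  expect_error(model_config(d = 30, H = 8), "divisible")
  cfg <- model_config(L = 2, d = 32, H = 8)
  expect_equal(cfg$d_head, 4L)
  expect_equal(cfg$ffn_hidden, 64L)
})

test_that("initialization is reproducible and sized by configuration", {
  cfg <- model_config(L = 2, d = 32, H = 8)
  p1 <- init_model(cfg, seed = 42)
  p2 <- init_model(cfg, seed = 42)
  expect_identical(p1, p2)
  p3 <- init_model(cfg, seed = 43)
  expect_false(identical(p1, p3))
  expect_identical(count_parameters(p1), count_parameters(p3))
})

test_that("parameter counts reproduce the published model sizes", {
  base <- init_model(model_config(L = 8, d = 128, H = 8, use_sasa = TRUE))
  expect_lt(abs(count_parameters(base) / 1.28e6 - 1), 0.10)
  big <- init_model(model_config(L = 12, d = 256, H = 8, use_sasa = TRUE))
  expect_lt(abs(count_parameters(big) / 7.34e6 - 1), 0.10)
})

test_that("attention logits are a scaled clamped triple product", {
  set.seed(5)
  q <- rnorm(4); k <- rnorm(4)
  # all-ones edge projection reduces to the scaled dot product
  expect_equal(attention_logits(q, k, rep(1, 4)),
               sum(q * k) / 2, tolerance = 1e-12)
  # clamping at +/- 5
  expect_equal(attention_logits(rep(10, 4), rep(10, 4), rep(1, 4)), 5)
  expect_equal(attention_logits(rep(10, 4), rep(-10, 4), rep(1, 4)), -5)
  # explicit loop oracle
  b <- rnorm(4)
  acc <- 0
  for (i in 1:4) acc <- acc + q[i] * k[i] * b[i]
  expect_equal(attention_logits(q, k, b), max(min(acc / 2, 5), -5))
  expect_error(attention_logits(q, k, rnorm(3)), "length")
})

test_that("a layer with zero attention weights is the normalized residual", {
  set.seed(6)
  cfg <- model_config(L = 1, d = 8, H = 2, dropout_rate = 0,
                      feature_cfg = feature_config(d = 8))
  params <- init_model(cfg, seed = 1)
  lp <- params$layers[[1]]
  lp$Wv[] <- 0; lp$bv[] <- 0; lp$Wo[] <- 0; lp$bo[] <- 0
  lp$W1[] <- 0; lp$b1[] <- 0; lp$W2[] <- 0; lp$b2[] <- 0
  g <- rand_pocket_graph(5)
  f <- matrix(rnorm(5 * 8), 5)
  ef <- edge_features(g, cfg$feature_cfg)
  out <- gt_layer(f, ef, g$edges, lp, cfg)
  ln <- function(x) t(apply(x, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
  }))
  expect_equal(out, ln(ln(f)), tolerance = 1e-12)
})

test_that("sparse edge attention equals the dense masked reference", {
  set.seed(7)
  cfg <- model_config(L = 1, d = 16, H = 4, dropout_rate = 0,
                      feature_cfg = feature_config(d = 16))
  for (rep in 1:12) {
    n <- sample(2:10, 1)
    g <- rand_pocket_graph(n, spread = 12)
    params <- init_model(cfg, seed = rep)
    lp <- params$layers[[1]]
    f <- matrix(rnorm(n * 16), n)
    ef <- edge_features(g, cfg$feature_cfg)
    got <- gt_layer(f, ef, g$edges, lp, cfg)
    want <- dense_layer_reference(f, ef, g$edges, lp, cfg)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("scores are sigmoid-bounded and exactly 0.5 for a zero head", {
  set.seed(8)
  cfg <- model_config(L = 2, d = 16, H = 4, dropout_rate = 0,
                      feature_cfg = feature_config(d = 16))
  params <- init_model(cfg, seed = 1)
  g <- rand_pocket_graph(7)
  sc <- forward(g, params, cfg)
  expect_true(sc > 0 && sc < 1)
  params$Wm2[] <- 0; params$bm2[] <- 0
  expect_equal(forward(g, params, cfg), 0.5)
})

test_that("the score is E(3) and node-permutation invariant", {
  set.seed(9)
  cfg <- model_config(L = 2, d = 16, H = 4, dropout_rate = 0,
                      feature_cfg = feature_config(d = 16))
  params <- init_model(cfg, seed = 2)
  g <- rand_pocket_graph(12)
  s0 <- forward(g, params, cfg)
  for (rep in 1:10) {
    g2 <- transform_graph(g, rand_rigid(reflect = rep == 10))
    expect_equal(forward(g2, params, cfg), s0, tolerance = 1e-8)
  }
  perm <- sample(12)
  gp <- pocket_graph(aa_token = g$aa_token[perm], sasa = g$sasa[perm],
                     coords = g$coords[perm, ], cutoff = g$cutoff,
                     label = g$label)
  expect_equal(forward(gp, params, cfg), s0, tolerance = 1e-5)
})

test_that("isolated nodes survive through the residual path", {
  cfg <- model_config(L = 2, d = 16, H = 4, dropout_rate = 0,
                      feature_cfg = feature_config(d = 16))
  params <- init_model(cfg, seed = 3)
  # 3 nodes, two within 25 A, one 500 A away (no edges to it)
  g <- pocket_graph(aa_token = c(1L, 2L, 3L), sasa = c(10, 20, 30),
                    coords = rbind(c(0, 0, 0), c(5, 0, 0), c(500, 0, 0)),
                    cutoff = 25)
  expect_equal(nrow(g$edges), 2)
  sc <- forward(g, params, cfg)
  expect_true(is.finite(sc) && sc > 0 && sc < 1)
  # single isolated node: no edges at all
  g1 <- pocket_graph(aa_token = 4L, sasa = 50, coords = matrix(0, 1, 3))
  expect_true(is.finite(forward(g1, params, cfg)))
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0.9, 1), -log(0.9), tolerance = 1e-12)
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-8)
  # logit form agrees on moderate logits and survives extreme ones
  z <- c(-3, -1, 0, 1, 3)
  y <- 1 / (1 + exp(-z))
  expect_equal(pocketgt:::bce_loss_logit(z, 1), bce_loss(y, 1),
               tolerance = 1e-9)
  expect_equal(pocketgt:::bce_loss_logit(z, 0), bce_loss(y, 0),
               tolerance = 1e-9)
  expect_true(all(is.finite(pocketgt:::bce_loss_logit(c(-1e4, 1e4), 0))))
})

test_that("analytic gradients match central finite differences", {
  set.seed(10)
  cfg <- model_config(L = 2, d = 8, H = 2, dropout_rate = 0,
                      feature_cfg = feature_config(d = 8))
  g <- rand_pocket_graph(4)
  params <- init_model(cfg, seed = 5)
  mg <- model_grad(g, params, cfg, y_star = 1)
  fl <- pocketgt:::par_flatten(params)
  gfl <- pocketgt:::par_flatten(mg$grads)
  idx <- sample(length(fl), 150)
  h <- 1e-5
  num <- vapply(idx, function(i) {
    fp <- fl; fp[i] <- fp[i] + h
    fm <- fl; fm[i] <- fm[i] - h
    pp <- pocketgt:::par_unflatten(fp, params)
    pm <- pocketgt:::par_unflatten(fm, params)
    lp <- pocketgt:::bce_loss_logit(
      pocketgt:::forward_cached(g, pp, cfg)$logit, 1)
    lm <- pocketgt:::bce_loss_logit(
      pocketgt:::forward_cached(g, pm, cfg)$logit, 1)
    (lp - lm) / (2 * h)
  }, numeric(1))
  rel <- abs(num - gfl[idx]) / pmax(abs(num) + abs(gfl[idx]), 1e-6)
  expect_lt(max(rel), 1e-3)
})

test_that("packed batches reproduce per-graph scores and gradients", {
  set.seed(11)
  cfg <- model_config(L = 2, d = 16, H = 4, dropout_rate = 0,
                      feature_cfg = feature_config(d = 16))
  params <- init_model(cfg, seed = 6)
  graphs <- lapply(c(1, 5, 9, 14), rand_pocket_graph)
  labs <- vapply(graphs, `[[`, logical(1), "label")
  pk <- pocketgt:::pack_graphs(graphs, cfg$feature_cfg)
  bg <- pocketgt:::batch_grad(pk, params, cfg, labs, training = FALSE)
  single <- vapply(graphs, forward, numeric(1), params = params, cfg = cfg)
  expect_equal(bg$scores, single, tolerance = 1e-12)
  ref <- Reduce(`+`, lapply(seq_along(graphs), function(i) {
    pocketgt:::par_flatten(
      model_grad(graphs[[i]], params, cfg, y_star = labs[i])$grads)
  })) / length(graphs)
  expect_lt(max(abs(pocketgt:::par_flatten(bg$grads) - ref)), 1e-10)
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- model_config(L = 1, d = 16, H = 4,
                      feature_cfg = feature_config(d = 16))
  params <- init_model(cfg, seed = 9)
  p <- tempfile(fileext = ".json")
  save_checkpoint(params, cfg, p)
  back <- load_checkpoint(p)
  expect_equal(back$config$d, 16L)
  expect_length(back$members, 1)
  g <- { set.seed(1); rand_pocket_graph(6) }
  expect_equal(forward(g, back$members[[1]], back$config),
               forward(g, params, cfg), tolerance = 1e-12)
  # ensembles hold several members
  save_checkpoint(list(params, params), cfg, p)
  expect_length(load_checkpoint(p)$members, 2)
})
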