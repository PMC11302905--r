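# Optimization loop, cross-validation, ensemble prediction and metrics.

#' Training configuration
#'
#' Defaults follow the training recipe: Adam, cosine annealing with a
#' 25-epoch linear warm-up to a maximum learning rate of 2e-4, batch size
#' 128, 300 epochs, 5-fold cross-validation with best-validation-PR-AUC
#' checkpointing.
#'
#' @param model a `model_config`.
#' @param augment an `augment_config`.
#' @param max_lr maximum learning rate.
#' @param warmup_epochs linear warm-up length (epochs).
#' @param total_epochs total training epochs.
#' @param batch_size graphs per optimizer step.
#' @param n_folds cross-validation folds.
#' @param seed root RNG seed for the run.
#' @return object of class `train_config`.
#' @export
train_config <- function(model, augment = augment_config(),
                         max_lr = 2e-4, warmup_epochs = 25L,
                         total_epochs = 300L, batch_size = 128L,
                         n_folds = 5L, seed = 1L) {
  stopifnot(inherits(model, "model_config"),
            inherits(augment, "augment_config"),
            warmup_epochs < total_epochs, n_folds >= 2, max_lr > 0)
  structure(list(model = model, augment = augment, max_lr = max_lr,
                 warmup_epochs = as.integer(warmup_epochs),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule: linear warm-up then cosine decay
#'
#' Epochs are 0-based. The rate ramps linearly from `max_lr / warmup` at
#' epoch 0 to `max_lr` at epoch `warmup`, then follows a half cosine down
#' to 0 at `total_epochs`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param cfg a `train_config` (or any list with `max_lr`,
#'   `warmup_epochs`, `total_epochs`).
#' @return learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (any(epoch < 0 | epoch >= cfg$total_epochs)) {
    stop("epoch out of range [0, ", cfg$total_epochs, ")")
  }
  ifelse(epoch < cfg$warmup_epochs,
         cfg$max_lr * (epoch + 1) / cfg$warmup_epochs,
         cfg$max_lr * 0.5 *
           (1 + cos(pi * (epoch - cfg$warmup_epochs) /
                      (cfg$total_epochs - cfg$warmup_epochs))))
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, flat, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(flat = flat - lr * mhat / (sqrt(vhat) + eps), state = state)
}

graph_labels <- function(graphs) {
  vapply(graphs, function(g) isTRUE(g$label), logical(1))
}

score_graphs <- function(graphs, params, cfg) {
  vapply(graphs, forward, numeric(1), params = params, cfg = cfg,
         training = FALSE)
}

#' Train one cross-validation fold
#'
#' Minimizes the mean batch binary cross-entropy over the (optionally
#' balanced and noise-augmented) training stream with Adam under the
#' warm-up/cosine schedule. After every epoch the validation partition is
#' scored without any augmentation; the parameters with the highest
#' validation PR-AUC are kept (ties keep the earlier epoch).
#'
#' @param graphs list of labeled `pocket_graph`.
#' @param train_idx,valid_idx disjoint index vectors into `graphs`; both
#'   partitions must contain both labels.
#' @param cfg a `train_config`.
#' @param seed RNG seed for this fold (initialization, balancing, noise).
#' @param verbose print per-epoch progress.
#' @return list with `params` (best checkpoint), `best_epoch`,
#'   `best_pr_auc`, `history` (per-epoch data.frame: epoch, lr, train
#'   loss, validation PR-AUC/ROC-AUC) and `final_params`.
#' @export
train_fold <- function(graphs, train_idx, valid_idx, cfg,
                       seed = cfg$seed, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"),
            length(intersect(train_idx, valid_idx)) == 0)
  lab <- graph_labels(graphs)
  if (!any(lab[valid_idx]) || all(lab[valid_idx])) {
    stop("validation partition must contain both labels")
  }
  if (!any(lab[train_idx]) || all(lab[train_idx])) {
    stop("training partition must contain both labels")
  }
  params <- init_model(cfg$model, seed = seed)
  flat <- par_flatten(params)
  opt <- adam_init(length(flat))
  vlab <- lab[valid_idx]
  vpack <- pack_graphs(graphs[valid_idx], cfg$model$feature_cfg)
  best <- list(pr = -Inf, epoch = NA_integer_, flat = flat)
  hist <- data.frame()

  for (epoch in seq_len(cfg$total_epochs) - 1L) {
    set.seed(seed + 7919L * (epoch + 1L))
    lr <- lr_schedule(epoch, cfg)
    idx <- if (cfg$augment$balance) {
      train_idx[balance_labels(lab[train_idx])]
    } else {
      train_idx[sample.int(length(train_idx))]
    }
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      gl <- graphs[b]
      if (cfg$augment$noise) {
        gl <- lapply(gl, augment_pocket, cfg = cfg$augment)
      }
      pk <- pack_graphs(gl, cfg$model$feature_cfg)
      bg <- batch_grad(pk, params, cfg$model, lab[b], training = TRUE)
      st <- adam_step(opt, flat, par_flatten(bg$grads), lr)
      flat <- st$flat
      opt <- st$state
      params <- par_unflatten(flat, params)
      ep_loss <- ep_loss + bg$loss * length(b)
    }
    ep_loss <- ep_loss / length(idx)
    vs <- batch_scores(NULL, params, cfg$model, pack = vpack)
    met <- pr_roc_auc(vs, vlab)
    if (met$pr_auc > best$pr) {
      best <- list(pr = met$pr_auc, epoch = epoch, flat = flat)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = ep_loss,
                                   valid_pr_auc = met$pr_auc,
                                   valid_roc_auc = met$roc_auc))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val PR %.4f ROC %.4f",
                      epoch, lr, ep_loss, met$pr_auc, met$roc_auc))
    }
  }
  best_params <- par_unflatten(best$flat, params)
  class(best_params) <- "model_parameters"
  list(params = best_params, best_epoch = best$epoch,
       best_pr_auc = best$pr, history = hist, final_params = params)
}

#' Seeded k-fold split
#'
#' @param n number of pockets.
#' @param k folds.
#' @param seed RNG seed.
#' @return integer vector of fold assignments in `1..k` (a true partition
#'   with near-equal part sizes).
#' @export
make_folds <- function(n, k, seed = 1L) {
  stopifnot(n >= k)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation training
#'
#' Randomly partitions the pockets into `cfg$n_folds` parts; each fold is
#' trained on the remaining parts with its part as validation, yielding
#' one best checkpoint per fold.
#'
#' @param graphs list of labeled `pocket_graph`.
#' @param cfg a `train_config`.
#' @param verbose print progress.
#' @return list with `members` (per-fold best `model_parameters`),
#'   `fold_assignment`, and `folds` (the full per-fold [train_fold()]
#'   results).
#' @export
cross_validate <- function(graphs, cfg, verbose = FALSE) {
  n <- length(graphs)
  if (n < cfg$n_folds) stop("need at least n_folds pockets")
  assign <- make_folds(n, cfg$n_folds, cfg$seed)
  folds <- lapply(seq_len(cfg$n_folds), function(f) {
    if (verbose) message("fold ", f, "/", cfg$n_folds)
    train_fold(graphs, which(assign != f), which(assign == f), cfg,
               seed = cfg$seed + f, verbose = verbose)
  })
  list(members = lapply(folds, `[[`, "params"), fold_assignment = assign,
       folds = folds)
}

#' Ensemble prediction over pocket graphs
#'
#' The score of a pocket is the arithmetic mean of the member models'
#' sigmoid outputs; ranks are assigned within each protein by descending
#' score, ties broken by pocket identifier order.
#'
#' @param members list of `model_parameters` (e.g. the 5 fold models).
#' @param graphs list of `pocket_graph` with `protein_id`/`pocket_id` set.
#' @param cfg the shared `model_config`.
#' @return data.frame with columns `protein_id`, `pocket_id`, `score`,
#'   `rank`.
#' @export
ensemble_predict <- function(members, graphs, cfg) {
  stopifnot(length(members) >= 1)
  pk <- pack_graphs(graphs, cfg$feature_cfg)
  scores <- rowMeans(vapply(members, function(p) {
    batch_scores(NULL, p, cfg, pack = pk)
  }, numeric(length(graphs))))
  if (length(graphs) == 1) scores <- mean(scores)
  df <- data.frame(
    protein_id = vapply(graphs, function(g) {
      if (is.null(g$protein_id)) "protein" else as.character(g$protein_id)
    }, character(1)),
    pocket_id = vapply(graphs, function(g) {
      if (is.null(g$pocket_id)) NA_character_ else as.character(g$pocket_id)
    }, character(1)),
    score = scores, stringsAsFactors = FALSE
  )
  df$rank <- NA_integer_
  for (pid in unique(df$protein_id)) {
    sel <- df$protein_id == pid
    ord <- order(-df$score[sel], df$pocket_id[sel])
    r <- integer(sum(sel))
    r[ord] <- seq_len(sum(sel))
    df$rank[sel] <- r
  }
  df
}

#' Precision-recall and ROC areas
#'
#' PR-AUC by step-wise interpolation of the precision-recall curve over
#' all distinct score thresholds (average-precision form); ROC-AUC as the
#' rank statistic (probability a positive outscores a negative, ties
#' half-credited), equivalent to the trapezoidal area.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels; both classes must be present.
#' @return list with `pr_auc` and `roc_auc`.
#' @export
pr_roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0 || N == 0) stop("both classes must be present")

  # ROC-AUC: Mann-Whitney with average ranks
  r <- rank(scores)
  roc <- (sum(r[labels]) - P * (P + 1) / 2) / (P * N)

  # PR-AUC: step-wise sum over distinct thresholds, descending
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie block
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  drec <- diff(c(0, rec))
  pr <- sum(prec * drec)
  list(pr_auc = pr, roc_auc = roc)
}

#' Top-(n+i) ligand-level success rate
#'
#' For each protein with `n` ligands, a ligand is a hit when any pocket
#' ranked in the top `n + i` has DCA < 4 Angstrom to that ligand. The
#' success rate is total hits over total ligands across the dataset.
#'
#' @param predictions data.frame from [ensemble_predict()] (columns
#'   `protein_id`, `pocket_id`, `rank`).
#' @param pockets data.frame with `protein_id`, `pocket_id`, and
#'   barycenter columns `x`, `y`, `z`.
#' @param ligands named list: `ligands[[protein_id]]` is a list of ligand
#'   coordinate matrices `[m, 3]`, one per ligand.
#' @param i_values integer offsets to report (default 0..6).
#' @param dca_threshold hit criterion (strict `<`, matching the labeling
#'   rule).
#' @return named numeric vector of success rates, one per `i`.
#' @export
success_rate <- function(predictions, pockets, ligands, i_values = 0:6,
                         dca_threshold = 4.0) {
  prot_ids <- names(ligands)
  stopifnot(length(prot_ids) > 0)
  out <- numeric(length(i_values))
  names(out) <- paste0("top_n_plus_", i_values)
  total_ligands <- sum(vapply(ligands, length, integer(1)))
  for (ii in seq_along(i_values)) {
    i <- i_values[ii]
    hits <- 0
    for (pid in prot_ids) {
      ligs <- ligands[[pid]]
      n <- length(ligs)
      if (n == 0) next
      pr <- predictions[predictions$protein_id == pid, , drop = FALSE]
      if (nrow(pr) == 0) {
        warning("protein ", pid, " has no ranked pockets; counted as miss")
        next
      }
      top <- pr$pocket_id[pr$rank <= n + i]
      pk <- pockets[pockets$protein_id == pid &
                      pockets$pocket_id %in% top, , drop = FALSE]
      if (nrow(pk) == 0) next
      bary <- as.matrix(pk[, c("x", "y", "z")])
      for (lig in ligs) {
        lig <- matrix(as.numeric(lig), ncol = 3)
        d2 <- outer(rowSums(bary^2), rowSums(lig^2), "+") -
          2 * bary %*% t(lig)
        if (min(d2) < dca_threshold^2) hits <- hits + 1
      }
    }
    out[ii] <- hits / total_ligands
  }
  out
}

#' Evaluation report
#'
#' @param scores,labels pocket-level scores and truth labels.
#' @param predictions,pockets,ligands optional inputs for the Top-(n+i)
#'   success rates (see [success_rate()]); omit to report AUCs only.
#' @return list with `pr_auc`, `roc_auc`, `success_rate` (or `NULL`) and
#'   `counts`.
#' @export
eval_report <- function(scores, labels, predictions = NULL, pockets = NULL,
                        ligands = NULL) {
  auc <- pr_roc_auc(scores, labels)
  sr <- NULL
  if (!is.null(predictions) && !is.null(pockets) && !is.null(ligands)) {
    sr <- success_rate(predictions, pockets, ligands)
  }
  list(pr_auc = auc$pr_auc, roc_auc = auc$roc_auc, success_rate = sr,
       counts = list(pockets = length(scores),
                     positives = sum(as.logical(labels)),
                     proteins = if (is.null(predictions)) NA_integer_
                                else length(unique(predictions$protein_id)),
                     ligands = if (is.null(ligands)) NA_integer_
                               else sum(vapply(ligands, length, integer(1)))))
}
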