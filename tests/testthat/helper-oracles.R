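# Independent reference implementations used as oracles. These are kept
# deliberately naive (dense matrices, explicit loops, exhaustive scans)
# and share no code with the package internals they check.

# one graph transformer layer via dense masked attention: non-edges get
# -Inf logits, everything computed with N x N matrices
dense_layer_reference <- function(f, efeat, edges, lp, cfg) {
  n <- nrow(f)
  d <- cfg$d
  dh <- cfg$d_head
  addb <- function(x, b) sweep(x, 2, b, "+")
  q <- addb(f %*% lp$Wq, lp$bq)
  k <- addb(f %*% lp$Wk, lp$bk)
  v <- addb(f %*% lp$Wv, lp$bv)
  bmat <- addb(efeat %*% lp$We, lp$be)
  O <- matrix(0, n, d)
  for (h in seq_len(cfg$H)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Z <- matrix(-Inf, n, n)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      z <- sum(q[i, cols] * k[j, cols] * bmat[e, cols]) / sqrt(dh)
      Z[i, j] <- min(max(z, -cfg$clamp_bound), cfg$clamp_bound)
    }
    for (i in seq_len(n)) {
      if (all(is.infinite(Z[i, ]))) next
      w <- exp(Z[i, ] - max(Z[i, ][is.finite(Z[i, ])]))
      w[is.infinite(Z[i, ])] <- 0
      a <- w / sum(w)
      O[i, cols] <- colSums(a * v[, cols, drop = FALSE])
    }
  }
  ln <- function(x, gain, off) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * gain + off
    }))
  }
  fh <- ln(addb(O %*% lp$Wo, lp$bo) + f, lp$g1, lp$o1)
  h1 <- pmax(addb(fh %*% lp$W1, lp$b1), 0)
  ln(addb(h1 %*% lp$W2, lp$b2) + fh, lp$g2, lp$o2)
}

# ROC-AUC by exhaustive concordant-pair counting with half-credit ties
brute_roc_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# PR-AUC by explicit threshold scan over the distinct scores
brute_pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# Top-(n+i) success rate by direct per-ligand scan
brute_success_rate <- function(predictions, pockets, ligands, i) {
  hits <- 0
  total <- 0
  for (pid in names(ligands)) {
    n <- length(ligands[[pid]])
    for (lig in ligands[[pid]]) {
      total <- total + 1
      found <- FALSE
      pr <- predictions[predictions$protein_id == pid, ]
      for (r in seq_len(nrow(pr))) {
        if (pr$rank[r] > n + i) next
        pk <- pockets[pockets$protein_id == pid &
                        pockets$pocket_id == pr$pocket_id[r], ]
        b <- c(pk$x, pk$y, pk$z)
        dmin <- min(sqrt(rowSums(sweep(lig, 2, b)^2)))
        if (dmin < 4) found <- TRUE
      }
      if (found) hits <- hits + 1
    }
  }
  hits / total
}

# scalar RBF component by direct formula evaluation
brute_rbf <- function(x, range, n, gamma) {
  mu <- seq(range[1], range[2], length.out = n)
  sapply(seq_len(n), function(k) exp(-gamma * (x - mu[k])^2))
}
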