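# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, pair counting) and never share code
# with the package internals they check.

# Plain multi-head self-attention, one query at a time.
ref_global_attention <- function(Xmat, p, heads) {
  n <- nrow(Xmat); c <- ncol(Xmat); dh <- c / heads
  Q <- sweep(Xmat %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(Xmat %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(Xmat %*% p$Wv, 2, p$bv, `+`)
  O <- matrix(0, n, c)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1) * dh + 1):(hd * dh)
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n)) logits[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
      wgt <- exp(logits - max(logits)); wgt <- wgt / sum(wgt)
      O[i, cols] <- colSums(wgt * V[, cols, drop = FALSE])
    }
  }
  sweep(O %*% p$Wo, 2, p$bo, `+`)
}

# Naive gated attention scores, tile by tile.
ref_gated_weights <- function(T, params) {
  n <- nrow(T)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ti <- T[i, ]
    s[i] <- sum(params$w * (tanh(params$V %*% ti) * (1 / (1 + exp(-params$U %*% ti)))))
  }
  e <- exp(s - max(s))
  e / sum(e)
}

# Pair-counting AUC with half weight for ties.
ref_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

ref_acc_f1 <- function(labels, scores) {
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  f1p <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1n <- if (2 * tn + fn + fp == 0) 0 else 2 * tn / (2 * tn + fn + fp)
  list(acc = (tp + tn) / length(labels), macro_f1 = (f1p + f1n) / 2)
}

# Brute-force neighbor list: sort every valid position by the stated rule.
ref_neighbors <- function(h, w, k, valid, qr, qc) {
  pos <- which(t(valid))
  rr <- (pos - 1) %/% w + 1
  cc <- (pos - 1) %% w + 1
  cheb <- pmax(abs(rr - qr), abs(cc - qc))
  eucl <- (rr - qr)^2 + (cc - qc)^2
  rid <- (rr - 1) * w + cc
  ord <- order(cheb, eucl, rid)[seq_len(min(k, length(pos)))]
  cbind(rr[ord], cc[ord])
}

# Random grid feature map with optional mask.
rand_map <- function(h, w, c, masked = FALSE) {
  valid <- if (masked) matrix(stats::runif(h * w) > 0.25, h, w) else matrix(TRUE, h, w)
  if (!any(valid)) valid[1, 1] <- TRUE
  grid_feature_map(array(stats::rnorm(h * w * c), c(h, w, c)), valid)
}

# Flat-color textured tiles (two classes) for encoder tests.
make_texture_tiles <- function(n_per_class, px = 12, seed = 1) {
  natmil:::with_seed(seed, {
    mk <- function(cls) {
      base <- if (cls == 1) c(0.48, 0.32, 0.58) else c(0.85, 0.60, 0.72)
      arr <- array(rep(base, each = px * px), c(px, px, 3))
      arr <- arr + array(stats::rnorm(px * px * 3, 0, 0.04), dim(arr))
      pmax(pmin(arr, 1), 0)
    }
    list(tiles = lapply(rep(1:2, each = n_per_class), mk),
         labels = rep(c(1L, 0L), each = n_per_class))
  })
}

# Small bag collections for fast MIL tests.
quick_bags <- function(n_bags = 24, grid = 8, d = 8, sep = 4, seed = 1,
                       tumor_fraction = 0.2, stain_sd = 1) {
  generate_feature_bags(bag_spec(n_bags, grid, grid, d,
                                 tumor_fraction = tumor_fraction,
                                 cluster = TRUE, class_separation = sep,
                                 stain_sd = stain_sd, seed = seed))
}

fast_settings <- function(epochs = 8L, lr = 3e-3) {
  train_settings(epochs = epochs, lr = lr, batch_size = 8L,
                 weight_decay = 0.1, patience = epochs)
}
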