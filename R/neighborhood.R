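# Neighborhood attention: each grid position attends over its k nearest
# valid neighbors (Chebyshev distance, ties by Euclidean then raster
# order) with learned projections and relative positional biases. Near
# edges the neighbor set shifts inward rather than shrinking, so every
# query keeps a uniform attention span. A brute-force masked-attention
# oracle provides the semantic reference.

#' Grid feature map
#'
#' @param X array `h x w x c`.
#' @param valid logical `h x w` validity mask (default all valid). Masked
#'   positions carry zeros and are excluded as attention keys/values.
#' @return a `grid_feature_map`.
#' @export
grid_feature_map <- function(X, valid = NULL) {
  stopifnot(length(dim(X)) == 3L)
  if (is.null(valid)) valid <- matrix(TRUE, dim(X)[1], dim(X)[2])
  stopifnot(all(dim(valid) == dim(X)[1:2]))
  for (ch in seq_len(dim(X)[3])) X[, , ch][!valid] <- 0
  structure(list(X = X, valid = valid), class = "grid_feature_map")
}

#' Pivot a feature bag to a grid feature map
#'
#' Places each tile's embedding at its `(row, col)` cell; cells with no
#' tile are masked invalid.
#'
#' @param bag a `feature_bag`.
#' @param h,w grid dimensions (default: minimal grid covering the tiles).
#' @return a `grid_feature_map`.
#' @export
grid_from_bag <- function(bag, h = NULL, w = NULL) {
  h <- h %||% (max(bag$rows) + 1L)
  w <- w %||% (max(bag$cols) + 1L)
  d <- ncol(bag$H)
  X <- array(0, c(h, w, d))
  valid <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(bag$H))) {
    r <- bag$rows[i] + 1L; c <- bag$cols[i] + 1L
    X[r, c, ] <- bag$H[i, ]
    valid[r, c] <- TRUE
  }
  grid_feature_map(X, valid)
}

# Canonical flattening: valid positions in row-major (raster) order.
# Returns X as an n x c matrix plus the (r, c) positions.
map_flatten <- function(map) {
  h <- dim(map$X)[1]; w <- dim(map$X)[2]; nc <- dim(map$X)[3]
  pos <- which(t(map$valid)) # row-major scan
  r <- (pos - 1L) %/% w + 1L
  c <- (pos - 1L) %% w + 1L
  X <- matrix(0, length(pos), nc)
  lin <- (c - 1L) * h + r
  Xm <- matrix(map$X, h * w, nc)
  X <- Xm[lin, , drop = FALSE]
  list(X = X, r = r, c = c, lin = lin, h = h, w = w)
}

map_scatter <- function(Xmat, flat) {
  nc <- ncol(Xmat)
  out <- array(0, c(flat$h, flat$w, nc))
  Om <- matrix(0, flat$h * flat$w, nc)
  Om[flat$lin, ] <- Xmat
  array(Om, c(flat$h, flat$w, nc))
}

#' Build the neighborhood index
#'
#' For every valid grid position, finds the `min(k, n_valid)` valid
#' positions (including the query itself) minimizing Chebyshev distance,
#' with ties broken by Euclidean distance and then raster order. For
#' `k = m^2` (odd `m`) on a fully valid grid this reproduces the centered
#' `m x m` sliding window, shifting inward at edges.
#'
#' @param h,w grid dimensions in tiles.
#' @param k neighbors per query (>= 1). Counts neighbors, not a window
#'   side; `k > n_valid` is clamped with a warning.
#' @param valid optional logical `h x w` mask.
#' @param rtab bias-table radius override; defaults to
#'   `ceiling(sqrt(k)) - 1` for the clamped `k`. Offsets beyond the table
#'   reuse the nearest tabulated offset.
#' @return a `neighborhood_index`: positions `r`, `c` (1-based, raster
#'   order), `nb` (n x k neighbor indices into that order), `off` (n x k
#'   relative-offset table ids), `pad` (n x k, TRUE = padding slot),
#'   `rtab` (bias table radius) and `n_off` (table size).
#' @export
build_neighborhood_index <- function(h, w, k, valid = NULL, rtab = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("no valid positions")
  if (k > n_valid) {
    warning(sprintf("k = %d exceeds %d valid positions; clamped", k, n_valid))
    k <- n_valid
  }
  k <- as.integer(k)
  # raster-ordered valid positions
  pos <- which(t(valid))
  qr <- (pos - 1L) %/% w + 1L
  qc <- (pos - 1L) %% w + 1L
  n <- length(pos)
  # map from (r, c) to canonical valid-position index
  idx_of <- matrix(0L, h, w)
  idx_of[cbind(qr, qc)] <- seq_len(n)
  nb <- matrix(0L, n, k)
  off_r <- matrix(0L, n, k)
  off_c <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    R <- max(1L, ceiling(sqrt(k)) %/% 2L)
    repeat {
      r0 <- max(1L, qr[i] - R); r1 <- min(h, qr[i] + R)
      c0 <- max(1L, qc[i] - R); c1 <- min(w, qc[i] + R)
      sub <- valid[r0:r1, c0:c1, drop = FALSE]
      if (sum(sub) >= k || (r0 == 1L && r1 == h && c0 == 1L && c1 == w)) break
      R <- R + 1L
    }
    wh <- which(sub)
    cr <- (wh - 1L) %% nrow(sub) + r0
    cc <- (wh - 1L) %/% nrow(sub) + c0
    dr <- cr - qr[i]; dc <- cc - qc[i]
    cheb <- pmax(abs(dr), abs(dc))
    eucl <- dr * dr + dc * dc
    rid <- (cr - 1L) * w + cc
    ord <- order(cheb, eucl, rid)[seq_len(k)]
    nb[i, ] <- idx_of[cbind(cr[ord], cc[ord])]
    off_r[i, ] <- dr[ord]
    off_c[i, ] <- dc[ord]
  }
  if (is.null(rtab)) rtab <- max(0L, as.integer(ceiling(sqrt(k))) - 1L)
  rtab <- as.integer(rtab)
  side <- 2L * rtab + 1L
  clamp <- function(x) pmin(pmax(x, -rtab), rtab)
  off <- (clamp(off_r) + rtab) * side + (clamp(off_c) + rtab) + 1L
  structure(list(h = h, w = w, k = k, r = qr, c = qc,
                 nb = nb, off = off, pad = matrix(FALSE, n, k),
                 rtab = rtab, n_off = side^2),
            class = "neighborhood_index")
}

# Blocked (non-overlapping) window index: each query attends to every
# valid position in its ceil(sqrt(k)) x ceil(sqrt(k)) block. Edge blocks
# are smaller; slots are padded. The ablation's "Window self-Attn" mixer.
build_window_index <- function(h, w, k, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  m <- max(1L, as.integer(ceiling(sqrt(k))))
  pos <- which(t(valid))
  qr <- (pos - 1L) %/% w + 1L
  qc <- (pos - 1L) %% w + 1L
  n <- length(pos)
  idx_of <- matrix(0L, h, w)
  idx_of[cbind(qr, qc)] <- seq_len(n)
  block <- paste((qr - 1L) %/% m, (qc - 1L) %/% m)
  members <- split(seq_len(n), block)
  kmax <- max(vapply(members, length, integer(1)))
  nb <- matrix(1L, n, kmax)
  pad <- matrix(TRUE, n, kmax)
  off_r <- matrix(0L, n, kmax)
  off_c <- matrix(0L, n, kmax)
  for (mb in members) {
    for (i in mb) {
      nb[i, seq_along(mb)] <- mb
      pad[i, seq_along(mb)] <- FALSE
      off_r[i, seq_along(mb)] <- qr[mb] - qr[i]
      off_c[i, seq_along(mb)] <- qc[mb] - qc[i]
    }
  }
  rtab <- m - 1L
  side <- 2L * rtab + 1L
  clamp <- function(x) pmin(pmax(x, -rtab), rtab)
  off <- (clamp(off_r) + rtab) * side + (clamp(off_c) + rtab) + 1L
  structure(list(h = h, w = w, k = kmax, r = qr, c = qc,
                 nb = nb, off = off, pad = pad,
                 rtab = rtab, n_off = side^2),
            class = "neighborhood_index")
}

#' Initialize attention parameters
#'
#' Query/key/value/output projections (with biases) plus one relative
#' positional bias table per head, zero-initialized.
#'
#' @param c channels (divisible by `heads`).
#' @param heads number of attention heads.
#' @param n_off size of the relative-offset bias table (from the index).
#' @param sd init scale for the truncated-normal projection weights.
#' @return parameter list (`Wq,Wk,Wv,Wo,bq,bk,bv,bo,B`) with attribute
#'   `heads`.
#' @export
attn_params_init <- function(c, heads, n_off, sd = 0.02) {
  if (c %% heads != 0L) stop("channels must be divisible by heads")
  p <- list(Wq = init_mat(c, c, sd), bq = numeric(c),
            Wk = init_mat(c, c, sd), bk = numeric(c),
            Wv = init_mat(c, c, sd), bv = numeric(c),
            Wo = init_mat(c, c, sd), bo = numeric(c),
            B = matrix(0, n_off, heads))
  attr(p, "heads") <- as.integer(heads)
  p
}

# Gather-based sparse attention over an index. X: n x c. Returns out + cache.
attn_index_forward <- function(X, index, p) {
  heads <- attr(p, "heads")
  n <- nrow(X); c <- ncol(X); k <- ncol(index$nb)
  dh <- c %/% heads
  Q <- sweep(X %*% p$Wq, 2L, p$bq, `+`)
  K <- sweep(X %*% p$Wk, 2L, p$bk, `+`)
  V <- sweep(X %*% p$Wv, 2L, p$bv, `+`)
  idxv <- as.vector(index$nb)
  offv <- as.vector(index$off)
  padv <- as.vector(index$pad)
  grp <- rep(seq_len(n), times = k)
  O <- matrix(0, n, c)
  Ph <- vector("list", heads)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    Qh <- Q[, cols, drop = FALSE]
    Kg <- K[idxv, cols, drop = FALSE]
    logits <- rowSums(Qh[grp, , drop = FALSE] * Kg) + p$B[offv, hd]
    L <- matrix(logits / sqrt(dh), n, k)
    L[index$pad] <- -Inf
    P <- softmax_rows(L)
    Pv <- as.vector(P)
    Oh <- rowsum(Pv * V[idxv, cols, drop = FALSE], grp)
    O[, cols] <- Oh
    Ph[[hd]] <- P
  }
  out <- sweep(O %*% p$Wo, 2L, p$bo, `+`)
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, P = Ph, p = p,
                    idxv = idxv, offv = offv, padv = padv, grp = grp,
                    n = n, c = c, k = k, dh = dh, heads = heads,
                    n_off = index$n_off))
}

attn_index_backward <- function(dout, cache) {
  p <- cache$p
  n <- cache$n; c <- cache$c; k <- cache$k; dh <- cache$dh
  idxv <- cache$idxv; grp <- cache$grp
  dWo <- t(cache$O) %*% dout
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, n, c); dK <- matrix(0, n, c); dV <- matrix(0, n, c)
  dB <- matrix(0, cache$n_off, cache$heads)
  scatter_rowsum <- function(vals, groups, nrow_out, ncol_out) {
    rs <- rowsum(vals, groups)
    out <- matrix(0, nrow_out, ncol_out)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  for (hd in seq_len(cache$heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    Qh <- cache$Q[, cols, drop = FALSE]
    Kg <- cache$K[idxv, cols, drop = FALSE]
    Vg <- cache$V[idxv, cols, drop = FALSE]
    P <- cache$P[[hd]]
    dOh <- dO[, cols, drop = FALSE]
    dOg <- dOh[grp, , drop = FALSE]
    dPv <- rowSums(dOg * Vg)
    dV[, cols] <- scatter_rowsum(as.vector(P) * dOg, idxv, n, dh)
    dP <- matrix(dPv, n, k)
    dA <- P * (dP - rowSums(P * dP))
    dA[cache$padv] <- 0
    dLv <- as.vector(dA) / sqrt(dh)
    keep <- !cache$padv
    dB[, hd] <- scatter_rowsum(matrix(dLv[keep], ncol = 1), cache$offv[keep],
                               cache$n_off, 1L)
    dQ[, cols] <- scatter_rowsum(dLv * Kg, grp, n, dh)
    dK[, cols] <- scatter_rowsum(dLv * Qh[grp, , drop = FALSE], idxv, n, dh)
  }
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       grads = list(Wq = t(cache$X) %*% dQ, bq = colSums(dQ),
                    Wk = t(cache$X) %*% dK, bk = colSums(dK),
                    Wv = t(cache$X) %*% dV, bv = colSums(dV),
                    Wo = dWo, bo = dbo, B = dB))
}

# Dense attention with an optional allowed-mask and offset-id matrix for
# the positional bias. The global-attention mixer and the oracle both use
# this path, which is computed with full n x n matrices.
attn_dense_forward <- function(X, p, offmat = NULL, allowed = NULL) {
  heads <- attr(p, "heads")
  n <- nrow(X); c <- ncol(X)
  dh <- c %/% heads
  Q <- sweep(X %*% p$Wq, 2L, p$bq, `+`)
  K <- sweep(X %*% p$Wk, 2L, p$bk, `+`)
  V <- sweep(X %*% p$Wv, 2L, p$bv, `+`)
  O <- matrix(0, n, c)
  Ph <- vector("list", heads)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    L <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])
    if (!is.null(offmat)) L <- L + matrix(p$B[offmat, hd], n, n)
    L <- L / sqrt(dh)
    if (!is.null(allowed)) L[!allowed] <- -Inf
    P <- softmax_rows(L)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    Ph[[hd]] <- P
  }
  out <- sweep(O %*% p$Wo, 2L, p$bo, `+`)
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O, P = Ph,
                               p = p, offmat = offmat, allowed = allowed,
                               n = n, c = c, dh = dh, heads = heads,
                               n_off = nrow(p$B)))
}

attn_dense_backward <- function(dout, cache) {
  p <- cache$p
  n <- cache$n; c <- cache$c; dh <- cache$dh
  dWo <- t(cache$O) %*% dout
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, n, c); dK <- matrix(0, n, c); dV <- matrix(0, n, c)
  dB <- matrix(0, cache$n_off, cache$heads)
  for (hd in seq_len(cache$heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    P <- cache$P[[hd]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dP <- dOh %*% t(Vh)
    dV[, cols] <- t(P) %*% dOh
    dA <- P * (dP - rowSums(P * dP))
    dL <- dA / sqrt(dh)
    if (!is.null(cache$offmat)) {
      rs <- rowsum(as.vector(dL), as.vector(cache$offmat))
      dB[as.integer(rownames(rs)), hd] <- rs
    }
    dQ[, cols] <- dL %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- t(dL) %*% cache$Q[, cols, drop = FALSE]
  }
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       grads = list(Wq = t(cache$X) %*% dQ, bq = colSums(dQ),
                    Wk = t(cache$X) %*% dK, bk = colSums(dK),
                    Wv = t(cache$X) %*% dV, bv = colSums(dV),
                    Wo = dWo, bo = dbo, B = dB))
}

# Full offset-id matrix for dense attention over a position list, clamped
# to the bias table radius.
dense_offsets <- function(r, c, rtab) {
  side <- 2L * rtab + 1L
  clampv <- function(x) pmin(pmax(x, -rtab), rtab)
  dr <- clampv(outer(r, r, function(a, b) b - a))
  dc <- clampv(outer(c, c, function(a, b) b - a))
  (dr + rtab) * side + (dc + rtab) + 1L
}

#' Neighborhood attention over a grid feature map
#'
#' Multi-head attention where query `i` attends over its `k` nearest valid
#' neighbors: logits `Q_i K_j^T + B(i, j)` scaled by `1/sqrt(d_head)`,
#' softmax over the neighborhood, values contracted and heads concatenated
#' then output-projected. Masked positions output zero.
#'
#' @param X a [grid_feature_map()].
#' @param params from [attn_params_init()].
#' @param k neighborhood size.
#' @param index optional precomputed [build_neighborhood_index()].
#' @return a `grid_feature_map` of the same shape.
#' @export
neighborhood_attention <- function(X, params, k, index = NULL) {
  flat <- map_flatten(X)
  if (is.null(index)) {
    index <- build_neighborhood_index(flat$h, flat$w, k, X$valid)
  }
  fw <- attn_index_forward(flat$X, index, params)
  grid_feature_map(map_scatter(fw$out, flat), X$valid)
}

#' Brute-force masked-attention oracle
#'
#' Computes the full `n x n` attention matrix, sets non-neighbor logits to
#' `-Inf` before the softmax, and contracts with all values. Semantically
#' definitive, asymptotically wasteful; used to verify
#' [neighborhood_attention()].
#'
#' @param X a [grid_feature_map()].
#' @param params from [attn_params_init()].
#' @param index a [build_neighborhood_index()] result.
#' @return a `grid_feature_map`.
#' @export
oracle_masked_attention <- function(X, params, index) {
  flat <- map_flatten(X)
  n <- nrow(flat$X)
  allowed <- matrix(FALSE, n, n)
  offmat <- matrix(1L, n, n)
  for (i in seq_len(n)) {
    keep <- !index$pad[i, ]
    allowed[i, index$nb[i, keep]] <- TRUE
    offmat[i, index$nb[i, keep]] <- index$off[i, keep]
  }
  fw <- attn_dense_forward(flat$X, params, offmat, allowed)
  grid_feature_map(map_scatter(fw$out, flat), X$valid)
}

#' Attention weights of the NA operator
#'
#' Returns the per-head row-stochastic neighborhood attention matrices
#' (`n x k`) for inspection/debugging.
#'
#' @inheritParams neighborhood_attention
#' @return list with `P` (list of n x k matrices, one per head) and the
#'   `index` used.
#' @export
na_attention_weights <- function(X, params, k, index = NULL) {
  flat <- map_flatten(X)
  if (is.null(index)) index <- build_neighborhood_index(flat$h, flat$w, k, X$valid)
  fw <- attn_index_forward(flat$X, index, params)
  list(P = fw$cache$P, index = index)
}
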