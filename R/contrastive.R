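# Two-view contrastive tile embeddings (SimCLR-style). The encoder is a
# configurable residual convolutional network scaled down to desk size
# (the reference 1024-d ResNet-50 setting is out of reach without
# pretrained weights); the projection head has two hidden layers and the
# NT-Xent loss is computed on L2-normalized projections.

#' Augmentation strengths
#'
#' @param crop_min minimum area fraction of the random resized crop
#'   (1 disables cropping).
#' @param flip_prob probability of each of horizontal and vertical flip.
#' @param jitter maximum relative brightness/contrast/saturation jitter.
#' @param blur_max maximum Gaussian blur sigma (pixels); blur applied with
#'   probability 0.5 when positive.
#' @return list of strengths; all-zero (`crop_min = 1`, rest 0) makes
#'   [augment()] the identity.
#' @export
augment_strengths <- function(crop_min = 0.5, flip_prob = 0.5,
                              jitter = 0.4, blur_max = 1.0) {
  list(crop_min = crop_min, flip_prob = flip_prob,
       jitter = jitter, blur_max = blur_max)
}

augment_one <- function(tile, s) {
  h <- dim(tile)[1]; w <- dim(tile)[2]
  out <- tile
  if (s$crop_min < 1) {
    area <- stats::runif(1, s$crop_min, 1)
    ch <- max(2L, round(h * sqrt(area)))
    cw <- max(2L, round(w * sqrt(area)))
    r0 <- sample.int(h - ch + 1L, 1L)
    c0 <- sample.int(w - cw + 1L, 1L)
    out <- resize_bilinear(out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), , drop = FALSE], h, w)
  }
  if (s$flip_prob > 0 && stats::runif(1) < s$flip_prob) out <- out[, rev(seq_len(w)), , drop = FALSE]
  if (s$flip_prob > 0 && stats::runif(1) < s$flip_prob) out <- out[rev(seq_len(h)), , , drop = FALSE]
  if (s$jitter > 0) {
    br <- 1 + stats::runif(1, -s$jitter, s$jitter)
    ct <- 1 + stats::runif(1, -s$jitter, s$jitter)
    sa <- 1 + stats::runif(1, -s$jitter, s$jitter)
    out <- out * br
    out <- (out - mean(out)) * ct + mean(out)
    gray <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3
    for (chn in 1:3) out[, , chn] <- gray + (out[, , chn] - gray) * sa
    out <- pmax(pmin(out, 1), 0)
  }
  if (s$blur_max > 0 && stats::runif(1) < 0.5) {
    out <- gaussian_blur(out, stats::runif(1, 0.1, s$blur_max))
  }
  out
}

#' Generate an augmented pair
#'
#' Two independently sampled views (random resized crop, horizontal and
#' vertical flips, color jitter, Gaussian blur) of the same square tile.
#' Deterministic per seed.
#'
#' @param tile array `p x p x 3` in \[0, 1\].
#' @param seed integer seed.
#' @param strengths from [augment_strengths()].
#' @return list with `view_a` and `view_b`.
#' @export
augment <- function(tile, seed, strengths = augment_strengths()) {
  stopifnot(dim(tile)[1] == dim(tile)[2])
  with_seed(seed, {
    list(view_a = augment_one(tile, strengths),
         view_b = augment_one(tile, strengths))
  })
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross entropy over `2N` paired
#' projections: rows `(2m-1, 2m)` are positive pairs, every other row is a
#' negative, similarities are cosine (rows must be unit-norm), and
#' `loss = mean_i -log( exp(s(i,pos)/tau) / sum_{k != i} exp(s(i,k)/tau) )`.
#'
#' @param Z numeric matrix `2N x p` of unit-norm projections.
#' @param tau temperature (> 0).
#' @return scalar loss.
#' @export
nt_xent_loss <- function(Z, tau = 0.5) {
  nt_xent(Z, tau)$loss
}

nt_xent <- function(Z, tau) {
  if (tau <= 0) stop("tau must be > 0")
  n2 <- nrow(Z)
  if (n2 < 4L || n2 %% 2L != 0L) stop("need at least N = 2 pairs (4 rows, even count)")
  S <- Z %*% t(Z) / tau
  diag(S) <- -Inf
  pos <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  P <- softmax_rows(S)
  lse <- apply(S, 1L, logsumexp)
  loss <- mean(lse - S[cbind(seq_len(n2), pos)])
  dS <- P
  dS[cbind(seq_len(n2), pos)] <- dS[cbind(seq_len(n2), pos)] - 1
  dS <- dS / n2
  dZ <- (dS + t(dS)) %*% Z / tau
  list(loss = loss, dZ = dZ)
}

# ---- toy residual encoder ---------------------------------------------

#' Encoder configuration
#'
#' @param channels stem width of the residual CNN.
#' @param n_blocks residual blocks (each followed by 2x2 average pooling).
#' @param d output feature dimension (the tile embedding width; 1024 in
#'   the reference full-scale setting, small for desk-scale runs).
#' @param proj_hidden width of the two hidden projection layers.
#' @param proj_out projection output width (NT-Xent space).
#' @param tau NT-Xent temperature (default 0.5).
#' @param freeze_up_to number of leading conv units (stem = 1, then one
#'   per block) excluded from training; 0 trains everything (the sensible
#'   default when starting from random initialization; the full-scale
#'   recipe freezes all but the last block of a pretrained encoder).
#' @param epochs,batch_size,lr training loop settings.
#' @param strengths augmentation strengths.
#' @return an `encoder_config`.
#' @export
encoder_config <- function(channels = 8L, n_blocks = 2L, d = 32L,
                           proj_hidden = 32L, proj_out = 16L, tau = 0.5,
                           freeze_up_to = 0L, epochs = 10L, batch_size = 16L,
                           lr = 1e-3, strengths = augment_strengths()) {
  structure(list(channels = as.integer(channels), n_blocks = as.integer(n_blocks),
                 d = as.integer(d), proj_hidden = as.integer(proj_hidden),
                 proj_out = as.integer(proj_out), tau = tau,
                 freeze_up_to = as.integer(freeze_up_to),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, strengths = strengths),
            class = "encoder_config")
}

init_encoder <- function(cfg, seed = 1L) {
  with_seed(seed, {
    c <- cfg$channels
    list(stem = conv2d_init(3L, c),
         blocks = lapply(seq_len(cfg$n_blocks), function(b) {
           list(ca = conv2d_init(c, c), cb = conv2d_init(c, c))
         }),
         feat = list(We = init_he(c, cfg$d), be = numeric(cfg$d)),
         proj = list(W1 = init_he(cfg$d, cfg$proj_hidden), b1 = numeric(cfg$proj_hidden),
                     W2 = init_he(cfg$proj_hidden, cfg$proj_hidden), b2 = numeric(cfg$proj_hidden),
                     W3 = init_he(cfg$proj_hidden, cfg$proj_out), b3 = numeric(cfg$proj_out)))
  })
}

avgpool2_forward <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  nh <- ceiling(h / 2); nw <- ceiling(w / 2)
  out <- array(0, c(nh, nw, nc))
  cnt <- matrix(0, nh, nw)
  for (i in seq_len(nh)) {
    rs <- (2L * i - 1L):min(2L * i, h)
    for (j in seq_len(nw)) {
      cs <- (2L * j - 1L):min(2L * j, w)
      cnt[i, j] <- length(rs) * length(cs)
      for (ch in seq_len(nc)) out[i, j, ch] <- mean(x[rs, cs, ch])
    }
  }
  list(out = out, cache = list(h = h, w = w, cnt = cnt))
}

avgpool2_backward <- function(dout, cache) {
  nh <- dim(dout)[1]; nw <- dim(dout)[2]; nc <- dim(dout)[3]
  dx <- array(0, c(cache$h, cache$w, nc))
  for (i in seq_len(nh)) {
    rs <- (2L * i - 1L):min(2L * i, cache$h)
    for (j in seq_len(nw)) {
      cs <- (2L * j - 1L):min(2L * j, cache$w)
      for (ch in seq_len(nc)) {
        dx[rs, cs, ch] <- dout[i, j, ch] / cache$cnt[i, j]
      }
    }
  }
  dx
}

# Conv trunk for one tile: stem, residual blocks with pooling, global mean
# pool. Returns channel vector + cache.
encoder_trunk_forward <- function(x, params) {
  st <- conv2d_forward(x, params$stem, stride = 2L, pad = 1L)
  a <- gelu(st$out)
  caches <- list(stem = st$cache, stem_pre = st$out)
  bl <- list()
  for (b in seq_along(params$blocks)) {
    p <- params$blocks[[b]]
    ca <- conv2d_forward(a, p$ca, stride = 1L, pad = 1L)
    ga <- gelu(ca$out)
    cb <- conv2d_forward(ga, p$cb, stride = 1L, pad = 1L)
    res <- a + cb$out
    act <- gelu(res)
    pl <- avgpool2_forward(act)
    bl[[b]] <- list(ca = ca$cache, ca_pre = ca$out, cb = cb$cache,
                    res = res, pool = pl$cache)
    a <- pl$out
  }
  f <- apply(a, 3L, mean)
  list(f = f, cache = list(stem = caches, blocks = bl, final_dim = dim(a)))
}

encoder_trunk_backward <- function(df, cache, params) {
  fd <- cache$final_dim
  da <- array(rep(df, each = fd[1] * fd[2]) / (fd[1] * fd[2]), fd)
  grads <- list(stem = NULL, blocks = vector("list", length(cache$blocks)))
  for (b in rev(seq_along(cache$blocks))) {
    bc <- cache$blocks[[b]]
    dact <- avgpool2_backward(da, bc$pool)
    dres <- gelu_backward(dact, bc$res)
    cbb <- conv2d_backward(dres, bc$cb)
    dga <- gelu_backward(cbb$dx, bc$ca_pre)
    cab <- conv2d_backward(dga, bc$ca)
    grads$blocks[[b]] <- list(ca = cab$grads, cb = cbb$grads)
    da <- dres + cab$dx
  }
  dstem_out <- gelu_backward(da, cache$stem$stem_pre)
  sb <- conv2d_backward(dstem_out, cache$stem$stem)
  grads$stem <- sb$grads
  list(grads = grads, dx = sb$dx)
}

normalize_rows_forward <- function(Z) {
  nrm <- sqrt(rowSums(Z * Z)) + 1e-12
  list(out = Z / nrm, cache = list(out = Z / nrm, nrm = nrm))
}

normalize_rows_backward <- function(dout, cache) {
  z <- cache$out
  (dout - z * rowSums(dout * z)) / cache$nrm
}

proj_forward <- function(Fm, p) {
  z1p <- sweep(Fm %*% p$W1, 2L, p$b1, `+`); z1 <- gelu(z1p)
  z2p <- sweep(z1 %*% p$W2, 2L, p$b2, `+`); z2 <- gelu(z2p)
  z3 <- sweep(z2 %*% p$W3, 2L, p$b3, `+`)
  nr <- normalize_rows_forward(z3)
  list(out = nr$out,
       cache = list(Fm = Fm, z1p = z1p, z1 = z1, z2p = z2p, z2 = z2,
                    nr = nr$cache, p = p))
}

proj_backward <- function(dZ, cache) {
  p <- cache$p
  d3 <- normalize_rows_backward(dZ, cache$nr)
  dW3 <- t(cache$z2) %*% d3; db3 <- colSums(d3)
  d2 <- gelu_backward(d3 %*% t(p$W3), cache$z2p)
  dW2 <- t(cache$z1) %*% d2; db2 <- colSums(d2)
  d1 <- gelu_backward(d2 %*% t(p$W2), cache$z1p)
  dW1 <- t(cache$Fm) %*% d1; db1 <- colSums(d1)
  list(dF = d1 %*% t(p$W1),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3))
}

#' Train the contrastive encoder
#'
#' Minimizes NT-Xent over augmented pairs with AdamW and a cosine
#' schedule. Deterministic per seed.
#'
#' @param tiles list of `p x p x 3` arrays.
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @return an `encoder`: list with `params`, `config`, `loss_trace`
#'   (per-epoch mean NT-Xent), and `seed`.
#' @export
train_encoder <- function(tiles, config, seed = 1L) {
  if (config$batch_size < 2L) stop("batch size must be >= 2")
  if (length(tiles) < 2L) stop("need at least 2 tiles")
  params <- init_encoder(config, derive_seed(seed, 1L))
  opt <- adamw_init(params)
  n <- length(tiles)
  steps_per_epoch <- max(1L, n %/% config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  step <- 0L
  trace <- numeric(config$epochs)
  frozen <- config$freeze_up_to
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(seed, 100L + ep), sample.int(n))
    losses <- c()
    for (bt in seq_len(steps_per_epoch)) {
      idx <- ord[((bt - 1L) * config$batch_size + 1L):min(n, bt * config$batch_size)]
      B <- length(idx)
      views <- vector("list", 2L * B)
      for (m in seq_along(idx)) {
        pr <- augment(tiles[[idx[m]]], derive_seed(seed, 10000L * ep + idx[m]),
                      config$strengths)
        views[[2L * m - 1L]] <- pr$view_a
        views[[2L * m]] <- pr$view_b
      }
      tr <- lapply(views, encoder_trunk_forward, params = params)
      Fm <- do.call(rbind, lapply(tr, `[[`, "f"))
      ft <- linear_forward(Fm, params$feat$We, params$feat$be)
      pj <- proj_forward(ft$out, params$proj)
      nx <- nt_xent(pj$out, config$tau)
      losses <- c(losses, nx$loss)
      pb <- proj_backward(nx$dZ, pj$cache)
      fb <- linear_backward(pb$dF, ft$cache)
      grads <- tree_zeros(params)
      grads$feat$We <- fb$dW
      grads$feat$be <- fb$db
      grads$proj <- pb$grads
      for (m in seq_len(2L * B)) {
        tb <- encoder_trunk_backward(fb$dX[m, ], tr[[m]]$cache, params)
        if (frozen < 1L) grads$stem <- tree_add(grads$stem, tb$grads$stem)
        for (b in seq_along(params$blocks)) {
          if (frozen < b + 1L) {
            grads$blocks[[b]] <- tree_add(grads$blocks[[b]], tb$grads$blocks[[b]])
          }
        }
      }
      step <- step + 1L
      lr <- lr_schedule(step, total_steps, config$lr)
      up <- adamw_step(params, grads, opt, lr)
      params <- up$params
      opt <- up$state
    }
    trace[ep] <- mean(losses)
  }
  structure(list(params = params, config = config, loss_trace = trace, seed = seed),
            class = "encoder")
}

#' Extract tile features into a bag
#'
#' Runs the encoder trunk + feature layer (no projection head) on each
#' manifest tile, preserving the manifest's `(row, col)` order.
#'
#' @param encoder an `encoder` (trained or freshly initialized via
#'   [init_encoder_model()]).
#' @param manifest a [tile_slide()] manifest (non-empty).
#' @param tiles either the slide raster (tiles are cropped using the
#'   manifest) or a list of tile arrays in manifest order.
#' @param label optional slide label to store on the bag.
#' @return a `feature_bag` with `H` of width `config$d`.
#' @export
extract_features <- function(encoder, manifest, tiles, label = NA_integer_) {
  if (nrow(manifest) == 0L) stop("manifest is empty")
  tile_px <- attr(manifest, "tile_px")
  get_tile <- if (is.list(tiles)) {
    function(i) tiles[[i]]
  } else {
    function(i) crop_tile(tiles, manifest$x[i], manifest$y[i], tile_px)
  }
  H <- matrix(0, nrow(manifest), encoder$config$d)
  for (i in seq_len(nrow(manifest))) {
    tr <- encoder_trunk_forward(get_tile(i), encoder$params)
    H[i, ] <- tr$f %*% encoder$params$feat$We + encoder$params$feat$be
  }
  new_feature_bag(manifest$slide_id[1], H, manifest$row, manifest$col, label)
}

#' Initialize an untrained encoder model
#'
#' Randomly initialized encoder usable with [extract_features()] (flagged
#' by `trained = FALSE`).
#'
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @return an `encoder`.
#' @export
init_encoder_model <- function(config, seed = 1L) {
  structure(list(params = init_encoder(config, seed), config = config,
                 loss_trace = numeric(0), seed = seed, trained = FALSE),
            class = "encoder")
}
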