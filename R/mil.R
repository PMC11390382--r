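# Gated attention pooling and the slide-level classifier, plus the full
# MIL model: a 1x1 embedding, a stack of full-resolution NAT blocks that
# contextualize the tile grid, gated pooling of (contextual + raw)
# embeddings, and a linear class head trained with cross-entropy.

#' Gated attention parameters
#'
#' @param d tile embedding dimension.
#' @param hidden gating hidden width (default 256, the AB-MIL convention).
#' @param seed integer seed.
#' @return list with `U`, `V` (hidden x d) and `w` (hidden).
#' @export
gated_params_init <- function(d, hidden = 256L, seed = 1L) {
  with_seed(seed, {
    list(U = matrix(trunc_normal(hidden * d, 0.1), hidden, d),
         V = matrix(trunc_normal(hidden * d, 0.1), hidden, d),
         w = trunc_normal(hidden, 0.1))
  })
}

gated_forward <- function(T, p) {
  TH <- tanh(T %*% t(p$V))     # n x hidden
  SG <- sigmoid(T %*% t(p$U))  # n x hidden
  s <- as.vector((TH * SG) %*% p$w)
  a <- softmax_vec(s)
  list(a = a, cache = list(T = T, TH = TH, SG = SG, s = s, a = a, p = p))
}

# da: gradient w.r.t. the attention weights a; returns dT and param grads.
gated_backward <- function(da, cache) {
  a <- cache$a
  ds <- a * (da - sum(a * da))
  G <- cache$TH * cache$SG
  dw <- as.vector(t(G) %*% ds)
  dG <- outer(ds, cache$p$w)          # n x hidden
  dTH <- dG * cache$SG
  dSG <- dG * cache$TH
  dpreV <- dTH * (1 - cache$TH^2)
  dpreU <- dSG * cache$SG * (1 - cache$SG)
  list(dT = dpreV %*% cache$p$V + dpreU %*% cache$p$U,
       grads = list(U = t(dpreU) %*% cache$T,
                    V = t(dpreV) %*% cache$T,
                    w = dw))
}

#' Gated attention pooling weights
#'
#' `a_i = softmax_i( w^T ( tanh(V t_i) * sigm(U t_i) ) )`: a tanh/sigmoid
#' gated score per tile, softmax-normalized over the bag.
#' Permutation-equivariant; weights sum to 1.
#'
#' @param T numeric matrix `n x d` of tile embeddings (n >= 1).
#' @param params from [gated_params_init()].
#' @return numeric vector of `n` attention weights.
#' @export
gated_attention <- function(T, params) {
  stopifnot(nrow(T) >= 1L)
  gated_forward(T, params)$a
}

#' Aggregate a bag into a slide embedding
#'
#' `g = sum_i a_i (t_ctx,i + t_raw,i)`: the contextualized embedding of
#' each tile plus its raw embedding as a residual, attention-weighted.
#' Set `T_ctx` to zeros for plain attention pooling.
#'
#' @param T_raw raw tile embeddings `n x d`.
#' @param T_ctx contextualized embeddings `n x d` (from the NAT blocks).
#' @param a attention weights of length `n`.
#' @return slide embedding vector of length `d`.
#' @export
aggregate_bag <- function(T_raw, T_ctx, a) {
  if (nrow(T_raw) == 0L) stop("empty bag")
  stopifnot(all(dim(T_raw) == dim(T_ctx)), length(a) == nrow(T_raw))
  as.vector(a %*% (T_ctx + T_raw))
}

#' Classify a slide embedding
#'
#' `y_pred = W_c g^T`, probabilities by softmax.
#'
#' @param g slide embedding of length `d`.
#' @param W_c class weight matrix `c x d` (c >= 2).
#' @return list with `y_pred` (scores) and `probs`.
#' @export
classify <- function(g, W_c) {
  y <- as.vector(W_c %*% g)
  list(y_pred = y, probs = softmax_vec(y))
}

#' Baseline pooling operators
#'
#' @param T tile embeddings `n x d`.
#' @param mode `"max"` (elementwise), `"mean"`, or `"abmil_gated"` (gated
#'   attention pooling of the raw embeddings, no contextual term).
#' @param params gated parameters (required for `"abmil_gated"`).
#' @return pooled embedding of length `d`.
#' @export
baseline_pool <- function(T, mode = c("max", "mean", "abmil_gated"), params = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(T) >= 1L)
  switch(mode,
         max = apply(T, 2L, max),
         mean = colMeans(T),
         abmil_gated = {
           if (is.null(params)) stop("abmil_gated needs gated params")
           as.vector(gated_attention(T, params) %*% T)
         })
}

# ---- full MIL model ----------------------------------------------------

#' MIL model configuration
#'
#' @param d tile feature dimension (model width; the contextualizer keeps
#'   channels at `d` so Eq.-style residual `g_i + t_i` is well-typed).
#' @param n_blocks NAT blocks in the contextualizer (full grid resolution,
#'   no downsampling).
#' @param heads,mlp_ratio,layer_scale_init block settings.
#' @param k neighborhood size.
#' @param variant attention mixer (`neighborhood`, `window`, `global`,
#'   `conv`).
#' @param gate_hidden gating hidden width.
#' @param n_classes output classes (binary tasks use 2 with softmax).
#' @param residual_raw include the raw embedding residually in the
#'   aggregate (`g = sum a_i (ctx_i + raw_i)`); `FALSE` drops the raw term.
#' @param gate_input `"context"` (gate the contextualized embeddings,
#'   default) or `"raw"`.
#' @return a `natmil_config`.
#' @export
natmil_config <- function(d = 32L, n_blocks = 2L, heads = 2L, mlp_ratio = 3,
                          layer_scale_init = 1e-5, k = 9L,
                          variant = c("neighborhood", "window", "global", "conv"),
                          gate_hidden = 64L, n_classes = 2L,
                          residual_raw = TRUE,
                          gate_input = c("context", "raw")) {
  variant <- match.arg(variant)
  gate_input <- match.arg(gate_input)
  if (d %% heads != 0L) stop("heads must divide d")
  structure(list(d = as.integer(d), n_blocks = as.integer(n_blocks),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio,
                 layer_scale_init = layer_scale_init, k = as.integer(k),
                 variant = variant, gate_hidden = as.integer(gate_hidden),
                 n_classes = as.integer(n_classes),
                 residual_raw = isTRUE(residual_raw), gate_input = gate_input),
            class = "natmil_config")
}

#' Initialize a NATMIL model
#'
#' @param config a [natmil_config()].
#' @param seed integer seed.
#' @return a `natmil_model` (config + parameter tree).
#' @export
init_natmil <- function(config, seed = 1L) {
  d <- config$d
  n_off <- k_table_size(config$k)
  params <- with_seed(seed, {
    list(embed = list(We = init_mat(d, d), be = numeric(d)),
         blocks = lapply(seq_len(config$n_blocks), function(b) {
           nat_block_params(d, config$heads, config$mlp_ratio,
                            config$layer_scale_init, n_off, config$variant)
         }),
         gate = gated_params_init(d, config$gate_hidden,
                                  derive_seed(seed, 77L)),
         Wc = init_mat(d, config$n_classes) |> t())
  })
  structure(list(config = config, params = params), class = "natmil_model")
}

# Mixer context for a bag's grid, cached by grid signature.
bag_ctx <- function(model, bag, cache_env = NULL) {
  h <- max(bag$rows) + 1L
  w <- max(bag$cols) + 1L
  key <- paste0(h, "x", w, ":", nrow(bag$H), ":", model$config$variant,
                ":", model$config$k)
  if (!is.null(cache_env) && !is.null(cache_env[[key]])) return(cache_env[[key]])
  map <- grid_from_bag(bag, h, w)
  flat <- map_flatten(map)
  cfg <- list(k = model$config$k, variant = model$config$variant)
  ctx <- suppressWarnings(make_mixer_ctx(cfg, h, w, map$valid))
  # permutation from bag row order to raster order
  ord <- order(bag$rows, bag$cols)
  res <- list(ctx = ctx, flat = flat, ord = ord, inv = order(ord))
  if (!is.null(cache_env)) cache_env[[key]] <- res
  res
}

# Forward pass for one bag. Returns prediction (+ caches when grad = TRUE).
natmil_forward <- function(model, bag, bc = NULL, grad = FALSE) {
  cfg <- model$config
  p <- model$params
  bc <- bc %||% bag_ctx(model, bag)
  H <- bag$H[bc$ord, , drop = FALSE] # raster order
  emb <- linear_forward(H, p$embed$We, p$embed$be)
  X <- emb$out
  bl_caches <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    fw <- block_forward(X, p$blocks[[b]], bc$ctx, bc$flat)
    X <- fw$out
    if (grad) bl_caches[[b]] <- fw$cache
  }
  T_ctx <- X
  G <- if (cfg$gate_input == "context") T_ctx else H
  gt <- gated_forward(G, p$gate)
  R <- if (cfg$residual_raw) T_ctx + H else T_ctx
  g <- as.vector(gt$a %*% R)
  y <- as.vector(p$Wc %*% g)
  probs <- softmax_vec(y)
  out <- list(probs = probs, y_pred = y, a = gt$a[bc$inv], g = g,
              T_ctx = T_ctx[bc$inv, , drop = FALSE])
  if (grad) {
    out$caches <- list(emb = emb$cache, blocks = bl_caches, gate = gt$cache,
                       H = H, R = R, T_ctx = T_ctx, a = gt$a, bc = bc)
  }
  out
}

# Loss + full parameter gradient for one labelled bag.
natmil_bag_grad <- function(model, bag, bc = NULL) {
  cfg <- model$config
  p <- model$params
  fw <- natmil_forward(model, bag, bc, grad = TRUE)
  ca <- fw$caches
  ce <- softmax_ce(fw$y_pred, bag$label)
  dy <- ce$dlogits
  grads <- tree_zeros(p)
  grads$Wc <- outer(dy, fw$g)
  dg <- as.vector(t(p$Wc) %*% dy)
  a <- ca$a
  dR <- outer(a, dg)
  da <- as.vector(ca$R %*% dg)
  gb <- gated_backward(da, ca$gate)
  grads$gate <- gb$grads
  dT_ctx <- dR
  dH <- if (cfg$residual_raw) dR else matrix(0, nrow(dR), ncol(dR))
  if (cfg$gate_input == "context") dT_ctx <- dT_ctx + gb$dT else dH <- dH + gb$dT
  dX <- dT_ctx
  for (b in rev(seq_len(cfg$n_blocks))) {
    bb <- block_backward(dX, ca$blocks[[b]])
    grads$blocks[[b]] <- bb$grads
    dX <- bb$dX
  }
  eb <- linear_backward(dX, ca$emb)
  grads$embed$We <- eb$dW
  grads$embed$be <- eb$db
  list(loss = ce$loss, probs = ce$probs, grads = grads)
}

#' Predict a slide from its feature bag
#'
#' @param model a `natmil_model`.
#' @param bag a `feature_bag`.
#' @return a `slide_prediction`: class probabilities, scores, attention
#'   weights `a` (bag tile order, summing to 1), slide embedding `g`, and
#'   contextualized tile embeddings.
#' @export
predict_bag <- function(model, bag) {
  out <- natmil_forward(model, bag)
  structure(list(slide_id = bag$slide_id, probs = out$probs,
                 y_pred = out$y_pred, a = out$a, g = out$g,
                 T_ctx = out$T_ctx),
            class = "slide_prediction")
}
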