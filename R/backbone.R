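# Hierarchical neighborhood-attention transformer: overlapping-convolution
# tokenizer (two 3x3 stride-2 convs), four stages of pre-norm NAT blocks
# with LayerScale, and channel-doubling 3x3 stride-2 downsamplers between
# stages. In tile mode a 1x1 linear embedding replaces the stride-4
# tokenizer (a coarse tile grid must not be divided by 32); the conv
# tokenizer stays available via `tokenizer = "conv"`.

#' Backbone configuration
#'
#' The reference configuration is depths (3, 4, 18, 5), 2 heads and MLP
#' ratio 3; tests use much smaller values (the shape laws are depth- and
#' width-independent).
#'
#' @param depths integer vector of 4 block counts per stage.
#' @param heads attention heads (fixed across stages; must divide every
#'   stage's channel count).
#' @param mlp_ratio MLP hidden width as a multiple of the channel count.
#' @param k neighborhood size (number of neighbors per query; `k = m^2`
#'   reproduces an `m x m` sliding window).
#' @param base_channels channels after the tokenizer; doubled at each
#'   downsampler.
#' @param layer_scale_init initial value of the per-channel LayerScale
#'   vectors on both residual branches.
#' @param drop_path reserved (default 0; stochastic depth is not used at
#'   desk scale).
#' @param mode `"tiles"` (input is a tile-feature grid) or `"image"`.
#' @param tokenizer `"auto"` (linear for tiles, conv for images),
#'   `"linear"` (1x1 embedding) or `"conv"` (two 3x3 stride-2 convs).
#' @param downsample apply the channel-doubling spatial-halving
#'   downsamplers after stages 1-3 (`TRUE`, the hierarchical backbone) or
#'   keep full grid resolution (`FALSE`, used by the MIL contextualizer).
#' @param in_channels input channels (3 for RGB rasters, `d` for tile
#'   features).
#' @param variant stage mixer: `"neighborhood"`, `"window"`, `"global"`,
#'   or `"conv"` (3x3 depthwise convolution).
#' @return a `nat_config`.
#' @export
nat_config <- function(depths = c(3L, 4L, 18L, 5L), heads = 2L, mlp_ratio = 3,
                       k = 9L, base_channels = 64L, layer_scale_init = 1e-5,
                       drop_path = 0, mode = c("tiles", "image"),
                       tokenizer = c("auto", "linear", "conv"),
                       downsample = TRUE, in_channels = NULL,
                       variant = c("neighborhood", "window", "global", "conv")) {
  mode <- match.arg(mode)
  tokenizer <- match.arg(tokenizer)
  variant <- match.arg(variant)
  if (length(depths) != 4L) stop("depths must have length 4")
  if (tokenizer == "auto") tokenizer <- if (mode == "tiles") "linear" else "conv"
  in_channels <- in_channels %||% if (mode == "image") 3L else base_channels
  cfg <- list(depths = as.integer(depths), heads = as.integer(heads),
              mlp_ratio = mlp_ratio, k = as.integer(k),
              base_channels = as.integer(base_channels),
              layer_scale_init = layer_scale_init, drop_path = drop_path,
              mode = mode, tokenizer = tokenizer,
              downsample = isTRUE(downsample),
              in_channels = as.integer(in_channels), variant = variant)
  if (any((cfg$base_channels * 2^(seq_len(4L) - 1L)) %% cfg$heads != 0)) {
    stop("heads must divide every stage's channel count")
  }
  class(cfg) <- "nat_config"
  cfg
}

stage_channels <- function(cfg) {
  if (cfg$downsample) cfg$base_channels * 2L^(0:3) else rep(cfg$base_channels, 4L)
}

# Bias-table size implied by a neighborhood size k.
k_table_size <- function(k) {
  rtab <- max(0L, as.integer(ceiling(sqrt(k))) - 1L)
  (2L * rtab + 1L)^2
}

#' NAT block parameters
#'
#' Pre-norm transformer block: `X + gamma1 * Mixer(LN(X))` then
#' `X + gamma2 * MLP(LN(X))`, with per-channel LayerScale vectors gamma.
#'
#' @param c channels.
#' @param heads attention heads.
#' @param mlp_ratio hidden width multiple.
#' @param layer_scale_init LayerScale initial value.
#' @param n_off positional-bias table size (ignored for the conv mixer).
#' @param variant mixer type (see [nat_config()]).
#' @return parameter list for one block.
#' @export
nat_block_params <- function(c, heads, mlp_ratio, layer_scale_init = 1e-5,
                             n_off = 9L, variant = "neighborhood") {
  hidden <- max(1L, round(mlp_ratio * c))
  p <- list(ln1 = list(g = rep(1, c), b = numeric(c)),
            ln2 = list(g = rep(1, c), b = numeric(c)),
            gamma1 = rep(layer_scale_init, c),
            gamma2 = rep(layer_scale_init, c),
            mlp = mlp_init(c, hidden))
  if (variant == "conv") {
    p$mixer <- dwconv_init(c)
  } else {
    p$mixer <- attn_params_init(c, heads, n_off)
  }
  attr(p, "variant") <- variant
  p
}

# Mixer context: everything a block needs besides parameters. flat is the
# map_flatten() record of the current grid; index/offmat depend on variant.
make_mixer_ctx <- function(cfg, h, w, valid) {
  variant <- cfg$variant
  rtab_cfg <- max(0L, as.integer(ceiling(sqrt(cfg$k))) - 1L)
  if (variant == "neighborhood") {
    idx <- build_neighborhood_index(h, w, min(cfg$k, sum(valid)), valid,
                                    rtab = rtab_cfg)
    list(variant = variant, index = idx)
  } else if (variant == "window") {
    idx <- build_window_index(h, w, cfg$k, valid)
    # window table radius must match the parameter table built from k
    side <- 2L * rtab_cfg + 1L
    if (idx$rtab != rtab_cfg) {
      # re-clamp offsets into the configured table
      or_ <- (idx$off - 1L) %/% (2L * idx$rtab + 1L) - idx$rtab
      oc_ <- (idx$off - 1L) %% (2L * idx$rtab + 1L) - idx$rtab
      clampv <- function(x) pmin(pmax(x, -rtab_cfg), rtab_cfg)
      idx$off <- (clampv(or_) + rtab_cfg) * side + clampv(oc_) + rtab_cfg + 1L
      idx$rtab <- rtab_cfg
      idx$n_off <- side^2
    }
    list(variant = variant, index = idx)
  } else if (variant == "global") {
    pos <- map_flatten(grid_feature_map(array(0, c(h, w, 1)), valid))
    list(variant = variant,
         offmat = dense_offsets(pos$r, pos$c, rtab_cfg))
  } else {
    list(variant = variant)
  }
}

block_forward <- function(Xmat, bp, ctx, flat) {
  ln1 <- layernorm_forward(Xmat, bp$ln1$g, bp$ln1$b)
  mix <- switch(ctx$variant,
    neighborhood = ,
    window = attn_index_forward(ln1$out, ctx$index, bp$mixer),
    global = attn_dense_forward(ln1$out, bp$mixer, ctx$offmat, NULL),
    conv = {
      g <- map_scatter(ln1$out, flat)
      cv <- dwconv_forward(g, bp$mixer)
      Om <- matrix(cv$out, flat$h * flat$w, dim(cv$out)[3])
      list(out = Om[flat$lin, , drop = FALSE], cache = cv$cache)
    },
    stop("unknown mixer variant '", ctx$variant,
         "'; valid: neighborhood, window, global, conv"))
  X1 <- Xmat + sweep(mix$out, 2L, bp$gamma1, `*`)
  ln2 <- layernorm_forward(X1, bp$ln2$g, bp$ln2$b)
  ml <- mlp_forward(ln2$out, bp$mlp)
  X2 <- X1 + sweep(ml$out, 2L, bp$gamma2, `*`)
  list(out = X2,
       cache = list(ln1 = ln1$cache, mix = mix$cache, mix_out = mix$out,
                    ln2 = ln2$cache, mlp = ml$cache, mlp_out = ml$out,
                    bp = bp, ctx = ctx, flat = flat))
}

block_backward <- function(dout, cache) {
  bp <- cache$bp
  dgamma2 <- colSums(dout * cache$mlp_out)
  dml <- sweep(dout, 2L, bp$gamma2, `*`)
  mb <- mlp_backward(dml, cache$mlp)
  lb2 <- layernorm_backward(mb$dX, cache$ln2)
  dX1 <- dout + lb2$dX
  dgamma1 <- colSums(dX1 * cache$mix_out)
  dmix <- sweep(dX1, 2L, bp$gamma1, `*`)
  if (cache$ctx$variant == "conv") {
    flat <- cache$flat
    dg <- map_scatter(dmix, flat)
    cb <- dwconv_backward(dg, cache$mix)
    dxm <- matrix(cb$dx, flat$h * flat$w, dim(cb$dx)[3])
    ab <- list(dX = dxm[flat$lin, , drop = FALSE], grads = cb$grads)
  } else if (cache$ctx$variant == "global") {
    ab <- attn_dense_backward(dmix, cache$mix)
  } else {
    ab <- attn_index_backward(dmix, cache$mix)
  }
  lb1 <- layernorm_backward(ab$dX, cache$ln1)
  dX <- dX1 + lb1$dX
  list(dX = dX,
       grads = list(ln1 = list(g = lb1$dg, b = lb1$db),
                    ln2 = list(g = lb2$dg, b = lb2$db),
                    gamma1 = dgamma1, gamma2 = dgamma2,
                    mlp = mb$grads, mixer = ab$grads))
}

#' Apply one NAT block to a grid feature map
#'
#' @param X a [grid_feature_map()].
#' @param params from [nat_block_params()].
#' @param k neighborhood size.
#' @param variant mixer variant.
#' @return a `grid_feature_map`.
#' @export
nat_block <- function(X, params, k, variant = "neighborhood") {
  flat <- map_flatten(X)
  cfg <- list(k = k, variant = variant)
  ctx <- make_mixer_ctx(cfg, flat$h, flat$w, X$valid)
  fw <- block_forward(flat$X, params, ctx, flat)
  grid_feature_map(map_scatter(fw$out, flat), X$valid)
}

#' Initialize backbone parameters
#'
#' @param config a [nat_config()].
#' @param seed integer seed for the truncated-normal initializers.
#' @return nested parameter list: `tokenizer`, `stages` (each a list of
#'   block parameter lists) and `downsamplers`.
#' @export
init_backbone <- function(config, seed = 1L) {
  ch <- stage_channels(config)
  n_off <- k_table_size(config$k)
  with_seed(seed, {
    tok <- if (config$tokenizer == "conv") {
      list(conv1 = conv2d_init(config$in_channels, config$base_channels),
           conv2 = conv2d_init(config$base_channels, config$base_channels))
    } else {
      list(We = init_mat(config$in_channels, config$base_channels),
           be = numeric(config$base_channels))
    }
    stages <- lapply(seq_len(4L), function(i) {
      lapply(seq_len(config$depths[i]), function(j) {
        nat_block_params(ch[i], config$heads, config$mlp_ratio,
                         config$layer_scale_init, n_off, config$variant)
      })
    })
    downs <- if (config$downsample) {
      lapply(seq_len(3L), function(i) conv2d_init(ch[i], ch[i + 1L]))
    } else {
      list()
    }
    list(tokenizer = tok, stages = stages, downsamplers = downs)
  })
}

#' Tokenize an input into the first-stage grid
#'
#' Conv tokenizer: two overlapping 3x3 stride-2 convolutions (padding 1)
#' with GELU between, spatial size `ceil(in/4)`. Linear tokenizer: a 1x1
#' embedding preserving the grid.
#'
#' @param x RGB raster array or [grid_feature_map()].
#' @param params backbone parameters ([init_backbone()]`$tokenizer`).
#' @param config the [nat_config()].
#' @return a `grid_feature_map` with `base_channels` channels.
#' @export
tokenize <- function(x, params, config) {
  if (inherits(x, "grid_feature_map")) {
    valid <- x$valid
    arr <- x$X
  } else {
    stopifnot(length(dim(x)) == 3L)
    arr <- x
    valid <- matrix(TRUE, dim(x)[1], dim(x)[2])
  }
  if (config$tokenizer == "conv") {
    if (min(dim(arr)[1:2]) < 4L) stop("conv tokenizer needs spatial dims >= 4")
    c1 <- conv2d_forward(arr, params$conv1, stride = 2L, pad = 1L)
    a1 <- gelu(c1$out)
    c2 <- conv2d_forward(a1, params$conv2, stride = 2L, pad = 1L)
    v <- pool_valid(pool_valid(valid))
    grid_feature_map(c2$out, v)
  } else {
    flat <- map_flatten(grid_feature_map(arr, valid))
    emb <- sweep(flat$X %*% params$We, 2L, params$be, `+`)
    grid_feature_map(map_scatter(emb, flat), valid)
  }
}

# Validity pooling for a stride-2 halving: OR over each 2x2 block.
pool_valid <- function(valid) {
  h <- nrow(valid); w <- ncol(valid)
  nh <- ceiling(h / 2); nw <- ceiling(w / 2)
  out <- matrix(FALSE, nh, nw)
  for (i in seq_len(nh)) {
    rs <- (2L * i - 1L):min(2L * i, h)
    for (j in seq_len(nw)) {
      cs <- (2L * j - 1L):min(2L * j, w)
      out[i, j] <- any(valid[rs, cs])
    }
  }
  out
}

#' Downsample a grid feature map
#'
#' 3x3 stride-2 convolution (padding 1): spatial size `ceil(in/2)`,
#' channels doubled; validity pooled by logical OR over each 2x2 block.
#'
#' @param map a [grid_feature_map()].
#' @param params a `conv2d_init(c, 2c)` parameter list.
#' @return a `grid_feature_map`.
#' @export
downsample_grid <- function(map, params) {
  # ceil(1/2) = 1: a 1x1 map passes through spatially, channels still double
  if (min(dim(map$X)[1:2]) < 1L) stop("downsampler needs spatial dims >= 1")
  cv <- conv2d_forward(map$X, params, stride = 2L, pad = 1L)
  grid_feature_map(cv$out, pool_valid(map$valid))
}

#' Run the hierarchical backbone
#'
#' Tokenizer, then four stages of NAT blocks with downsamplers after
#' stages 1-3 (when `config$downsample`), returning all four stage maps
#' plus a masked global-average-pooled final embedding.
#'
#' @param x input raster or `grid_feature_map`.
#' @param params from [init_backbone()].
#' @param config the matching [nat_config()].
#' @return list with `maps` (4 `grid_feature_map`s) and `pooled` (final
#'   channel vector).
#' @export
forward_backbone <- function(x, params, config) {
  map <- tokenize(x, params$tokenizer, config)
  maps <- vector("list", 4L)
  for (i in seq_len(4L)) {
    dims <- dim(map$X)
    if (min(dims[1:2]) < 1L || !any(map$valid)) {
      stop(sprintf("stage %d input collapsed to %dx%d valid=%d",
                   i, dims[1], dims[2], sum(map$valid)))
    }
    flat <- map_flatten(map)
    ctx <- make_mixer_ctx(config, flat$h, flat$w, map$valid)
    Xmat <- flat$X
    for (bp in params$stages[[i]]) {
      Xmat <- block_forward(Xmat, bp, ctx, flat)$out
    }
    map <- grid_feature_map(map_scatter(Xmat, flat), map$valid)
    maps[[i]] <- map
    if (i < 4L && config$downsample) {
      map <- downsample_grid(map, params$downsamplers[[i]])
    }
  }
  final <- map_flatten(maps[[4L]])
  list(maps = maps, pooled = colMeans(final$X))
}
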