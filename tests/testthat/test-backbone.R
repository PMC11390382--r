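# Tokenizer, downsampler, NAT block and the hierarchical backbone.

toy_cfg <- function(...) {
  nat_config(depths = c(1, 1, 1, 1), heads = 2, mlp_ratio = 2, k = 4,
             base_channels = 8, mode = "image", ...)
}

test_that("conv tokenizer quarters space; zero input with zero bias gives zeros", {
  cfg <- toy_cfg()
  par <- init_backbone(cfg, seed = 1)
  t8 <- tokenize(array(rnorm(8 * 8 * 3), c(8, 8, 3)), par$tokenizer, cfg)
  expect_equal(dim(t8$X), c(2, 2, 8))
  t33 <- tokenize(array(rnorm(33 * 30 * 3), c(33, 30, 3)), par$tokenizer, cfg)
  expect_equal(dim(t33$X)[1:2], c(ceiling(33 / 4), ceiling(30 / 4)))

  tz <- tokenize(array(0, c(8, 8, 3)), par$tokenizer, cfg)
  expect_true(all(tz$X == 0)) # conv biases initialize to zero
  expect_error(tokenize(array(0, c(3, 3, 3)), par$tokenizer, cfg), ">= 4")
})

test_that("downsampler halves space, doubles channels, ORs validity", {
  p <- natmil:::with_seed(2, natmil:::conv2d_init(4, 8))
  m7 <- grid_feature_map(array(rnorm(7 * 7 * 4), c(7, 7, 4)))
  expect_equal(dim(downsample_grid(m7, p)$X), c(4, 4, 8))
  m2 <- grid_feature_map(array(rnorm(2 * 2 * 4), c(2, 2, 4)))
  expect_equal(dim(downsample_grid(m2, p)$X), c(1, 1, 8))

  valid <- matrix(FALSE, 4, 4); valid[1, 2] <- TRUE
  mv <- grid_feature_map(array(rnorm(4 * 4 * 4), c(4, 4, 4)), valid)
  dv <- downsample_grid(mv, p)
  expect_identical(dv$valid, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
})

test_that("LayerScale zero makes a NAT block the identity; masks persist", {
  bp <- natmil:::with_seed(3, nat_block_params(8, 2, 2, layer_scale_init = 0,
                                               n_off = 9))
  X <- rand_map(5, 5, 8, masked = TRUE)
  out <- nat_block(X, bp, k = 4)
  expect_equal(out$X, X$X, tolerance = 1e-12)
  bp2 <- natmil:::with_seed(3, nat_block_params(8, 2, 2, layer_scale_init = 0.3,
                                                n_off = 9))
  out2 <- nat_block(X, bp2, k = 4)
  expect_true(all(out2$X[, , 1][!X$valid] == 0))
})

test_that("a NAT block matches its straight-line oracle composition", {
  natmil:::with_seed(4, {
    X <- rand_map(6, 6, 8)
    bp <- nat_block_params(8, 2, 3, layer_scale_init = 0.2,
                           n_off = natmil:::k_table_size(9))
    bp$mixer$B <- matrix(rnorm(length(bp$mixer$B), 0, 0.2), nrow(bp$mixer$B))
    out <- nat_block(X, bp, k = 9)
    # independent composition: LN -> oracle attention -> scale/skip -> LN ->
    # explicit MLP -> scale/skip
    flat <- natmil:::map_flatten(X)
    ln <- function(M, g, b) {
      t(apply(M, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6))) *
        rep(g, each = nrow(M)) + rep(b, each = nrow(M))
    }
    idx <- build_neighborhood_index(6, 6, 9)
    A <- natmil:::map_flatten(
      oracle_masked_attention(grid_feature_map(natmil:::map_scatter(
        ln(flat$X, bp$ln1$g, bp$ln1$b), flat)), bp$mixer, idx))$X
    X1 <- flat$X + sweep(A, 2, bp$gamma1, `*`)
    Z <- ln(X1, bp$ln2$g, bp$ln2$b)
    gelu_ref <- function(x) {
      u <- sqrt(2 / pi) * (x + 0.044715 * x^3)
      0.5 * x * (1 + tanh(u))
    }
    M <- gelu_ref(sweep(Z %*% bp$mlp$W1, 2, bp$mlp$b1, `+`)) %*% bp$mlp$W2
    M <- sweep(M, 2, bp$mlp$b2, `+`)
    X2 <- X1 + sweep(M, 2, bp$gamma2, `*`)
    expect_lt(max(abs(natmil:::map_flatten(out)$X - X2)), 1e-5)
  })
})

test_that("stage outputs halve space and double channels at every boundary", {
  cfg <- toy_cfg()
  par <- init_backbone(cfg, seed = 5)
  for (px in c(32, 48, 64)) {
    out <- suppressWarnings(
      forward_backbone(array(rnorm(px * px * 3), c(px, px, 3)), par, cfg))
    s <- ceiling(px / 4)
    for (i in 1:4) {
      expect_equal(dim(out$maps[[i]]$X),
                   c(s, s, 8 * 2^(i - 1)),
                   info = sprintf("px=%d stage=%d", px, i))
      if (i < 4) s <- ceiling(s / 2)
    }
    expect_length(out$pooled, 64)
  }
  # tile mode: linear tokenizer preserves the grid before the downsamplers
  cfgt <- nat_config(depths = c(1, 1, 1, 1), heads = 2, mlp_ratio = 2, k = 4,
                     base_channels = 8, mode = "tiles", in_channels = 6)
  part <- init_backbone(cfgt, seed = 6)
  bag <- quick_bags(2, grid = 16, d = 6, seed = 3)[[1]]
  outt <- suppressWarnings(forward_backbone(grid_from_bag(bag), part, cfgt))
  expect_equal(dim(outt$maps[[1]]$X), c(16, 16, 8))
  expect_equal(dim(outt$maps[[4]]$X), c(2, 2, 64))
})

test_that("empty stages reduce the backbone to tokenizer + downsamplers", {
  cfg <- nat_config(depths = c(0, 0, 0, 0), heads = 2, base_channels = 8,
                    mode = "image")
  par <- init_backbone(cfg, seed = 7)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  out <- forward_backbone(x, par, cfg)
  ref <- tokenize(x, par$tokenizer, cfg)
  expect_equal(out$maps[[1]]$X, ref$X)
  for (i in 1:3) ref <- downsample_grid(ref, par$downsamplers[[i]])
  expect_equal(out$maps[[4]]$X, ref$X)
})

test_that("the backbone is deterministic and size-independent in parameters", {
  cfg <- toy_cfg()
  p1 <- init_backbone(cfg, seed = 9)
  p2 <- init_backbone(cfg, seed = 9)
  expect_identical(p1, p2)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  o1 <- suppressWarnings(forward_backbone(x, p1, cfg))
  o2 <- suppressWarnings(forward_backbone(x, p2, cfg))
  expect_identical(o1, o2)
  n0 <- count_params(p1)
  for (px in c(16, 32)) {
    invisible(suppressWarnings(forward_backbone(array(0, c(px, px, 3)), p1, cfg)))
    expect_identical(count_params(p1), n0)
  }
})

test_that("with maximal k the backbone equals its global-attention twin", {
  cfg_na <- nat_config(depths = c(1, 1, 1, 1), heads = 2, mlp_ratio = 2,
                       k = 64, base_channels = 8, mode = "image",
                       variant = "neighborhood")
  cfg_gl <- cfg_na
  cfg_gl$variant <- "global"
  p <- init_backbone(cfg_na, seed = 11) # same shapes for both variants
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  o_na <- suppressWarnings(forward_backbone(x, p, cfg_na))
  o_gl <- suppressWarnings(forward_backbone(x, p, cfg_gl))
  for (i in 1:4) {
    expect_lt(max(abs(o_na$maps[[i]]$X - o_gl$maps[[i]]$X)), 1e-4)
  }
})
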