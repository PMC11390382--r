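# Augmentations, NT-Xent, encoder training and feature extraction.

test_that("augmentation is deterministic, identity at zero strength, varied otherwise", {
  tile <- array(stats::runif(12 * 12 * 3), c(12, 12, 3))
  a1 <- augment(tile, seed = 5)
  a2 <- augment(tile, seed = 5)
  expect_identical(a1, a2)

  z <- augment(tile, seed = 5,
               augment_strengths(crop_min = 1, flip_prob = 0, jitter = 0,
                                 blur_max = 0))
  expect_identical(z$view_a, tile)
  expect_identical(z$view_b, tile)

  diffs <- vapply(1:25, function(i) {
    pr <- augment(tile, seed = i)
    mean(abs(pr$view_a - pr$view_b))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_true(all(diffs >= 0))
})

test_that("NT-Xent reproduces its analytic values", {
  # orthonormal two-pair batch: each anchor sees sims (1, 0, 0)
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(nt_xent_loss(Z, tau = 1), -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-12)

  for (N in c(2, 4, 8)) {
    Zsame <- matrix(rep(c(1, rep(0, 3)), 2 * N), ncol = 4, byrow = TRUE)
    expect_equal(nt_xent_loss(Zsame, tau = 0.7), log(2 * N - 1),
                 tolerance = 1e-12)
  }

  expect_error(nt_xent_loss(Z, tau = 0), "tau")
  expect_error(nt_xent_loss(Z[1:2, , drop = FALSE], 1), "pairs")
})

test_that("NT-Xent is permutation-invariant over pairs and concentrates in high dim", {
  natmil:::with_seed(12, {
    p <- 48
    Z <- matrix(rnorm(12 * p), 12, p)
    Z <- Z / sqrt(rowSums(Z^2))
    l0 <- nt_xent_loss(Z, 0.5)
    perm <- sample(6)
    idx <- as.vector(rbind(2 * perm - 1, 2 * perm))
    expect_equal(nt_xent_loss(Z[idx, ], 0.5), l0, tolerance = 1e-12)

    # random unit vectors, p >> 1: loss near log(2N - 1)
    vals <- vapply(1:10, function(s) {
      Zr <- natmil:::with_seed(s, matrix(rnorm(128 * 256), 128, 256))
      Zr <- Zr / sqrt(rowSums(Zr^2))
      nt_xent_loss(Zr, 1)
    }, numeric(1))
    expect_lt(max(abs(vals - log(127)) / log(127)), 0.05)
  })
})

test_that("contrastive training lowers the NT-Xent loss and is reproducible", {
  # scaled to desk size: 60 tiles of 12 px (the full-size recipe is the
  # same loop at 256 px)
  tx <- make_texture_tiles(30, px = 12, seed = 4)
  cfg <- encoder_config(channels = 6, n_blocks = 1, d = 16, proj_hidden = 16,
                        proj_out = 8, epochs = 12, batch_size = 16, lr = 3e-3)
  enc <- train_encoder(tx$tiles, cfg, seed = 0)
  expect_lt(mean(tail(enc$loss_trace, 3)), enc$loss_trace[1])

  cfg2 <- encoder_config(channels = 4, n_blocks = 1, d = 8, proj_hidden = 8,
                         proj_out = 4, epochs = 2, batch_size = 8, lr = 2e-3)
  e1 <- train_encoder(tx$tiles[1:16], cfg2, seed = 3)
  e2 <- train_encoder(tx$tiles[1:16], cfg2, seed = 3)
  expect_identical(e1$loss_trace, e2$loss_trace)
  expect_lt(natmil:::tree_max_abs_diff(e1$params, e2$params), 1e-15)

  cfg0 <- encoder_config(channels = 4, n_blocks = 1, d = 8, proj_hidden = 8,
                         proj_out = 4, epochs = 2, batch_size = 8, lr = 0)
  p0 <- natmil:::init_encoder(cfg0, natmil:::derive_seed(3, 1))
  e0 <- train_encoder(tx$tiles[1:16], cfg0, seed = 3)
  expect_lt(natmil:::tree_max_abs_diff(e0$params, p0), 1e-15)

  expect_error(train_encoder(tx$tiles[1:4],
                             encoder_config(batch_size = 1)), "batch")
})

test_that("extract_features follows the manifest and separates textures", {
  # tiles cut from a generated slide, labels from the generator itself
  sl <- generate_slide(slide_spec(10, 10, tile_px = 12, tumor_fraction = 0.4,
                                  blob_count = 1, tissue_fraction = 1,
                                  seed = 21))
  man <- tile_slide(sl$image, NULL, 12, 0, "s21")
  labs <- sl$tile_labels[cbind(man$row + 1L, man$col + 1L)]

  cfg <- encoder_config(channels = 6, n_blocks = 1, d = 16, proj_hidden = 16,
                        proj_out = 8, epochs = 8, batch_size = 16, lr = 3e-3)
  train_idx <- which(seq_len(nrow(man)) %% 2 == 1)
  tiles_all <- lapply(seq_len(nrow(man)),
                      function(i) natmil:::crop_tile(sl$image, man$x[i], man$y[i], 12))
  enc <- train_encoder(tiles_all[train_idx], cfg, seed = 2)

  bag <- extract_features(enc, man, sl$image, label = sl$slide_label)
  expect_equal(dim(bag$H), c(nrow(man), 16))
  expect_identical(bag$rows, man$row)

  # single-tile manifest
  man1 <- man[1, , drop = FALSE]
  attr(man1, "tile_px") <- 12L
  class(man1) <- class(man)
  b1 <- extract_features(enc, man1, sl$image)
  expect_equal(dim(b1$H), c(1, 16))
  expect_equal(as.vector(b1$H), as.vector(bag$H[1, ]), tolerance = 1e-10)

  # re-extracting the same tile reproduces its feature row exactly
  b1b <- extract_features(enc, man1, sl$image)
  expect_identical(b1$H, b1b$H)

  expect_error(extract_features(enc, man[0, , drop = FALSE], sl$image), "empty")

  # held-out linear probe separates tumor vs normal embeddings
  test_idx <- which(seq_len(nrow(man)) %% 2 == 0)
  dirv <- colMeans(bag$H[intersect(train_idx, which(labs == 1)), , drop = FALSE]) -
    colMeans(bag$H[intersect(train_idx, which(labs == 0)), , drop = FALSE])
  sc <- as.vector(bag$H[test_idx, ] %*% dirv)
  expect_gt(compute_metrics(labs[test_idx], sc)$auc, 0.9)
})
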