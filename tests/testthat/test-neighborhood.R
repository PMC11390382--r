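# The neighborhood-attention operator, its index, and the oracle.

test_that("index construction matches a brute-force sort of all positions", {
  idx <- build_neighborhood_index(1, 1, 1)
  expect_equal(idx$nb, matrix(1L, 1, 1))

  idx9 <- build_neighborhood_index(3, 3, 9)
  for (i in 1:9) expect_setequal(idx9$nb[i, ], 1:9)

  # spec'd corner case: 4x4 grid, k=4, query (0,0)
  idx4 <- build_neighborhood_index(4, 4, 4)
  nb_rc <- cbind(idx4$r[idx4$nb[1, ]], idx4$c[idx4$nb[1, ]])
  expect_equal(nb_rc[order(nb_rc[, 1], nb_rc[, 2]), ],
               cbind(c(1, 1, 2, 2), c(1, 2, 1, 2)))

  natmil:::with_seed(8, {
    for (rep in 1:25) {
      h <- sample(2:7, 1); w <- sample(2:7, 1)
      valid <- matrix(runif(h * w) > 0.3, h, w)
      if (!any(valid)) valid[1, 1] <- TRUE
      k <- sample.int(sum(valid), 1)
      idx <- build_neighborhood_index(h, w, k, valid)
      for (q in sample(nrow(idx$nb), min(4, nrow(idx$nb)))) {
        want <- ref_neighbors(h, w, k, valid, idx$r[q], idx$c[q])
        got <- cbind(idx$r[idx$nb[q, ]], idx$c[idx$nb[q, ]])
        expect_equal(got, unname(want))
      }
    }
  })
})

test_that("index clamps k and rejects empty masks", {
  expect_warning(idx <- build_neighborhood_index(2, 2, 9), "clamped")
  expect_equal(idx$k, 4L)
  expect_error(build_neighborhood_index(2, 2, 1, matrix(FALSE, 2, 2)), "valid")
  expect_error(build_neighborhood_index(2, 2, 0), "k must")
})

test_that("neighborhood attention agrees with the masked-attention oracle", {
  natmil:::with_seed(3, {
    for (rep in 1:15) {
      h <- sample(2:6, 1); w <- sample(2:6, 1)
      c <- sample(c(4, 8), 1); heads <- sample(c(1, 2), 1)
      X <- rand_map(h, w, c, masked = rep %% 3 == 0)
      k <- min(sample(c(1, 2, 4, 8, 9), 1), sum(X$valid))
      idx <- build_neighborhood_index(h, w, k, X$valid)
      p <- attn_params_init(c, heads, idx$n_off)
      p$B <- matrix(rnorm(length(p$B), 0, 0.5), nrow(p$B))
      out <- neighborhood_attention(X, p, k, idx)
      orc <- oracle_masked_attention(X, p, idx)
      expect_lt(max(abs(out$X - orc$X)), 1e-5)
      expect_true(all(out$X[, , 1][!X$valid] == 0))
    }
  })
})

test_that("1x1 grid reduces to the output projection of V", {
  X <- grid_feature_map(array(rnorm(6), c(1, 1, 6)))
  p <- natmil:::with_seed(1, attn_params_init(6, 2, 1))
  out <- neighborhood_attention(X, p, 1)
  v <- as.vector(X$X[1, 1, ] %*% p$Wv + p$bv)
  expect_equal(as.vector(out$X[1, 1, ]), as.vector(v %*% p$Wo + p$bo),
               tolerance = 1e-10)
})

test_that("k = full grid with B = 0 equals global self-attention", {
  natmil:::with_seed(5, {
    for (heads in c(1, 2, 4)) {
      h <- 5; w <- 4; c <- 8
      X <- rand_map(h, w, c)
      idx <- build_neighborhood_index(h, w, h * w)
      p <- attn_params_init(c, heads, idx$n_off)
      out <- neighborhood_attention(X, p, h * w, idx)
      ref <- ref_global_attention(natmil:::map_flatten(X)$X, p, heads)
      expect_lt(max(abs(natmil:::map_flatten(out)$X - ref)), 1e-5)
    }
  })
})

test_that("attention rows are stochastic and local", {
  natmil:::with_seed(6, {
    X <- rand_map(5, 5, 8)
    idx <- build_neighborhood_index(5, 5, 9)
    p <- attn_params_init(8, 2, idx$n_off)
    wts <- na_attention_weights(X, p, 9, idx)
    for (P in wts$P) {
      expect_true(all(abs(rowSums(P) - 1) < 1e-6))
      expect_true(all(P >= 0))
    }
    # locality: perturbing a tile outside neighbors(i) leaves output at i alone
    out1 <- neighborhood_attention(X, p, 9, idx)
    q <- 13 # center of the 5x5 grid, raster order -> (3, 3)
    outside <- setdiff(seq_len(25), idx$nb[q, ])
    X2 <- X
    pos <- outside[1]
    rr <- idx$r[pos]; cc <- idx$c[pos]
    X2$X[rr, cc, ] <- X2$X[rr, cc, ] + 10
    out2 <- neighborhood_attention(X2, p, 9, idx)
    expect_lt(max(abs(out1$X[3, 3, ] - out2$X[3, 3, ])), 1e-10)
    expect_gt(max(abs(out1$X - out2$X)), 1e-4) # but something changed
  })
})

test_that("interior outputs are translationally equivariant", {
  natmil:::with_seed(7, {
    h <- 9; w <- 9; c <- 4; k <- 9
    core <- array(rnorm(3 * 3 * c), c(3, 3, c))
    base <- array(rnorm(h * w * c), c(h, w, c))
    place <- function(r0, c0) {
      X <- base
      X[r0:(r0 + 2), c0:(c0 + 2), ] <- core
      grid_feature_map(X)
    }
    idx <- build_neighborhood_index(h, w, k)
    p <- attn_params_init(c, 2, idx$n_off)
    p$B <- matrix(rnorm(length(p$B), 0, 0.3), nrow(p$B))
    # shift the core by (1, 2); compare outputs at the core centers, whose
    # full 3x3 windows see identical content in both placements
    o1 <- neighborhood_attention(place(4, 3), p, k, idx)
    o2 <- neighborhood_attention(place(5, 5), p, k, idx)
    expect_lt(max(abs(o1$X[5, 4, ] - o2$X[6, 6, ])), 1e-8)
  })
})

test_that("outputs follow grid geometry, not bag storage order", {
  natmil:::with_seed(9, {
    bags <- quick_bags(2, grid = 5, d = 6, seed = 2)
    bag <- bags[[1]]
    perm <- sample(nrow(bag$H))
    bag2 <- bag
    bag2$H <- bag$H[perm, , drop = FALSE]
    bag2$rows <- bag$rows[perm]
    bag2$cols <- bag$cols[perm]
    m1 <- grid_from_bag(bag)
    m2 <- grid_from_bag(bag2)
    expect_identical(m1, m2)
    p <- attn_params_init(6, 2, build_neighborhood_index(5, 5, 4)$n_off)
    expect_identical(neighborhood_attention(m1, p, 4),
                     neighborhood_attention(m2, p, 4))
  })
})
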