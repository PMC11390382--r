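# Synthetic slide and feature-bag generators.

test_that("generate_slide handles empty and saturated tumor fractions", {
  s0 <- generate_slide(slide_spec(8, 8, tile_px = 8, tumor_fraction = 0,
                                  blob_count = 0, seed = 1))
  expect_true(all(s0$tile_labels == 0))
  expect_identical(s0$slide_label, 0L)

  s1 <- generate_slide(slide_spec(8, 8, tile_px = 8, tumor_fraction = 1,
                                  blob_count = 1, seed = 1))
  expect_true(all(s1$tile_labels == 1))
  expect_identical(s1$slide_label, 1L)
})

test_that("tumor fraction is controlled by construction", {
  # spec'd case: 32x32 at 5% -> between 45 and 57 of 1024 tiles
  sl <- generate_slide(slide_spec(32, 32, tile_px = 8, tumor_fraction = 0.05,
                                  blob_count = 2, seed = 7))
  n_tumor <- sum(sl$tile_labels)
  expect_gte(n_tumor, 45)
  expect_lte(n_tumor, 57)
  expect_identical(n_tumor, 51L) # floor(0.05 * 1024), exact by construction

  for (seed in 1:3) {
    sp <- slide_spec(32, 40, tile_px = 8, tumor_fraction = 0.12,
                     blob_count = 3, seed = seed)
    sl <- generate_slide(sp)
    expect_lt(abs(mean(sl$tile_labels) - 0.12), 0.02)
    expect_identical(sl$slide_label, as.integer(any(sl$tile_labels == 1)))
  }
})

test_that("tumor tiles form few connected blobs and sit inside tissue", {
  sl <- generate_slide(slide_spec(24, 24, tile_px = 8, tumor_fraction = 0.08,
                                  blob_count = 2, seed = 3))
  lab <- natmil:::label_components(sl$tile_labels == 1)
  expect_gte(max(lab), 1)
  expect_lte(max(lab), 2) # blobs may merge, never fragment
  expect_true(all(sl$tissue_tiles[sl$tile_labels == 1]))
})

test_that("tumor texture carries the periodic luminance motif", {
  sl <- generate_slide(slide_spec(16, 16, tile_px = 8, tumor_fraction = 1,
                                  blob_count = 1, motif_period = 8,
                                  noise_sd = 0, seed = 2))
  # all-tumor noise-free slide: per-tile-column luminance is exactly
  # base * (1 + 0.15 sin(2 pi c / 8))
  colmeans <- sapply(seq_len(16), function(c) {
    mean(sl$image[, ((c - 1) * 8 + 1):(c * 8), 1])
  })
  expected <- 0.48 * (1 + 0.15 * sin(2 * pi * (0:15) / 8))
  expect_lt(max(abs(colmeans - pmin(expected, 1))), 1e-6)
  # period 8: identical every 8 columns, not constant
  expect_lt(max(abs(colmeans[1:8] - colmeans[9:16])), 1e-9)
  expect_gt(diff(range(colmeans)), 0.05)
})

test_that("slide generation is deterministic and validates its spec", {
  a <- generate_slide(slide_spec(8, 8, tile_px = 8, seed = 5))
  b <- generate_slide(slide_spec(8, 8, tile_px = 8, seed = 5))
  expect_identical(a, b)
  expect_error(generate_slide(slide_spec(8, 8, tumor_fraction = 0.2,
                                         blob_count = 0)), "blob_count")
  expect_error(generate_slide(slide_spec(2, 8)), ">= 4")
  expect_error(generate_slide(slide_spec(8, 8, tile_px = 4)), "tile_px")
})

test_that("write_slide emits a readable raster and label table", {
  sl <- generate_slide(slide_spec(8, 8, tile_px = 8, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_slide(sl, dir, "s1")
  img <- read_ppm(paths[["image"]])
  expect_equal(dim(img), dim(sl$image))
  expect_lt(max(abs(img - sl$image)), 1 / 255)
  df <- read.csv(paths[["labels"]])
  expect_equal(nrow(df), 64)
  expect_equal(sum(df$label), sum(sl$tile_labels))
})

test_that("feature bags respect labels, counts and determinism", {
  bags <- generate_feature_bags(bag_spec(10, 6, 6, d = 8, positive_fraction = 0.5,
                                         seed = 4))
  labs <- vapply(bags, `[[`, integer(1), "label")
  expect_identical(sum(labs), 5L) # forced by construction
  for (b in bags) {
    expect_identical(b$label, as.integer(any(b$tile_labels == 1)))
    if (b$label == 0L) expect_true(all(b$tile_labels == 0))
  }
  again <- generate_feature_bags(bag_spec(10, 6, 6, d = 8, positive_fraction = 0.5,
                                          seed = 4))
  expect_identical(bags, again)

  expect_error(generate_feature_bags(bag_spec(1, 4, 4)), "n_bags")
  expect_error(generate_feature_bags(bag_spec(10, 4, 4, d = 1)), "d must")
  expect_error(generate_feature_bags(bag_spec(10, 4, 4, positive_fraction = 1)),
               "positive_fraction")
})

test_that("clustered positives occupy one contiguous region", {
  bags <- generate_feature_bags(bag_spec(8, 10, 10, d = 4, tumor_fraction = 0.1,
                                         cluster = TRUE, seed = 9))
  for (b in bags) {
    if (b$label == 0L) next
    tl <- matrix(FALSE, 10, 10)
    tl[cbind(b$rows + 1L, b$cols + 1L)] <- b$tile_labels == 1L
    expect_identical(max(natmil:::label_components(tl)), 1L)
  }
})

test_that("zero class separation leaves tumor and normal tiles exchangeable", {
  bags <- generate_feature_bags(bag_spec(40, 8, 8, d = 8, class_separation = 0,
                                         stain_sd = 0, seed = 2))
  Ht <- do.call(rbind, lapply(bags, function(b) b$H[b$tile_labels == 1, , drop = FALSE]))
  Hn <- do.call(rbind, lapply(bags, function(b) b$H[b$tile_labels == 0, , drop = FALSE]))
  # standard errors: both groups are N(0, I) draws
  se <- sqrt(1 / nrow(Ht) + 1 / nrow(Hn))
  expect_lt(max(abs(colMeans(Ht) - colMeans(Hn))), 5 * se)
})

test_that("large separation yields a near-perfectly separable probe", {
  spec <- bag_spec(200, 12, 12, d = 16, class_separation = 6, seed = 1)
  bags <- generate_feature_bags(spec)
  labs <- vapply(bags, `[[`, integer(1), "label")
  M <- t(vapply(bags, function(b) colMeans(b$H), numeric(16)))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, M), labs, family = stats::binomial()))
  co <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  scores <- as.vector(cbind(1, M) %*% co)
  expect_gt(compute_metrics(labs, scores)$auc, 0.95)
})

test_that("feature bags round-trip through TSV + JSON", {
  bags <- generate_feature_bags(bag_spec(2, 4, 4, d = 5, seed = 3))
  dir <- withr::local_tempdir()
  path <- write_feature_bag(bags[[1]], dir)
  back <- read_feature_bag(path)
  expect_identical(back$slide_id, bags[[1]]$slide_id)
  expect_identical(back$label, bags[[1]]$label)
  expect_identical(back$rows, bags[[1]]$rows)
  expect_identical(back$tile_labels, bags[[1]]$tile_labels)
  expect_lt(max(abs(back$H - bags[[1]]$H)), 1e-10)
})
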