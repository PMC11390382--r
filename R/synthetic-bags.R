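# Feature-space bag generator: bags of tile embeddings on a grid with
# slide-level labels derived from tile composition (the MIL assumption),
# bypassing images entirely so the attention/MIL stages can be exercised in
# milliseconds.

#' Specification of a synthetic feature-bag collection
#'
#' Tile embeddings are isotropic Gaussians: normal tiles ~ N(b, I_d) and
#' tumor tiles ~ N(b + s * mu, I_d), where mu is one random unit direction
#' shared by the whole collection and s is `class_separation` (the
#' Mahalanobis distance between the two tile distributions). b is a
#' per-bag slide-level stain/batch shift drawn from a rank-3 Gaussian,
#' `b = stain_sd * (z1 mu + z2 v1 + z3 v2)` with z ~ N(0, 1) and v1, v2
#' orthonormal directions: stain variation in H&E is low-dimensional and
#' co-varies with the stain-density axis that also separates tumor from
#' normal tissue (the mu component). Because the shift has sd `stain_sd`
#' along mu, mean-pooling cannot project the nuisance away, which is what
#' makes sparse-tumor bags hard for global pooling while per-tile
#' attention remains informative.
#'
#' @param n_bags number of bags (>= 2).
#' @param grid_height,grid_width tile grid; every cell holds a tile.
#' @param d embedding dimension (>= 2).
#' @param positive_fraction fraction of bags labelled 1, in (0, 1); the
#'   realized count is `round(n_bags * positive_fraction)`, clamped so both
#'   classes occur.
#' @param tumor_fraction fraction of tiles that are tumor in each positive
#'   bag (realized count `max(1, round(fraction * n_tiles))`).
#' @param cluster if `TRUE` tumor tiles form one contiguous grid region
#'   (random-walk growth); otherwise they are scattered uniformly.
#' @param class_separation distance between tumor and normal tile
#'   distributions (identity covariance, so Mahalanobis = Euclidean).
#' @param stain_sd standard deviation of the per-bag stain shift along
#'   each of its three axes (default 1, comparable to per-tile noise; 0
#'   disables the nuisance).
#' @param seed integer seed.
#' @return a `synthetic_bag_spec`.
#' @export
bag_spec <- function(n_bags, grid_height = 16, grid_width = 16, d = 32,
                     positive_fraction = 0.5, tumor_fraction = 0.5,
                     cluster = TRUE, class_separation = 4,
                     stain_sd = 1, seed = 1L) {
  spec <- list(n_bags = as.integer(n_bags),
               grid_height = as.integer(grid_height),
               grid_width = as.integer(grid_width),
               d = as.integer(d),
               positive_fraction = positive_fraction,
               tumor_fraction = tumor_fraction,
               cluster = isTRUE(cluster),
               class_separation = class_separation,
               stain_sd = stain_sd,
               seed = as.integer(seed))
  class(spec) <- "synthetic_bag_spec"
  spec
}

new_feature_bag <- function(slide_id, H, rows, cols, label, tile_labels = NULL) {
  stopifnot(nrow(H) >= 1L, length(rows) == nrow(H), length(cols) == nrow(H))
  if (anyDuplicated(paste(rows, cols))) stop("duplicate (row, col) tile coordinates")
  structure(list(slide_id = slide_id, H = H,
                 rows = as.integer(rows), cols = as.integer(cols),
                 label = as.integer(label),
                 tile_labels = tile_labels),
            class = "feature_bag")
}

#' Generate synthetic feature bags
#'
#' @param spec a [bag_spec()].
#' @return list of `feature_bag` objects (fields `slide_id`, `H` (n x d),
#'   `rows`, `cols` (0-based grid coordinates), `label`, `tile_labels`).
#'   Positive bags contain at least one tumor tile; negative bags contain
#'   none. Deterministic per seed.
#' @export
generate_feature_bags <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bag_spec"))
  if (spec$n_bags < 2L) stop("n_bags must be >= 2 (both classes must occur)")
  if (spec$d < 2L) stop("d must be >= 2")
  if (spec$positive_fraction <= 0 || spec$positive_fraction >= 1) {
    stop("positive_fraction must be in (0, 1)")
  }
  h <- spec$grid_height; w <- spec$grid_width
  n <- h * w
  npos <- min(spec$n_bags - 1L, max(1L, round(spec$n_bags * spec$positive_fraction)))
  with_seed(spec$seed, {
    labels <- sample(c(rep(1L, npos), rep(0L, spec$n_bags - npos)))
    mu <- stats::rnorm(spec$d)
    mu <- mu / sqrt(sum(mu^2))
    # rank-3 stain basis: mu plus two orthonormal complements
    v1 <- stats::rnorm(spec$d); v1 <- v1 - sum(v1 * mu) * mu; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- stats::rnorm(spec$d); v2 <- v2 - sum(v2 * mu) * mu - sum(v2 * v1) * v1
    v2 <- v2 / sqrt(sum(v2^2))
    stain_basis <- cbind(mu, v1, v2)
    grid_rows <- rep(seq_len(h) - 1L, times = w)
    grid_cols <- rep(seq_len(w) - 1L, each = h)
    lapply(seq_len(spec$n_bags), function(b) {
      tl <- matrix(FALSE, h, w)
      if (labels[b] == 1L) {
        nt <- max(1L, round(spec$tumor_fraction * n))
        if (spec$cluster) {
          seed_rc <- cbind(sample.int(h, 1L), sample.int(w, 1L))
          tl <- grow_region(h, w, seed_rc, matrix(TRUE, h, w), nt)
        } else {
          tl[sample.int(n, nt)] <- TRUE
        }
      }
      shift <- as.vector(stain_basis %*% stats::rnorm(3L, 0, spec$stain_sd))
      H <- matrix(stats::rnorm(n * spec$d), n, spec$d)
      H <- sweep(H, 2L, shift, `+`)
      tumor_vec <- as.vector(tl) # column-major matches grid_rows/grid_cols
      if (any(tumor_vec)) {
        H[tumor_vec, ] <- sweep(H[tumor_vec, , drop = FALSE], 2L,
                                spec$class_separation * mu, `+`)
      }
      new_feature_bag(sprintf("bag_%03d", b), H, grid_rows, grid_cols,
                      labels[b], as.integer(tumor_vec))
    })
  })
}

#' Write / read a feature bag
#'
#' The on-disk contract shared between feature extraction and the MIL
#' stages: `<slide_id>.tsv` holds one row per tile with columns
#' `row`, `col`, `tile_label`, then the `d` feature values; a JSON sidecar
#' `<slide_id>.json` carries `slide_id`, `bag_label`, `d`, and `n`.
#'
#' @param bag a `feature_bag`.
#' @param dir directory to write into (created if needed).
#' @return `write_feature_bag`: the TSV path, invisibly.
#' @export
write_feature_bag <- function(bag, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, paste0(bag$slide_id, ".tsv"))
  js <- file.path(dir, paste0(bag$slide_id, ".json"))
  df <- data.frame(row = bag$rows, col = bag$cols,
                   tile_label = bag$tile_labels %||% rep(NA_integer_, nrow(bag$H)))
  df <- cbind(df, as.data.frame(bag$H))
  names(df)[-(1:3)] <- sprintf("f%04d", seq_len(ncol(bag$H)))
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(slide_id = bag$slide_id, bag_label = bag$label,
                            d = ncol(bag$H), n = nrow(bag$H)),
                       js, auto_unbox = TRUE)
  invisible(tsv)
}

#' @rdname write_feature_bag
#' @param path path to a bag `.tsv` (its `.json` sidecar must sit alongside).
#' @return `read_feature_bag`: the reconstructed `feature_bag`.
#' @export
read_feature_bag <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  H <- as.matrix(df[, grep("^f[0-9]+$", names(df)), drop = FALSE])
  dimnames(H) <- NULL
  tl <- if (all(is.na(df$tile_label))) NULL else as.integer(df$tile_label)
  new_feature_bag(meta$slide_id, H, df$row, df$col, meta$bag_label, tl)
}
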