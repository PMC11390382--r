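# Synthetic slide generator: seeded RGB rasters with a known tissue region,
# tumor blobs grown to an exact tile count, and a periodic luminance motif
# inside tumor tissue. Every downstream stage (segmentation, tiling,
# feature learning, MIL) can be exercised against this ground truth.

#' Specification of a synthetic slide
#'
#' @param grid_height,grid_width slide size in tiles (each >= 4).
#' @param tile_px pixels per tile side (>= 8).
#' @param tumor_fraction target fraction of tiles that are tumor, in
#'   \[0, 1\]. The generator paints blobs until exactly
#'   `max(1, floor(tumor_fraction * n_tiles))` tiles are tumor (0 tiles when
#'   the fraction is 0), so the realized fraction is controlled by
#'   construction.
#' @param blob_count number of tumor seed points; tumor tiles grow from
#'   these by random-walk region growing, giving connected irregular
#'   regions. Must be >= 1 whenever `tumor_fraction > 0`.
#' @param motif_period period, in tiles, of the sinusoidal luminance
#'   modulation applied to tumor tissue (default 8).
#' @param noise_sd per-pixel Gaussian intensity noise (image units, images
#'   live in \[0, 1\]).
#' @param tissue_fraction fraction of the grid covered by tissue (tumor +
#'   normal); tissue is one connected region grown from the grid center.
#' @param seed integer seed; all randomness derives from it.
#' @return a `synthetic_slide_spec`.
#' @export
slide_spec <- function(grid_height, grid_width, tile_px = 32,
                       tumor_fraction = 0.05, blob_count = 2,
                       motif_period = 8, noise_sd = 0.02,
                       tissue_fraction = 0.6, seed = 1L) {
  spec <- list(grid_height = as.integer(grid_height),
               grid_width = as.integer(grid_width),
               tile_px = as.integer(tile_px),
               tumor_fraction = tumor_fraction,
               blob_count = as.integer(blob_count),
               motif_period = motif_period,
               noise_sd = noise_sd,
               tissue_fraction = tissue_fraction,
               seed = as.integer(seed))
  class(spec) <- "synthetic_slide_spec"
  spec
}

# Random-walk region growing: grow `length(seeds)` blobs round-robin inside
# `allowed` until `target` cells are painted. Returns a logical matrix.
# Blobs stay 4-connected; a blob whose frontier is exhausted goes dormant.
grow_region <- function(h, w, seeds, allowed, target) {
  region <- matrix(FALSE, h, w)
  if (target <= 0) return(region)
  nb_of <- function(id) {
    r <- (id - 1L) %% h + 1L
    c <- (id - 1L) %/% h + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, id - 1L)
    if (r < h) out <- c(out, id + 1L)
    if (c > 1L) out <- c(out, id - h)
    if (c < w) out <- c(out, id + h)
    out
  }
  nblob <- nrow(seeds)
  frontier <- vector("list", nblob)
  count <- 0L
  for (b in seq_len(nblob)) {
    id <- (seeds[b, 2L] - 1L) * h + seeds[b, 1L]
    if (!allowed[id] || region[id]) { frontier[[b]] <- integer(0); next }
    region[id] <- TRUE
    count <- count + 1L
    frontier[[b]] <- nb_of(id)
    if (count >= target) return(region)
  }
  alive <- rep(TRUE, nblob)
  while (count < target && any(alive)) {
    for (b in which(alive)) {
      picked <- NA_integer_
      while (length(frontier[[b]])) {
        j <- if (length(frontier[[b]]) == 1L) 1L else sample.int(length(frontier[[b]]), 1L)
        cand <- frontier[[b]][j]
        frontier[[b]] <- frontier[[b]][-j]
        if (allowed[cand] && !region[cand]) { picked <- cand; break }
      }
      if (is.na(picked)) { alive[b] <- FALSE; next }
      region[picked] <- TRUE
      count <- count + 1L
      frontier[[b]] <- c(frontier[[b]], nb_of(picked))
      if (count >= target) break
    }
  }
  if (count < target) {
    # degenerate geometry (blobs boxed in): fill remaining allowed cells,
    # preferring cells adjacent to the painted region
    remaining <- which(allowed & !region)
    if (length(remaining)) {
      take <- remaining[seq_len(min(length(remaining), target - count))]
      region[take] <- TRUE
    }
  }
  region
}

# Sample blob seed tiles inside the tissue region, spread apart when possible.
sample_seeds <- function(tissue, blob_count) {
  ids <- which(tissue)
  h <- nrow(tissue)
  if (length(ids) == 0L) return(matrix(integer(0), 0, 2))
  picked <- integer(0)
  for (b in seq_len(blob_count)) {
    cand <- sample(ids, min(16L, length(ids)))
    if (length(picked) == 0L) {
      picked <- cand[1L]
    } else {
      pr <- (picked - 1L) %% h + 1L; pc <- (picked - 1L) %/% h + 1L
      dmin <- vapply(cand, function(id) {
        r <- (id - 1L) %% h + 1L; c <- (id - 1L) %/% h + 1L
        min(pmax(abs(r - pr), abs(c - pc)))
      }, numeric(1))
      picked <- c(picked, cand[which.max(dmin)])
    }
  }
  cbind((picked - 1L) %% h + 1L, (picked - 1L) %/% h + 1L)
}

#' Generate a synthetic slide
#'
#' Paints a connected tissue region on a near-white background, grows
#' `blob_count` tumor blobs inside it until exactly the target tile count is
#' reached, and renders tiles as flat colors (pink normal tissue, darker
#' purple tumor) with a sinusoidal luminance motif of period `motif_period`
#' tiles across tumor columns, plus Gaussian pixel noise. Deterministic for
#' a fixed spec.
#'
#' @param spec a [slide_spec()].
#' @return a `synthetic_slide`: list with `image` (array
#'   `grid_height*tile_px x grid_width*tile_px x 3`), `tile_labels`
#'   (0/1 matrix, 1 = tumor), `tissue_tiles` (logical matrix),
#'   `slide_label` (1 iff any tumor tile), and `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  h <- spec$grid_height; w <- spec$grid_width
  if (h < 4L || w < 4L) stop("grid dimensions must be >= 4 tiles")
  if (spec$tile_px < 8L) stop("tile_px must be >= 8")
  if (spec$tumor_fraction < 0 || spec$tumor_fraction > 1) stop("tumor_fraction must be in [0, 1]")
  if (spec$tumor_fraction > 0 && spec$blob_count < 1L) {
    stop("invalid spec: tumor_fraction > 0 requires blob_count >= 1")
  }
  n <- h * w
  tumor_target <- if (spec$tumor_fraction == 0) 0L else max(1L, floor(spec$tumor_fraction * n))
  tissue_target <- min(n, max(ceiling(spec$tissue_fraction * n), tumor_target))

  with_seed(spec$seed, {
    tissue <- grow_region(h, w, cbind((h + 1L) %/% 2L, (w + 1L) %/% 2L),
                          matrix(TRUE, h, w), tissue_target)
    tumor <- if (tumor_target > 0L) {
      grow_region(h, w, sample_seeds(tissue, spec$blob_count), tissue, tumor_target)
    } else {
      matrix(FALSE, h, w)
    }

    hp <- h * spec$tile_px; wp <- w * spec$tile_px
    image <- array(0.96, c(hp, wp, 3))
    normal_rgb <- c(0.85, 0.60, 0.72)
    tumor_rgb <- c(0.48, 0.32, 0.58)
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        if (!tissue[r, c]) next
        rows <- ((r - 1L) * spec$tile_px + 1L):(r * spec$tile_px)
        cols <- ((c - 1L) * spec$tile_px + 1L):(c * spec$tile_px)
        if (tumor[r, c]) {
          lum <- 1 + 0.15 * sin(2 * pi * (c - 1L) / spec$motif_period)
          col3 <- pmin(1, tumor_rgb * lum)
        } else {
          col3 <- normal_rgb
        }
        for (ch in 1:3) image[rows, cols, ch] <- col3[ch]
      }
    }
    if (spec$noise_sd > 0) {
      image <- image + array(stats::rnorm(length(image), 0, spec$noise_sd), dim(image))
      image <- pmax(pmin(image, 1), 0) # argument order keeps the dim attribute
    }
    structure(list(image = image,
                   tile_labels = tumor + 0L,
                   tissue_tiles = tissue,
                   slide_label = as.integer(any(tumor)),
                   spec = spec),
              class = "synthetic_slide")
  })
}

#' Write a synthetic slide to disk
#'
#' Writes `<slide_id>.ppm` (RGB raster) and `<slide_id>_labels.csv` with
#' columns `slide_id,row,col,label` (0-based grid coordinates).
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if needed).
#' @param slide_id identifier used in file names and the CSV.
#' @return named character vector of the two paths, invisibly.
#' @export
write_slide <- function(slide, dir, slide_id = "slide") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(slide_id, ".ppm"))
  lab_path <- file.path(dir, paste0(slide_id, "_labels.csv"))
  write_ppm(slide$image, img_path)
  tl <- slide$tile_labels
  df <- data.frame(slide_id = slide_id,
                   row = rep(seq_len(nrow(tl)) - 1L, times = ncol(tl)),
                   col = rep(seq_len(ncol(tl)) - 1L, each = nrow(tl)),
                   label = as.integer(tl))
  utils::write.csv(df, lab_path, row.names = FALSE, quote = FALSE)
  invisible(c(image = img_path, labels = lab_path))
}
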