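# Tissue segmentation and grid tiling. The recipe follows standard WSI
# practice: HSV saturation, Otsu threshold (with an absolute saturation
# floor so blank slides yield an empty mask), median filtering,
# morphological closing, and an area floor on connected components.

# Otsu threshold on values in [0, 1]; returns the class boundary.
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L || diff(range(v)) < 1e-8) return(Inf)
  br <- seq(0, 1, length.out = nbins + 1L)
  hcount <- tabulate(findInterval(pmin(pmax(v, 0), 1), br, all.inside = TRUE), nbins)
  p <- hcount / sum(hcount)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# 3x3 binary median filter (majority of the 9-neighborhood), zero-padded.
median_filter3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  acc <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    sh <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    sh[rs, cs] <- mask[rs - dr, cs - dc]
    acc <- acc + sh
  }
  acc >= 5L
}

# Binary dilation/erosion with a 3x3 structuring element.
dilate3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- out[rs, cs] | mask[rs - dr, cs - dc]
  }
  out
}

erode3 <- function(mask) !dilate3(!mask)

# Label 8-connected components; returns integer matrix (0 = background).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      id <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (id - 1L) %% h + 1L
      c <- (id - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > h || cc < 1L || cc > w) next
        nid <- (cc - 1L) * h + rr
        if (mask[nid] && lab[nid] == 0L) {
          lab[nid] <- cur
          stack <- c(stack, nid)
        }
      }
    }
  }
  lab
}

#' Segment tissue from background
#'
#' Downsamples the slide, converts to HSV, thresholds saturation at
#' `max(Otsu, sat_floor)`, median-filters, applies a morphological closing,
#' and drops connected components below `min_area` mask pixels. A
#' fully-background (e.g. uniform white) image yields an all-false mask.
#'
#' @param image RGB array `h x w x 3` in \[0, 1\].
#' @param downsample_factor integer block-mean downsample applied before
#'   segmentation (mask resolution = slide / factor).
#' @param sat_floor absolute minimum saturation for tissue (default 0.05);
#'   guards Otsu against blank slides.
#' @param min_area minimum component area in mask pixels; `NULL` (default)
#'   uses 4 tile areas assuming 256 px tiles at the mask scale, i.e.
#'   `4 * (256 / downsample_factor)^2`, capped at 1% of the mask.
#' @return a `tissue_mask`: list with `mask` (logical matrix) and
#'   `downsample_factor`.
#' @export
segment_tissue <- function(image, downsample_factor = 1L, sat_floor = 0.05,
                           min_area = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L, all(dim(image) > 0))
  small <- downsample_raster(image, as.integer(downsample_factor))
  rgb <- rbind(as.vector(small[, , 1]), as.vector(small[, , 2]), as.vector(small[, , 3]))
  sat <- grDevices::rgb2hsv(rgb, maxColorValue = 1)[2L, ]
  sat <- matrix(sat, nrow(small), ncol(small))
  thr <- max(otsu_threshold(as.vector(sat)), sat_floor)
  mask <- sat > thr
  if (any(mask)) {
    mask <- median_filter3(mask)
    mask <- erode3(dilate3(mask)) # closing
    if (is.null(min_area)) {
      min_area <- min(4 * (256 / downsample_factor)^2, ceiling(0.01 * length(mask)))
    }
    if (min_area > 1 && any(mask)) {
      lab <- label_components(mask)
      sizes <- tabulate(lab[lab > 0L])
      keep <- which(sizes >= min_area)
      mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    }
  }
  structure(list(mask = mask, downsample_factor = as.integer(downsample_factor)),
            class = "tissue_mask")
}

#' Tile a slide on a fixed grid
#'
#' Cuts the raster into non-overlapping `tile_px` x `tile_px` tiles
#' (trailing partial tiles dropped) and keeps tiles whose tissue fraction,
#' measured on the mask, is at least `min_tissue_fraction`.
#'
#' @param image RGB array (only its dimensions are used).
#' @param mask a [segment_tissue()] result, or `NULL` to treat everything
#'   as tissue.
#' @param tile_px tile side in pixels (default 256).
#' @param min_tissue_fraction minimum within-tile tissue fraction
#'   (default 0.5).
#' @param slide_id identifier recorded in the manifest.
#' @return a `tile_manifest`: data.frame with columns
#'   `slide_id, x, y, row, col, tissue_fraction` (0-based pixel origins and
#'   grid coordinates, sorted by `(row, col)`), with attribute `tile_px`.
#' @export
tile_slide <- function(image, mask = NULL, tile_px = 256L,
                       min_tissue_fraction = 0.5, slide_id = "slide") {
  tile_px <- as.integer(tile_px)
  if (tile_px <= 0L) stop("tile_px must be positive")
  h <- dim(image)[1]; w <- dim(image)[2]
  nr <- h %/% tile_px; nc <- w %/% tile_px
  rows <- integer(0); cols <- integer(0); tf <- numeric(0)
  mfrac <- function(r, c) {
    if (is.null(mask)) return(1)
    f <- mask$downsample_factor
    m <- mask$mask
    r0 <- floor((r - 1L) * tile_px / f) + 1L
    r1 <- min(nrow(m), ceiling(r * tile_px / f))
    c0 <- floor((c - 1L) * tile_px / f) + 1L
    c1 <- min(ncol(m), ceiling(c * tile_px / f))
    if (r0 > r1 || c0 > c1) return(0)
    mean(m[r0:r1, c0:c1])
  }
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      frac <- mfrac(r, c)
      if (frac >= min_tissue_fraction) {
        rows <- c(rows, r - 1L); cols <- c(cols, c - 1L); tf <- c(tf, frac)
      }
    }
  }
  man <- data.frame(slide_id = rep(slide_id, length(rows)),
                    x = cols * tile_px, y = rows * tile_px,
                    row = rows, col = cols,
                    tissue_fraction = tf)
  man <- man[order(man$row, man$col), , drop = FALSE]
  rownames(man) <- NULL
  attr(man, "tile_px") <- tile_px
  class(man) <- c("tile_manifest", "data.frame")
  man
}

#' Manifest CSV round-trip
#'
#' @param manifest a `tile_manifest`.
#' @param path CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   manifest (lossless round-trip).
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  df$tile_px <- attr(manifest, "tile_px")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tile_px <- df$tile_px[1] %||% 256L
  df$tile_px <- NULL
  attr(df, "tile_px") <- as.integer(tile_px)
  class(df) <- c("tile_manifest", "data.frame")
  df
}

# Extract one tile's pixels from the slide raster given a manifest record.
crop_tile <- function(image, x, y, tile_px) {
  image[(y + 1L):(y + tile_px), (x + 1L):(x + tile_px), , drop = FALSE]
}
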