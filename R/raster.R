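# Minimal raster I/O and image ops. Images are numeric arrays h x w x 3 in
# [0, 1]. Netpbm PPM is the on-disk interchange format: it is plain text
# (P3) or byte-exact binary (P6), readable/writable without any external
# imaging library.

#' Write an RGB raster as PPM
#'
#' @param image numeric array `h x w x 3` with values in \[0, 1\].
#' @param path output file path.
#' @param binary write binary P6 (default) or plain-text P3.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path, binary = TRUE) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- pmin(255L, pmax(0L, as.integer(round(image * 255))))
  # interleave RGB row-major: for each row, for each col, r g b
  arr <- aperm(array(px, dim(image)), c(3, 2, 1)) # c, w, h -> vector runs c fastest
  flat <- as.integer(arr)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P6", paste(w, h), "255"), con, sep = "\n")
    writeBin(as.raw(flat), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(flat[seq(1, length(flat), by = 3)],
                     flat[seq(2, length(flat), by = 3)],
                     flat[seq(3, length(flat), by = 3)]), con)
  }
  invisible(path)
}

#' Read a PPM raster
#'
#' @param path PPM file (P3 or P6).
#' @return numeric array `h x w x 3` in \[0, 1\].
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") { # comment to end of line
        repeat {
          ch2 <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch2) == 0L || ch2 == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P3", "P6")) stop("not a PPM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxv <- as.integer(read_token())
  n <- 3L * w * h
  flat <- if (magic == "P6") {
    as.integer(readBin(con, "raw", n))
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      tok <- read_token()
      if (!nzchar(tok)) break
      vals <- c(vals, as.integer(tok))
    }
    vals
  }
  if (length(flat) != n) stop("truncated PPM: ", path)
  arr <- array(flat / maxv, c(3, w, h))
  aperm(arr, c(3, 2, 1))
}

# Block-mean downsample by an integer factor (trailing partial blocks kept
# by truncation of the source).
downsample_raster <- function(image, factor) {
  stopifnot(factor >= 1)
  if (factor == 1) return(image)
  h <- dim(image)[1] %/% factor * factor
  w <- dim(image)[2] %/% factor * factor
  nh <- h %/% factor; nw <- w %/% factor
  out <- array(0, c(nh, nw, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) {
    m <- image[seq_len(h), seq_len(w), ch]
    # average factor x factor blocks
    m <- matrix(colMeans(matrix(m, factor)), nh, w, byrow = FALSE)
    m <- t(matrix(colMeans(matrix(t(m), factor)), nw, nh))
    out[, , ch] <- m
  }
  out
}

# Bilinear resize of an h x w x c array to nh x nw.
resize_bilinear <- function(image, nh, nw) {
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  if (h == nh && w == nw) return(image)
  ys <- (seq_len(nh) - 0.5) * h / nh + 0.5
  xs <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(nh, nw, nc))
  for (ch in seq_len(nc)) {
    m <- image[, , ch]
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
    d <- m[y1, x0, drop = FALSE]; e <- m[y1, x1, drop = FALSE]
    top <- a * outer(rep(1, nh), 1 - wx) + b * outer(rep(1, nh), wx)
    bot <- d * outer(rep(1, nh), 1 - wx) + e * outer(rep(1, nh), wx)
    out[, , ch] <- top * outer(1 - wy, rep(1, nw)) + bot * outer(wy, rep(1, nw))
  }
  out
}

# Separable Gaussian blur with reflecting borders; sigma = 0 is identity.
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect <- function(q, h) {
    q <- ifelse(q < 1, 2 - q, q)
    q <- ifelse(q > h, 2 * h - q, q)
    pmin(pmax(q, 1), h)
  }
  blur1 <- function(m) { # along rows (dim 1)
    h <- nrow(m)
    out <- matrix(0, h, ncol(m))
    for (j in seq_along(k)) {
      idx <- reflect(seq_len(h) + (j - r - 1L), h)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    m <- image[, , ch]
    out[, , ch] <- t(blur1(t(blur1(m))))
  }
  out
}
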