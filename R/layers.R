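# Differentiable building blocks. Each layer exposes a *_forward returning
# (out, cache) and a *_backward returning gradients; models compose these
# by hand (no autodiff exists in this stack).

linear_forward <- function(X, W, b = NULL) {
  out <- X %*% W
  if (!is.null(b)) out <- sweep(out, 2L, b, `+`)
  list(out = out, cache = list(X = X, W = W, has_b = !is.null(b)))
}

linear_backward <- function(dout, cache) {
  list(dX = dout %*% t(cache$W),
       dW = t(cache$X) %*% dout,
       db = if (cache$has_b) colSums(dout) else NULL)
}

# tanh-approximation GELU (the common fast form); backward matches the
# approximation exactly.
gelu <- function(x) {
  u <- 0.7978845608028654 * (x + 0.044715 * x^3)
  0.5 * x * (1 + tanh(u))
}

gelu_backward <- function(dout, x) {
  u <- 0.7978845608028654 * (x + 0.044715 * x^3)
  t <- tanh(u)
  dout * (0.5 * (1 + t) +
            0.5 * x * (1 - t^2) * 0.7978845608028654 * (1 + 3 * 0.044715 * x^2))
}

layernorm_forward <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_backward <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, cache$g, `*`)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dout * xhat), db = colSums(dout))
}

mlp_init <- function(d, hidden, sd = 0.02) {
  list(W1 = init_mat(d, hidden, sd), b1 = numeric(hidden),
       W2 = init_mat(hidden, d, sd), b2 = numeric(d))
}

mlp_forward <- function(X, p) {
  pre <- sweep(X %*% p$W1, 2L, p$b1, `+`)
  hid <- gelu(pre)
  out <- sweep(hid %*% p$W2, 2L, p$b2, `+`)
  list(out = out, cache = list(X = X, pre = pre, hid = hid, p = p))
}

mlp_backward <- function(dout, cache) {
  p <- cache$p
  dhid <- dout %*% t(p$W2)
  dpre <- gelu_backward(dhid, cache$pre)
  list(dX = dpre %*% t(p$W1),
       grads = list(W1 = t(cache$X) %*% dpre, b1 = colSums(dpre),
                    W2 = t(cache$hid) %*% dout, b2 = colSums(dout)))
}

# Softmax cross-entropy on a single logit vector; label is 0-based.
softmax_ce <- function(logits, label) {
  p <- softmax_vec(logits)
  dy <- p
  dy[label + 1L] <- dy[label + 1L] - 1
  list(loss = -log(max(p[label + 1L], 1e-12)), probs = p, dlogits = dy)
}

# ---- 2-D convolution via im2col ---------------------------------------
# x: h x w x cin array. W: (kh*kw*cin) x cout. Column ordering of a patch:
# (dr, dc, cin) with dr fastest, matching the unrolling below.

im2col <- function(x, kh, kw, stride, pad) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  oh <- (h + 2 * pad - kh) %/% stride + 1L
  ow <- (w + 2 * pad - kw) %/% stride + 1L
  xp <- array(0, c(h + 2 * pad, w + 2 * pad, cin))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  cols <- matrix(0, oh * ow, kh * kw * cin)
  j <- 0L
  for (ci in seq_len(cin)) {
    for (dc in seq_len(kw)) {
      for (dr in seq_len(kh)) {
        j <- j + 1L
        sub <- xp[seq(dr, by = stride, length.out = oh),
                  seq(dc, by = stride, length.out = ow), ci]
        cols[, j] <- as.vector(sub) # column-major: rows fastest
      }
    }
  }
  list(cols = cols, oh = oh, ow = ow, h = h, w = w, cin = cin,
       kh = kh, kw = kw, stride = stride, pad = pad)
}

col2im <- function(dcols, meta) {
  xp <- array(0, c(meta$h + 2 * meta$pad, meta$w + 2 * meta$pad, meta$cin))
  j <- 0L
  for (ci in seq_len(meta$cin)) {
    for (dc in seq_len(meta$kw)) {
      for (dr in seq_len(meta$kh)) {
        j <- j + 1L
        rs <- seq(dr, by = meta$stride, length.out = meta$oh)
        cs <- seq(dc, by = meta$stride, length.out = meta$ow)
        xp[rs, cs, ci] <- xp[rs, cs, ci] + matrix(dcols[, j], meta$oh, meta$ow)
      }
    }
  }
  xp[meta$pad + seq_len(meta$h), meta$pad + seq_len(meta$w), , drop = FALSE]
}

conv2d_init <- function(cin, cout, k = 3L, sd = NULL) {
  # He init by default: the 0.02 transformer convention starves conv stacks
  kern <- if (is.null(sd)) init_he(k * k * cin, cout) else init_mat(k * k * cin, cout, sd)
  p <- list(kernel = kern, b = numeric(cout))
  attr(p, "ksize") <- as.integer(k)
  p
}

conv2d_forward <- function(x, p, stride = 1L, pad = 1L) {
  k <- attr(p, "ksize") %||% 3L
  ic <- im2col(x, k, k, stride, pad)
  out2 <- sweep(ic$cols %*% p$kernel, 2L, p$b, `+`)
  out <- array(out2, c(ic$oh, ic$ow, ncol(p$kernel)))
  list(out = out, cache = list(ic = ic, p = p))
}

conv2d_backward <- function(dout, cache) {
  ic <- cache$ic
  cout <- dim(dout)[3]
  dout2 <- matrix(dout, ic$oh * ic$ow, cout)
  dcols <- dout2 %*% t(cache$p$kernel)
  list(dx = col2im(dcols, ic),
       grads = list(kernel = t(ic$cols) %*% dout2, b = colSums(dout2)))
}

# ---- depthwise 3x3 convolution on a grid map ---------------------------
# Used as the "Convolution" mixer in the attention-type ablation. x is an
# h x w x c array; kernel is 9 x c (offsets raster order dr=-1..1 within
# dc=-1..1), zero padding.

dwconv_init <- function(c, sd = 0.02) {
  list(kernel = matrix(trunc_normal(9L * c, sd), 9L, c), b = numeric(c))
}

dwconv_forward <- function(x, p) {
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  out <- array(0, dim(x))
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    for (ch in seq_len(nc)) {
      out[rs, cs, ch] <- out[rs, cs, ch] + p$kernel[j, ch] * x[rs - dr, cs - dc, ch]
    }
  }
  out <- sweep(out, 3L, p$b, `+`)
  list(out = out, cache = list(x = x, p = p))
}

dwconv_backward <- function(dout, cache) {
  x <- cache$x; p <- cache$p
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  dx <- array(0, dim(x))
  dk <- matrix(0, 9L, nc)
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    for (ch in seq_len(nc)) {
      dx[rs - dr, cs - dc, ch] <- dx[rs - dr, cs - dc, ch] +
        p$kernel[j, ch] * dout[rs, cs, ch]
      dk[j, ch] <- dk[j, ch] + sum(dout[rs, cs, ch] * x[rs - dr, cs - dc, ch])
    }
  }
  db <- apply(dout, 3L, sum)
  list(dx = dx, grads = list(kernel = dk, b = db))
}
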