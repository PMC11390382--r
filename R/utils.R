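# Low-level numeric and RNG plumbing shared by every module.

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so no exported operation touches global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit seed from a base seed and a salt.
derive_seed <- function(seed, salt) {
  x <- ((as.numeric(seed) %% 2147483647) * 48271 + 104729 * as.numeric(salt)) %% 2147483629
  as.integer(x)
}

# Row-wise softmax with max subtraction; -Inf entries map to exact zeros.
softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0 # all -Inf row guard
  e <- exp(m - mx)
  e[!is.finite(m)] <- 0
  s <- rowSums(e)
  s[s == 0] <- 1
  e / s
}

softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Truncated-normal initializer (|x| <= 2 sd), the transformer convention.
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

init_mat <- function(nin, nout, sd = 0.02) {
  matrix(trunc_normal(nin * nout, sd), nin, nout)
}

# He initialization for convolutional / ReLU-family layers.
init_he <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# ---- parameter trees ---------------------------------------------------
# Model parameters live in nested named lists whose leaves are numeric
# arrays; these walkers implement map/zip over such trees.

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree) {
  if (is_leaf(tree)) return(f(tree))
  lapply(tree, function(x) tree_map(f, x))
}

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
  out
}

# In-place style accumulation grads <- grads + delta
tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

#' Count parameters of a model tree
#'
#' @param tree nested list of numeric arrays (model parameters).
#' @return total number of scalar parameters.
#' @export
count_params <- function(tree) {
  if (is_leaf(tree)) return(length(tree))
  sum(vapply(tree, count_params, numeric(1)))
}

tree_max_abs_diff <- function(a, b) {
  if (is_leaf(a)) return(max(abs(a - b)))
  max(vapply(seq_along(a), function(i) tree_max_abs_diff(a[[i]], b[[i]]), numeric(1)))
}

# ---- AdamW -------------------------------------------------------------
# Decoupled weight decay applied only to weight matrices (leaf names listed
# below), never to biases, gains, LayerScale or positional-bias tables.

.decay_names <- c("Wq", "Wk", "Wv", "Wo", "W1", "W2", "We", "U", "V", "Wc", "kernel")

adamw_init <- function(params) {
  list(t = 0L, m = tree_zeros(params), v = tree_zeros(params))
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, weight_decay = 0.05) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v, name) {
    if (is_leaf(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      wd <- if (name %in% .decay_names) weight_decay else 0
      p <- p - lr * (mh / (sqrt(vh) + eps) + wd * p)
      return(list(p = p, m = m, v = v))
    }
    for (i in seq_along(p)) {
      r <- walk(p[[i]], g[[i]], m[[i]], v[[i]], names(p)[i] %||% "")
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v, "")
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cosine learning-rate schedule with linear warmup (fractions of total steps).
lr_schedule <- function(step, total_steps, base_lr, warmup_frac = 0.1) {
  warm <- max(1, floor(total_steps * warmup_frac))
  if (step <= warm) return(base_lr * step / warm)
  prog <- (step - warm) / max(1, total_steps - warm)
  base_lr * 0.5 * (1 + cos(pi * min(1, prog)))
}

# Stable hash of an R object (via its canonical JSON) for config fingerprints.
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
}
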