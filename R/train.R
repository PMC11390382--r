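# Training/evaluation loops: stratified splits, AdamW with cosine
# schedule and warmup, early stopping on validation AUC, and the k-sweep
# and attention-type ablation harnesses.

#' Stratified train/validation/test split
#'
#' @param labels 0/1 labels.
#' @param fractions length-3 fractions summing to 1 (default 0.70/0.15/0.15).
#' @param seed integer seed.
#' @return list with integer index vectors `train`, `val`, `test`; every
#'   non-empty part of a class is allocated train-first.
#' @export
stratified_split <- function(labels, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  with_seed(seed, {
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_tr <- max(1L, round(fractions[1] * n))
      n_va <- max(1L, round(fractions[2] * n))
      n_tr <- min(n_tr, n - 2L)
      n_va <- min(n_va, n - n_tr - 1L)
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$val <- c(parts$val, idx[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, idx[(n_tr + n_va + 1L):n])
    }
    lapply(parts, sort)
  })
}

#' Training hyperparameters
#'
#' @param epochs maximum epochs.
#' @param lr base AdamW learning rate (cosine schedule, 10% linear warmup).
#' @param batch_size bags per optimizer step.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param patience early-stopping patience on validation AUC (epochs).
#' @param min_epochs epochs to run before early stopping may fire
#'   (attention-MIL training has a long flat phase before the gate
#'   sharpens; stopping inside it truncates learning).
#' @param split_frac train/val/test fractions.
#' @return list of settings.
#' @export
train_settings <- function(epochs = 30L, lr = 1e-3, batch_size = 8L,
                           weight_decay = 0.05, patience = 5L,
                           min_epochs = 15L, split_frac = c(0.7, 0.15, 0.15)) {
  list(epochs = as.integer(epochs), lr = lr, batch_size = as.integer(batch_size),
       weight_decay = weight_decay, patience = as.integer(patience),
       min_epochs = as.integer(min_epochs), split_frac = split_frac)
}

# Internal: one engine for NATMIL and the pooling baselines. `kind` is
# "natmil", "mean", "max" or "abmil_gated".
fit_mil <- function(bags, kind, config = natmil_config(), seed = 1L,
                    settings = train_settings(), split = NULL,
                    verbose = FALSE) {
  labels <- vapply(bags, `[[`, integer(1), "label")
  if (length(bags) < 4L) stop("need at least 4 bags")
  split <- split %||% stratified_split(labels, settings$split_frac,
                                       derive_seed(seed, 5L))
  if (length(unique(labels[split$train])) < 2L) {
    stop("a class is missing from the training split")
  }
  d <- ncol(bags[[1]]$H)
  cache_env <- new.env(parent = emptyenv())

  if (kind == "natmil") {
    model <- init_natmil(config, derive_seed(seed, 1L))
    params <- model$params
    grad_fn <- function(params, bag) {
      model$params <- params
      bc <- bag_ctx(model, bag, cache_env)
      natmil_bag_grad(model, bag, bc)
    }
    score_fn <- function(params, bag) {
      model$params <- params
      bc <- bag_ctx(model, bag, cache_env)
      natmil_forward(model, bag, bc)$probs[2L]
    }
  } else if (kind %in% c("mean", "max")) {
    params <- with_seed(derive_seed(seed, 1L), list(Wc = t(init_mat(d, 2L))))
    pool_fn <- if (kind == "mean") function(H) colMeans(H) else function(H) apply(H, 2L, max)
    grad_fn <- function(params, bag) {
      g <- pool_fn(bag$H)
      ce <- softmax_ce(as.vector(params$Wc %*% g), bag$label)
      list(loss = ce$loss, grads = list(Wc = outer(ce$dlogits, g)))
    }
    score_fn <- function(params, bag) {
      softmax_vec(as.vector(params$Wc %*% pool_fn(bag$H)))[2L]
    }
  } else if (kind == "abmil_gated") {
    params <- with_seed(derive_seed(seed, 1L),
                        list(gate = gated_params_init(d, config$gate_hidden,
                                                      derive_seed(seed, 77L)),
                             Wc = t(init_mat(d, 2L))))
    grad_fn <- function(params, bag) {
      gt <- gated_forward(bag$H, params$gate)
      g <- as.vector(gt$a %*% bag$H)
      ce <- softmax_ce(as.vector(params$Wc %*% g), bag$label)
      dg <- as.vector(t(params$Wc) %*% ce$dlogits)
      da <- as.vector(bag$H %*% dg)
      gb <- gated_backward(da, gt$cache)
      list(loss = ce$loss,
           grads = list(gate = gb$grads, Wc = outer(ce$dlogits, g)))
    }
    score_fn <- function(params, bag) {
      a <- gated_attention(bag$H, params$gate)
      softmax_vec(as.vector(params$Wc %*% as.vector(a %*% bag$H)))[2L]
    }
  } else {
    stop("unknown model kind '", kind, "'")
  }

  opt <- adamw_init(params)
  n_tr <- length(split$train)
  steps_per_epoch <- max(1L, ceiling(n_tr / settings$batch_size))
  total_steps <- settings$epochs * steps_per_epoch
  step <- 0L
  best <- list(auc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- data.frame()

  eval_split <- function(params, idx) {
    if (!length(idx)) return(NULL)
    scores <- vapply(bags[idx], function(b) score_fn(params, b), numeric(1))
    compute_metrics(labels[idx], scores)
  }

  for (ep in seq_len(settings$epochs)) {
    ord <- with_seed(derive_seed(seed, 1000L + ep), sample(split$train))
    losses <- numeric(0)
    for (bt in seq_len(steps_per_epoch)) {
      idx <- ord[((bt - 1L) * settings$batch_size + 1L):min(n_tr, bt * settings$batch_size)]
      grads <- NULL
      for (bi in idx) {
        r <- grad_fn(params, bags[[bi]])
        losses <- c(losses, r$loss)
        grads <- if (is.null(grads)) r$grads else tree_add(grads, r$grads)
      }
      grads <- tree_map(function(x) x / length(idx), grads)
      step <- step + 1L
      up <- adamw_step(params, grads, opt,
                       lr_schedule(step, total_steps, settings$lr),
                       weight_decay = settings$weight_decay)
      params <- up$params
      opt <- up$state
    }
    vm <- eval_split(params, split$val)
    val_auc <- if (is.null(vm) || is.na(vm$auc)) 0.5 else vm$auc
    history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                         val_auc = val_auc))
    if (verbose) message(sprintf("[%s] epoch %d loss %.4f val AUC %.4f",
                                 kind, ep, mean(losses), val_auc))
    if (val_auc > best$auc + 1e-4) {
      best <- list(auc = val_auc, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= settings$patience && ep >= (settings$min_epochs %||% 0L)) break
    }
  }
  params <- best$params
  test_metrics <- eval_split(params, split$test)
  res <- list(kind = kind, params = params, config = config,
              metrics = test_metrics, val_auc = best$auc,
              history = history, split = split, seed = seed)
  if (kind == "natmil") {
    model$params <- params
    res$model <- model
  }
  res
}

#' Train the NATMIL model end-to-end
#'
#' Trains embedding, NAT contextualizer blocks, gated pooling and the
#' class head jointly with cross-entropy, early-stopping on validation
#' AUC; deterministic per seed.
#'
#' @param bags list of `feature_bag`s (>= 4, both classes present).
#' @param config a [natmil_config()] matching the bag feature width.
#' @param seed integer seed.
#' @param settings from [train_settings()].
#' @param split optional precomputed [stratified_split()] result.
#' @param verbose print per-epoch progress.
#' @return list with the trained `model`, test-set `metrics`
#'   (a `metric_report`), per-epoch `history`, `split` and `val_auc`.
#' @export
train_natmil <- function(bags, config = natmil_config(), seed = 1L,
                         settings = train_settings(), split = NULL,
                         verbose = FALSE) {
  fit_mil(bags, "natmil", config, seed, settings, split, verbose)
}

#' Train a pooling baseline
#'
#' @inheritParams train_natmil
#' @param mode `"mean"`, `"max"`, or `"abmil_gated"`.
#' @return as [train_natmil()] (no `model` element).
#' @export
train_mil_baseline <- function(bags, mode = c("mean", "max", "abmil_gated"),
                               config = natmil_config(), seed = 1L,
                               settings = train_settings(), split = NULL,
                               verbose = FALSE) {
  mode <- match.arg(mode)
  fit_mil(bags, mode, config, seed, settings, split, verbose)
}

#' Neighborhood-size sweep
#'
#' One seeded training run per `k` on shared splits.
#'
#' @inheritParams train_natmil
#' @param k_values integer vector of neighborhood sizes (non-empty).
#' @return data.frame with columns `k`, `auc`, `acc`, `macro_f1`,
#'   `n_slides`.
#' @export
k_sweep <- function(bags, config = natmil_config(), k_values = c(1L, 2L, 3L, 4L, 8L),
                    seed = 1L, settings = train_settings(), verbose = FALSE) {
  if (!length(k_values)) stop("k_values must be non-empty")
  labels <- vapply(bags, `[[`, integer(1), "label")
  split <- stratified_split(labels, settings$split_frac, derive_seed(seed, 5L))
  rows <- lapply(k_values, function(k) {
    cfg <- config
    cfg$k <- as.integer(k)
    fit <- train_natmil(bags, cfg, seed, settings, split, verbose)
    m <- fit$metrics
    data.frame(k = k, auc = m$auc, acc = m$acc, macro_f1 = m$macro_f1,
               n_slides = m$n_slides)
  })
  do.call(rbind, rows)
}

#' Attention-type ablation
#'
#' Swaps the stage mixer (neighborhood / blocked-window / global attention
#' or 3x3 depthwise convolution) under one configuration and reports
#' slide-level metrics and attention parameter counts per variant.
#'
#' @inheritParams train_natmil
#' @param variants subset of `c("neighborhood", "window", "global", "conv")`.
#' @return data.frame with `variant`, `auc`, `acc`, `macro_f1`,
#'   `attn_params` (parameters in the mixers).
#' @export
ablation_attention_type <- function(bags, config = natmil_config(),
                                    variants = c("neighborhood", "window",
                                                 "global", "conv"),
                                    seed = 1L, settings = train_settings(),
                                    verbose = FALSE) {
  valid <- c("neighborhood", "window", "global", "conv")
  bad <- setdiff(variants, valid)
  if (length(bad)) {
    stop("unknown variant(s) ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "))
  }
  labels <- vapply(bags, `[[`, integer(1), "label")
  split <- stratified_split(labels, settings$split_frac, derive_seed(seed, 5L))
  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    fit <- train_natmil(bags, cfg, seed, settings, split, verbose)
    m <- fit$metrics
    # conv mixers hold convolution weights, not attention parameters
    ap <- if (v == "conv") 0 else sum(vapply(fit$params$blocks,
                                             function(bp) count_params(bp$mixer),
                                             numeric(1)))
    data.frame(variant = v, auc = m$auc, acc = m$acc, macro_f1 = m$macro_f1,
               attn_params = ap)
  })
  do.call(rbind, rows)
}
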