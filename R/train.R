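# AdamW training loop with deep supervision, checkpointing, and prediction
# helpers.

train_dc <- function(model, cases) {
  dcs <- vapply(cases, function(cs) {
    m <- predict(model, cs$x)
    overlap_metrics(cs$y, m)$DC
  }, numeric(1))
  mean(dcs)
}

#' Train a segmentation model with AdamW
#'
#' Optimizes the deep-supervision Dice + cross-entropy loss. Batches are drawn
#' in a seeded shuffled order that cycles over the training cases; gradients
#' are averaged over the batch. Everything (ordering, updates) is determined
#' by `seed` given the model's initial weights.
#'
#' @param model a model from [lemunet()] or [mednext_backbone()].
#' @param cases list of training cases, each a list with `x` (input tensor,
#'   in_channels x grid) and `y` (binary label array at full resolution).
#' @param steps number of optimizer steps.
#' @param batch_size cases per step (default 2).
#' @param lr initial (constant) learning rate, default 1e-3.
#' @param weight_decay AdamW decoupled weight decay.
#' @param weights a [loss_weights()]; defaults to the halving scheme.
#' @param seed RNG seed for data ordering.
#' @param log_every record loss/train-DC every this many steps (0 = never).
#' @param stop_at_dc optional early-stopping threshold: training ends at the
#'   first logging point whose mean training DC exceeds this value.
#' @param opt_state optional AdamW state (from a previous `train_model` call's
#'   `model$opt_state`) to resume optimization bit-identically.
#' @param verbose print progress lines.
#' @return the trained model; the training history (`step`, `loss`,
#'   `train_dc`) is attached as `model$history`.
#' @export
train_model <- function(model, cases, steps = 100L, batch_size = 2L,
                        lr = 1e-3, weight_decay = 1e-5,
                        weights = NULL, seed = 1L, log_every = 25L,
                        stop_at_dc = NULL, verbose = FALSE, opt_state = NULL) {
  if (length(cases) == 0L) stop("no training cases")
  for (cs in cases)
    if (dim(cs$x)[1] != model$cfg$in_channels)
      stop("case channel count does not match model config")
  if (is.null(weights)) weights <- loss_weights(model$cfg$ds_levels)
  fl <- flatten_params(model$params)
  theta <- fl$vec
  opt <- if (is.null(opt_state)) adamw_init(length(theta)) else opt_state
  set.seed(seed)
  ord <- sample(length(cases))
  ptr <- 0L
  hist <- list()
  for (step in seq_len(steps)) {
    idx <- integer(batch_size)
    for (b in seq_len(batch_size)) {
      ptr <- ptr + 1L
      if (ptr > length(ord)) { ord <- sample(length(cases)); ptr <- 1L }
      idx[b] <- ord[ptr]
    }
    gsum <- NULL
    lsum <- 0
    for (i in idx) {
      r <- net_fwd(model, cases[[i]]$x, keep_cache = TRUE)
      lg <- seg_loss_grad(r$logits, cases[[i]]$y, weights)
      g <- net_bwd(model, r$cache, lg$dz)
      gv <- flatten_params(g)$vec
      gsum <- if (is.null(gsum)) gv else gsum + gv
      lsum <- lsum + lg$loss
    }
    upd <- adamw_step(theta, gsum / length(idx), opt, lr = lr,
                      weight_decay = weight_decay)
    theta <- upd$theta
    opt <- upd$state
    model$params <- unflatten_params(theta, model$params)
    if (log_every > 0L && (step %% log_every == 0L || step == steps)) {
      dc <- train_dc(model, cases)
      hist[[length(hist) + 1L]] <- data.frame(step = step,
                                              loss = lsum / length(idx),
                                              train_dc = dc)
      if (verbose)
        message(sprintf("step %4d  loss %.4f  train DC %.4f",
                        step, lsum / length(idx), dc))
      if (!is.null(stop_at_dc) && dc > stop_at_dc) break
    }
  }
  model$history <- if (length(hist)) do.call(rbind, hist) else NULL
  model$opt_state <- opt
  model
}

#' Save / load a model checkpoint
#'
#' Single-file versioned checkpoint containing the config and all named
#' parameter arrays (plus optimizer state if present).
#'
#' @param model a `lemunet_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "lemunet_checkpoint", version = 1L, type = model$type,
               cfg = unclass(model$cfg), params = model$params,
               opt_state = model$opt_state, history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "lemunet_checkpoint"))
    stop("not a model checkpoint: ", path)
  structure(list(params = ck$params,
                 cfg = structure(ck$cfg, class = "backbone_config"),
                 type = ck$type, opt_state = ck$opt_state,
                 history = ck$history),
            class = "lemunet_model")
}
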