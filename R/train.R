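## Training: Adam optimisation of the BCE+Dice loss with on-the-fly
## augmentation, early stopping on the validation loss, and transfer learning
## by fine-tuning all layers from pre-trained weights.

adam_init <- function(P) {
  list(m = lapply(P, function(p) p * 0), v = lapply(P, function(p) p * 0),
       t = 0L)
}

adam_step <- function(P, G, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (nm in names(G)) {
    g <- G[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(P = P, opt = opt)
}

pairs_to_arrays <- function(pairs, px) {
  n <- length(pairs)
  X <- array(0, c(px, px, n, 1L))
  Tg <- array(0, c(px, px, n, 1L))
  for (i in seq_len(n)) {
    if (!all(dim(pairs[[i]]$image) == c(px, px)))
      stop("training pair size does not match the model input size")
    X[, , i, 1] <- pairs[[i]]$image
    Tg[, , i, 1] <- pairs[[i]]$target
  }
  list(X = X, T = Tg)
}

eval_loss <- function(net, X, Tg, batch, max_steps = NULL) {
  n <- dim(X)[3]
  starts <- seq(1L, n, by = batch)
  if (!is.null(max_steps)) starts <- head(starts, max_steps)
  tot <- 0; cnt <- 0
  for (s in starts) {
    e <- min(s + batch - 1L, n)
    fw <- unet_forward(net, X[, , s:e, , drop = FALSE], training = FALSE)
    tot <- tot + bce_dice_loss(fw$p, Tg[, , s:e, , drop = FALSE],
                               net$config$bce_weight, net$config$dice_weight) *
      (e - s + 1L)
    cnt <- cnt + (e - s + 1L)
  }
  tot / cnt
}

#' Train a U-Net
#'
#' Minimises the combined BCE+Dice loss with Adam. Augmentation (if given) is
#' applied on the fly to each training sample. Training stops early when the
#' validation loss has not improved for `config$patience` epochs; the weights
#' from the best validation epoch are returned. Deterministic given `seed`.
#'
#' @param net a `unet` from [build_unet()] (or a previously trained one).
#' @param train_pairs,val_pairs lists of `training_pair`s (image + binary
#'   target at the model input size). `val_pairs = NULL` monitors the training
#'   loss instead.
#' @param epochs override of `config$epochs`.
#' @param seed RNG seed for shuffling, augmentation and dropout.
#' @param augment_params augmentation ranges as in [augment_pair()], applied
#'   on the fly; `NULL` disables augmentation.
#' @param verbose print per-epoch losses.
#' @return the trained `unet`, with `$history` a data.frame of per-epoch
#'   `train_loss` and `val_loss`.
#' @export
train_unet <- function(net, train_pairs, val_pairs = NULL, epochs = NULL,
                       seed = 1L, augment_params = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "unet"))
  if (length(train_pairs) == 0) stop("empty training set")
  cfg <- net$config
  if (is.null(epochs)) epochs <- cfg$epochs
  px <- cfg$input_px
  tr <- pairs_to_arrays(train_pairs, px)
  va <- if (!is.null(val_pairs) && length(val_pairs) > 0)
    pairs_to_arrays(val_pairs, px)
  opt <- adam_init(net$params)
  batch <- min(cfg$batch_size, length(train_pairs))
  steps <- if (is.null(cfg$steps_per_epoch))
    ceiling(length(train_pairs) / batch) else cfg$steps_per_epoch

  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_loss <- Inf; best_P <- net$params; best_S <- net$state; wait <- 0L

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps)) {
        idx <- sample.int(dim(tr$X)[3], batch, replace = batch > dim(tr$X)[3])
        Xb <- tr$X[, , idx, , drop = FALSE]
        Tb <- tr$T[, , idx, , drop = FALSE]
        if (!is.null(augment_params)) {
          for (k in seq_len(batch)) {
            ap <- augment_pair(
              structure(list(image = Xb[, , k, 1], target = Tb[, , k, 1]),
                        class = "training_pair"),
              augment_params)
            Xb[, , k, 1] <- ap$image
            Tb[, , k, 1] <- ap$target
          }
        }
        fw <- unet_forward(net, Xb, training = TRUE, cache = TRUE)
        net$state <- fw$state
        lg <- bce_dice_grad(fw$logits, Tb, cfg$bce_weight, cfg$dice_weight)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged: non-finite loss at epoch %d step %d",
                       ep, st))
        G <- unet_backward(net, fw$tape, lg$dlogits)
        up <- adam_step(net$params, G, opt, cfg$learning_rate)
        net$params <- up$P; opt <- up$opt
        ep_loss <- ep_loss + lg$loss
      }
      ep_loss <- ep_loss / steps
      vl <- if (!is.null(va))
        eval_loss(net, va$X, va$T, batch, cfg$validation_steps) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_loss,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
      monitor <- if (is.na(vl)) ep_loss else vl
      if (monitor < best_loss - 1e-6) {
        best_loss <- monitor; best_P <- net$params; best_S <- net$state
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  net$params <- best_P
  net$state <- best_S
  net$history <- hist
  net
}

#' Fine-tune a pre-trained U-Net on a new dataset
#'
#' Transfer learning: training restarts from the pre-trained weights and
#' fine-tunes all layers on the new data (default 12 epochs).
#'
#' @param pretrained a trained `unet`.
#' @param new_pairs list of training pairs for the new label/dataset.
#' @param val_pairs optional validation pairs.
#' @param epochs fine-tuning epochs (default 12).
#' @param ... passed to [train_unet()] (e.g. `seed`, `augment_params`).
#' @return the fine-tuned `unet`.
#' @export
transfer_learn <- function(pretrained, new_pairs, val_pairs = NULL,
                           epochs = 12, ...) {
  stopifnot(inherits(pretrained, "unet"))
  if (is.null(pretrained$history))
    warning("fine-tuning a model that has no training history")
  train_unet(pretrained, new_pairs, val_pairs, epochs = epochs, ...)
}

#' Save / load U-Net weights
#'
#' Weights, batch-norm state, configuration and training history are written
#' as an RDS checkpoint with a YAML sidecar describing the architecture; a
#' checkpoint only loads into a matching architecture.
#'
#' @param net a `unet`.
#' @param path checkpoint path (`.rds`); the sidecar gets the extension
#'   `.yml`.
#' @return `save_weights` the path invisibly; `load_weights` the `unet`.
#' @export
save_weights <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  saveRDS(list(params = net$params, state = net$state,
               config = unclass(net$config), history = net$history), path)
  side <- paste0(tools::file_path_sans_ext(path), ".yml")
  cfg <- unclass(net$config)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], side)
  invisible(path)
}

#' @rdname save_weights
#' @param config optional `unet_config` the checkpoint must match.
#' @export
load_weights <- function(path, config = NULL) {
  obj <- readRDS(path)
  cfg <- do.call(unet_config, obj$config[!vapply(obj$config, is.null, logical(1))])
  if (!is.null(config)) {
    for (f in c("input_px", "levels", "base_filters"))
      if (!identical(cfg[[f]], config[[f]]))
        stop("checkpoint architecture does not match the requested config (", f, ")")
  }
  structure(list(config = cfg, params = obj$params, state = obj$state,
                 history = obj$history), class = "unet")
}
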