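## U-Net architecture: encoder-decoder with skip concatenations.
##
## Each contraction block is two convolutional sub-blocks (3x3 convolution,
## batch normalisation, ReLU) followed by 2x2 max-pooling and dropout; the
## filter count starts at `base_filters` and doubles per level. Expansion
## blocks are a stride-2 3x3 transposed convolution, concatenation with the
## matching encoder activation, dropout, and two convolutional sub-blocks.
## The head is a 1x1 convolution with sigmoid activation, so the output is a
## per-pixel probability map of the input's spatial size.

#' U-Net configuration
#'
#' @param input_px input tile side in pixels; must be divisible by
#'   `2^(levels - 1)`.
#' @param levels number of resolution levels (contraction blocks including the
#'   bottleneck); the published models use 5.
#' @param base_filters filters at the first level, doubled per level
#'   (published: 32).
#' @param dropout_rate dropout rate after pooling and after concatenation.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param steps_per_epoch minibatches per epoch (`NULL` = one pass over the
#'   training set).
#' @param epochs maximum training epochs.
#' @param validation_steps maximum validation minibatches per epoch (`NULL` =
#'   full validation set).
#' @param patience early-stopping patience in epochs (stop when the validation
#'   loss has not improved for this long).
#' @param bce_weight,dice_weight loss-term weights; the loss is
#'   `bce_weight * BCE + dice_weight * (1 - Dice)`.
#' @param bn_momentum exponential-smoothing momentum of the batch-norm
#'   population statistics.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(input_px = 128, levels = 5, base_filters = 32,
                        dropout_rate = 0.5, learning_rate = 1e-4,
                        batch_size = 32, steps_per_epoch = NULL,
                        epochs = 183, validation_steps = NULL,
                        patience = 10, bce_weight = 1, dice_weight = 1,
                        bn_momentum = 0.9) {
  cfg <- list(input_px = as.integer(input_px), levels = as.integer(levels),
              base_filters = as.integer(base_filters),
              dropout_rate = dropout_rate, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              steps_per_epoch = steps_per_epoch, epochs = as.integer(epochs),
              validation_steps = validation_steps,
              patience = as.integer(patience),
              bce_weight = bce_weight, dice_weight = dice_weight,
              bn_momentum = bn_momentum)
  class(cfg) <- "unet_config"
  if (cfg$levels < 1 || cfg$base_filters < 1)
    stop("levels and base_filters must be >= 1")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (cfg$input_px %% 2^(cfg$levels - 1) != 0)
    stop("input_px must be divisible by 2^(levels - 1)")
  cfg
}

#' Published-scale and desk-scale configuration presets
#'
#' `unet_config_counting()` and `unet_config_segmentation()` carry the
#' published training settings of the two models (128-px counting tiles at
#' batch 32 for 183 epochs of 256 steps; 512-px segmentation tiles at batch 16
#' for 35 epochs; both 5 levels, 32 base filters, dropout 0.5, Adam at 1e-4,
#' 64 validation steps). `unet_config_desk()` is a reduced model for
#' desk-scale training on synthetic data: 3 levels, 16 base filters, no
#' dropout, a larger learning rate and few epochs.
#'
#' @param ... overrides passed to [unet_config()].
#' @return a `unet_config`.
#' @export
unet_config_counting <- function(...) {
  do.call(unet_config, modifyList(
    list(input_px = 128, levels = 5, base_filters = 32, dropout_rate = 0.5,
         learning_rate = 1e-4, batch_size = 32, steps_per_epoch = 256,
         epochs = 183, validation_steps = 64), list(...)))
}

#' @rdname unet_config_counting
#' @export
unet_config_segmentation <- function(...) {
  do.call(unet_config, modifyList(
    list(input_px = 512, levels = 5, base_filters = 32, dropout_rate = 0.5,
         learning_rate = 1e-4, batch_size = 16, steps_per_epoch = NULL,
         epochs = 35, validation_steps = 64), list(...)))
}

#' @rdname unet_config_counting
#' @export
unet_config_desk <- function(...) {
  do.call(unet_config, modifyList(
    list(input_px = 128, levels = 3, base_filters = 16, dropout_rate = 0,
         learning_rate = 1e-3, batch_size = 4, steps_per_epoch = 25,
         epochs = 12, patience = 5), list(...)))
}

unet_filters <- function(cfg, level) cfg$base_filters * 2^(level - 1)

#' Build an untrained U-Net
#'
#' Initialises convolution weights with He scaling and batch-norm parameters
#' at identity. Deterministic given `seed`.
#'
#' @param config a [unet_config()].
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `unet`: list with `config`, `params` (named flat
#'   list of weight arrays), `state` (batch-norm running statistics) and
#'   `history` (`NULL` until trained).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  P <- list(); S <- list()
  he_conv <- function(cin, cout) matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout)
  add_conv <- function(name, cin, cout) {
    P[[paste0(name, ".W")]] <<- he_conv(cin, cout)
    P[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c) {
    P[[paste0(name, ".gamma")]] <<- rep(1, c)
    P[[paste0(name, ".beta")]] <<- numeric(c)
    S[[paste0(name, ".mean")]] <<- numeric(c)
    S[[paste0(name, ".var")]] <<- rep(1, c)
  }
  with_seed(seed, {
    L <- config$levels
    for (l in seq_len(L)) {
      f <- unet_filters(config, l)
      cin <- if (l == 1) 1L else unet_filters(config, l - 1)
      add_conv(sprintf("enc%d.conv1", l), cin, f)
      add_bn(sprintf("enc%d.bn1", l), f)
      add_conv(sprintf("enc%d.conv2", l), f, f)
      add_bn(sprintf("enc%d.bn2", l), f)
    }
    for (l in rev(seq_len(L - 1))) {
      f <- unet_filters(config, l)
      add_conv(sprintf("dec%d.tconv", l), unet_filters(config, l + 1), f)
      add_conv(sprintf("dec%d.conv1", l), 2L * f, f)
      add_bn(sprintf("dec%d.bn1", l), f)
      add_conv(sprintf("dec%d.conv2", l), f, f)
      add_bn(sprintf("dec%d.bn2", l), f)
    }
    P[["out.W"]] <- matrix(rnorm(config$base_filters, sd = sqrt(2 / config$base_filters)),
                           config$base_filters, 1)
    P[["out.b"]] <- numeric(1)
  })
  structure(list(config = config, params = P, state = S, history = NULL),
            class = "unet")
}

#' Number of trainable parameters of a U-Net
#' @param net a `unet`.
#' @return integer parameter count (convolution weights and biases plus
#'   batch-norm scales and offsets).
#' @export
n_params <- function(net) sum(vapply(net$params, length, integer(1)))

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("U-Net: %d levels, %d base filters, %d-px input, %s parameters\n",
              cfg$levels, cfg$base_filters, cfg$input_px,
              format(n_params(x), big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; best val loss %.4f\n",
                nrow(x$history), min(x$history$val_loss, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.unet <- function(object, ...) {
  print(object)
  cfg <- object$config
  for (l in seq_len(cfg$levels))
    cat(sprintf("  enc%d: %4d px, %d filters\n", l,
                cfg$input_px / 2^(l - 1), unet_filters(cfg, l)))
  invisible(object)
}

## Forward pass. Returns list(p, logits, tape (if cache), state).
## `training` switches batch-norm statistics and enables dropout.
unet_forward <- function(net, X, training = FALSE, cache = FALSE) {
  cfg <- net$config
  P <- net$params; S <- net$state
  L <- cfg$levels
  tape <- if (cache) list()
  rec <- function(entry) if (cache) tape[[length(tape) + 1L]] <<- entry

  conv_bn_relu <- function(x, name) {
    cn <- paste0(name$conv, "."); bn <- paste0(name$bn, ".")
    xin <- x
    x <- conv3x3_forward(x, P[[paste0(cn, "W")]], P[[paste0(cn, "b")]])
    bnc <- bn_forward(x, P[[paste0(bn, "gamma")]], P[[paste0(bn, "beta")]],
                      training, S[[paste0(bn, "mean")]], S[[paste0(bn, "var")]],
                      cfg$bn_momentum)
    if (training) {
      S[[paste0(bn, "mean")]] <<- bnc$rmean
      S[[paste0(bn, "var")]] <<- bnc$rvar
    }
    y <- relu_forward(bnc$Y)
    rec(list(op = "cbr", conv = name$conv, bn = name$bn, xin = xin,
             bncache = list(xhat = bnc$xhat, istd = bnc$istd), yout = y))
    y
  }
  drop_layer <- function(x) {
    if (training && cfg$dropout_rate > 0) {
      dc <- dropout_forward(x, cfg$dropout_rate)
      rec(list(op = "dropout", mask = dc$mask))
      dc$Y
    } else x
  }

  skips <- list()
  x <- X
  for (l in seq_len(L)) {
    if (l > 1) {
      mp <- maxpool_forward(x)
      rec(list(op = "pool", cache = mp))
      x <- drop_layer(mp$Y)
    }
    x <- conv_bn_relu(x, list(conv = sprintf("enc%d.conv1", l), bn = sprintf("enc%d.bn1", l)))
    x <- conv_bn_relu(x, list(conv = sprintf("enc%d.conv2", l), bn = sprintf("enc%d.bn2", l)))
    if (l < L) {
      skips[[l]] <- x
      rec(list(op = "save", level = l))
    }
  }
  for (l in rev(seq_len(L - 1))) {
    z <- zerostuff_forward(x)
    rec(list(op = "stuff"))
    nm <- sprintf("dec%d.tconv", l)
    zin <- z
    x <- conv3x3_forward(z, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]])
    rec(list(op = "conv", name = nm, xin = zin))
    sk <- skips[[l]]
    cmain <- dim(x)[4]
    x <- array(c(x, sk), dim = dim(x) + c(0, 0, 0, dim(sk)[4]))
    rec(list(op = "concat", level = l, cmain = cmain))
    x <- drop_layer(x)
    x <- conv_bn_relu(x, list(conv = sprintf("dec%d.conv1", l), bn = sprintf("dec%d.bn1", l)))
    x <- conv_bn_relu(x, list(conv = sprintf("dec%d.conv2", l), bn = sprintf("dec%d.bn2", l)))
  }
  xin <- x
  logits <- conv1x1_forward(x, P[["out.W"]], P[["out.b"]])
  rec(list(op = "conv1x1", name = "out", xin = xin))
  list(p = sigmoid(logits), logits = logits, tape = tape, state = S)
}

## Backward pass over a recorded tape. Returns named gradient list.
unet_backward <- function(net, tape, dlogits) {
  P <- net$params
  G <- list()
  addg <- function(name, g) G[[name]] <<- if (is.null(G[[name]])) g else G[[name]] + g
  pending <- list() # gradients waiting at encoder save points
  d <- dlogits
  for (i in rev(seq_along(tape))) {
    e <- tape[[i]]
    switch(e$op,
      conv1x1 = {
        bk <- conv1x1_backward(d, e$xin, P[[paste0(e$name, ".W")]])
        addg(paste0(e$name, ".W"), bk$dW); addg(paste0(e$name, ".b"), bk$db)
        d <- bk$dX
      },
      cbr = {
        d <- relu_backward(d, e$yout)
        bnb <- bn_backward(d, e$bncache, P[[paste0(e$bn, ".gamma")]])
        addg(paste0(e$bn, ".gamma"), bnb$dgamma)
        addg(paste0(e$bn, ".beta"), bnb$dbeta)
        bk <- conv3x3_backward(bnb$dX, e$xin, P[[paste0(e$conv, ".W")]])
        addg(paste0(e$conv, ".W"), bk$dW); addg(paste0(e$conv, ".b"), bk$db)
        d <- bk$dX
      },
      conv = {
        bk <- conv3x3_backward(d, e$xin, P[[paste0(e$name, ".W")]])
        addg(paste0(e$name, ".W"), bk$dW); addg(paste0(e$name, ".b"), bk$db)
        d <- bk$dX
      },
      concat = {
        dims <- dim(d)
        dmain <- d[,, , seq_len(e$cmain), drop = FALSE]
        dskip <- d[, , , (e$cmain + 1):dims[4], drop = FALSE]
        pending[[as.character(e$level)]] <- dskip
        d <- dmain
      },
      save = {
        key <- as.character(e$level)
        if (!is.null(pending[[key]])) {
          d <- d + pending[[key]]
          pending[[key]] <- NULL
        }
      },
      stuff = {
        d <- zerostuff_backward(d)
      },
      pool = {
        d <- maxpool_backward(d, e$cache)
      },
      dropout = {
        d <- d * e$mask
      }
    )
  }
  G
}

#' Predict probability maps with a U-Net
#'
#' @param object a `unet`.
#' @param x a matrix of side `config$input_px`, or an (H, W, N) array of N
#'   such tiles.
#' @param batch_size tiles per forward pass.
#' @param ... unused.
#' @return probabilities in (0, 1), same spatial shape as the input.
#' @export
predict.unet <- function(object, x, batch_size = 16L, ...) {
  px <- object$config$input_px
  one <- is.matrix(x)
  if (one) { dim(x) <- c(dim(x), 1L) }
  d <- dim(x)
  if (d[1] != px || d[2] != px)
    stop(sprintf("model expects %d x %d tiles, got %d x %d", px, px, d[1], d[2]))
  out <- array(0, d)
  for (s in seq(1L, d[3], by = batch_size)) {
    e <- min(s + batch_size - 1L, d[3])
    Xb <- x[, , s:e, drop = FALSE]
    dim(Xb) <- c(d[1], d[2], e - s + 1L, 1L)
    fw <- unet_forward(object, Xb, training = FALSE)
    out[, , s:e] <- fw$p
  }
  if (one) out[, , 1] else out
}
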