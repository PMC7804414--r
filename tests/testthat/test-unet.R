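test_that("compiled convolution matches the pure-R im2col reference", {
  withr::with_seed(17, {
    for (cfg in list(c(6, 6, 2, 3, 4), c(9, 7, 1, 2, 5))) {
      H <- cfg[1]; W <- cfg[2]; N <- cfg[3]; Cin <- cfg[4]; Cout <- cfg[5]
      X <- array(rnorm(H * W * N * Cin), c(H, W, N, Cin))
      Wm <- matrix(rnorm(9 * Cin * Cout), 9 * Cin, Cout)
      b <- rnorm(Cout)
      got <- rgcountr:::conv3x3_forward(X, Wm, b)
      want <- ref_conv3x3(X, Wm, b)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("layer gradients agree with finite differences", {
  withr::with_seed(42, {
    cfg <- unet_config(input_px = 8, levels = 2, base_filters = 3,
                       dropout_rate = 0.3, batch_size = 2)
    net <- build_unet(cfg, seed = 3)
    X <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
    Tg <- array(rbinom(128, 1, 0.3), c(8, 8, 2, 1))
    loss_at <- function(net) {
      set.seed(9) # fixed dropout mask
      f <- rgcountr:::unet_forward(net, X, training = TRUE)
      rgcountr:::bce_dice_grad(f$logits, Tg)$loss
    }
    set.seed(9)
    fw <- rgcountr:::unet_forward(net, X, training = TRUE, cache = TRUE)
    lg <- rgcountr:::bce_dice_grad(fw$logits, Tg)
    G <- rgcountr:::unet_backward(net, fw$tape, lg$dlogits)
    eps <- 1e-6
    worst <- 0
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      for (j in sample(length(p), min(2, length(p)))) {
        n2 <- net
        n2$params[[nm]][j] <- p[j] + eps
        lp <- loss_at(n2)
        n2$params[[nm]][j] <- p[j] - eps
        lm <- loss_at(n2)
        num <- (lp - lm) / (2 * eps)
        ana <- G[[nm]][j]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-4)
  })
})

test_that("filter counts double per level and parameters match a hand count", {
  cfg <- unet_config(input_px = 64, levels = 5, base_filters = 32,
                     batch_size = 1)
  expect_equal(vapply(1:5, function(l) rgcountr:::unet_filters(cfg, l),
                      numeric(1)),
               c(32, 64, 128, 256, 512))

  ## independent layer-by-layer parameter count for a tiny config
  cfg2 <- unet_config(input_px = 8, levels = 2, base_filters = 4)
  net2 <- build_unet(cfg2)
  conv_p <- function(cin, cout) 9 * cin * cout + cout
  bn_p <- function(c) 2 * c
  want <- conv_p(1, 4) + bn_p(4) + conv_p(4, 4) + bn_p(4) + # enc1
    conv_p(4, 8) + bn_p(8) + conv_p(8, 8) + bn_p(8) + # enc2 (bottleneck)
    conv_p(8, 4) + # transposed conv
    conv_p(8, 4) + bn_p(4) + conv_p(4, 4) + bn_p(4) + # dec1
    (4 * 1 + 1) # 1x1 output conv
  expect_equal(n_params(net2), want)
})

test_that("output is a probability map of the input size", {
  net <- build_unet(unet_config(input_px = 16, levels = 2, base_filters = 2),
                    seed = 1)
  x <- matrix(runif(16 * 16, -2, 3), 16, 16) # arbitrary finite input
  p <- predict(net, x)
  expect_equal(dim(p), c(16, 16))
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(net, matrix(0, 8, 8)), "expects")
})

test_that("bce_dice_loss matches its closed forms", {
  t <- matrix(rbinom(64, 1, 0.4), 8, 8)
  ## perfect prediction: loss -> 0 as the clamp tightens
  p_perfect <- ifelse(t == 1, 1 - 1e-9, 1e-9)
  expect_lt(bce_dice_loss(p_perfect, t), 1e-6)
  ## flat 0.5 prediction: BCE term is log(2) for any target
  p_half <- matrix(0.5, 8, 8)
  expect_equal(bce_dice_loss(p_half, t, dice_weight = 0), log(2),
               tolerance = 1e-12)
  ## disjoint foregrounds: the Dice term contributes ~1
  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1 - 1e-9
  b <- matrix(0, 8, 8); b[6:8, 6:8] <- 1
  expect_equal(bce_dice_loss(a + 1e-9, b, bce_weight = 0), 1, tolerance = 1e-4)
  expect_error(bce_dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shape")
  ## non-negativity over random cases
  withr::with_seed(2, {
    for (i in 1:20) {
      p <- matrix(runif(64, 0.01, 0.99), 8, 8)
      expect_gte(bce_dice_loss(p, t), 0)
    }
  })
})

test_that("training runs, records history, reduces loss and is reproducible", {
  pairs <- tiny_pairs(12)
  cfg <- unet_config(input_px = 16, levels = 2, base_filters = 6,
                     dropout_rate = 0, learning_rate = 2e-3, batch_size = 4,
                     epochs = 2, patience = 10)
  net <- build_unet(cfg, seed = 1)
  tr <- train_unet(net, pairs[1:8], pairs[9:12], seed = 2)
  expect_equal(nrow(tr$history), 2)
  expect_true(all(is.finite(tr$history$train_loss)))
  expect_true(all(is.finite(tr$history$val_loss)))
  ## same seeds and config: identical loss curves
  tr2 <- train_unet(build_unet(cfg, seed = 1), pairs[1:8], pairs[9:12], seed = 2)
  expect_identical(tr$history, tr2$history)
  ## optimisation sanity: longer training reduces the loss on separable data
  cfg15 <- unet_config(input_px = 16, levels = 2, base_filters = 6,
                       dropout_rate = 0, learning_rate = 2e-3, batch_size = 4,
                       epochs = 15, patience = 15)
  tr15 <- train_unet(build_unet(cfg15, seed = 1), pairs[1:8], pairs[9:12],
                     seed = 2)
  expect_lt(tail(tr15$history$train_loss, 1), tr15$history$train_loss[1])
})

test_that("transfer learning fine-tunes from pretrained weights", {
  pairs <- tiny_pairs(8)
  cfg <- unet_config(input_px = 16, levels = 2, base_filters = 4,
                     dropout_rate = 0, learning_rate = 1e-3, batch_size = 4,
                     epochs = 6, patience = 20)
  pre <- train_unet(build_unet(cfg, seed = 1), pairs, seed = 2)
  ## default fine-tuning schedule is 12 epochs
  ft <- transfer_learn(pre, pairs, seed = 3)
  expect_equal(nrow(ft$history), 12)
  ## self-transfer control: fine-tuning on the pretraining data does not
  ## materially degrade the loss
  l_pre <- rgcountr:::eval_loss(pre, rgcountr:::pairs_to_arrays(pairs, 16)$X,
                                rgcountr:::pairs_to_arrays(pairs, 16)$T, 4)
  l_ft <- rgcountr:::eval_loss(ft, rgcountr:::pairs_to_arrays(pairs, 16)$X,
                               rgcountr:::pairs_to_arrays(pairs, 16)$T, 4)
  expect_lt(l_ft, l_pre * 1.05)
})

test_that("weights round-trip through checkpoints and reject mismatches", {
  net <- build_unet(unet_config(input_px = 16, levels = 2, base_filters = 3),
                    seed = 4)
  d <- withr::local_tempdir()
  path <- file.path(d, "w.rds")
  save_weights(net, path)
  expect_true(file.exists(file.path(d, "w.yml")))
  net2 <- load_weights(path)
  x <- matrix(runif(256), 16, 16)
  expect_identical(predict(net, x), predict(net2, x))
  wrong <- unet_config(input_px = 32, levels = 2, base_filters = 3)
  expect_error(load_weights(path, wrong), "does not match")
})

test_that("a non-finite loss aborts training with a diagnostic", {
  pairs <- tiny_pairs(4)
  pairs[[2]]$image[3, 3] <- NaN # corrupted input propagates to the loss
  cfg <- unet_config(input_px = 16, levels = 2, base_filters = 4,
                     dropout_rate = 0, learning_rate = 1e-3, batch_size = 4,
                     epochs = 3, patience = 10)
  expect_error(train_unet(build_unet(cfg, seed = 1), pairs, seed = 2),
               "diverged|non-finite")
})
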