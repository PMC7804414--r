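# Pure-R reference implementations used as independent oracles for the
# compiled kernels, plus small shared fixtures built in code.

# Reference 3x3 same-padding convolution via explicit im2col. Weight rows are
# ordered dx (outer) then dy in {-1,0,1}, channels fastest, matching the
# layer contract.
ref_conv3x3 <- function(X, W, b) {
  d <- dim(X)
  H <- d[1]; Wd <- d[2]; N <- d[3]; C <- d[4]
  P <- array(0, c(H + 2, Wd + 2, N, C))
  P[2:(H + 1), 2:(Wd + 1), , ] <- X
  cols <- matrix(0, H * Wd * N, 9 * C)
  k <- 0
  for (dx in 0:2) {
    for (dy in 0:2) {
      k <- k + 1
      blk <- P[(1 + dy):(H + dy), (1 + dx):(Wd + dx), , , drop = FALSE]
      dim(blk) <- c(H * Wd * N, C)
      cols[, ((k - 1) * C + 1):(k * C)] <- blk
    }
  }
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(H, Wd, N, ncol(W))
  Y
}

# Brute-force rasterized disc pixel count.
ref_disc_pixels <- function(cx, cy, r, h, w) {
  cnt <- 0L
  for (x in 0:(w - 1)) {
    for (y in 0:(h - 1)) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2) cnt <- cnt + 1L
    }
  }
  cnt
}

# A small synthetic retina shared across tests (generated once per session).
.fixture_env <- new.env(parent = emptyenv())

tiny_retina <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- generate_retina(
      synthetic_spec(retina_radius = 200, seed = 42))
  }
  .fixture_env$tiny
}

# Tiny training pairs (16 px) with a centred disc target, separable enough
# for quick optimisation checks.
tiny_pairs <- function(n = 10, px = 16, seed = 5) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cx <- sample(5:(px - 5), 1)
      cy <- sample(5:(px - 5), 1)
      pts <- data.frame(x_px = cx, y_px = cy)
      tgt <- points_to_mask(pts, c(px, px), 2)
      img <- tgt * 0.7 + matrix(runif(px * px, 0, 0.15), px, px)
      structure(list(image = img, target = tgt), class = "training_pair")
    })
  })
}
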