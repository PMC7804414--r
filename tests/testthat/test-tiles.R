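test_that("tile plans reproduce the documented tile counts", {
  expect_equal(nrow(plan_tiles(c(2048, 2048), 512, 0.25)$origins), 25)
  expect_equal(nrow(plan_tiles(c(768, 768), 256, 0)$origins), 9)
  expect_equal(nrow(plan_tiles(c(256, 256), 256, 0.125)$origins), 1)
  expect_error(plan_tiles(c(100, 100), 256, 0), "exceeds")
})

test_that("every pixel is covered by at least one tile (random plans)", {
  withr::with_seed(7, {
    for (i in 1:25) {
      h <- sample(40:300, 1)
      w <- sample(40:300, 1)
      tp <- sample(10:min(h, w), 1)
      ov <- runif(1, 0, 0.6)
      plan <- plan_tiles(c(h, w), tp, ov)
      cover <- matrix(0L, h, w)
      for (k in seq_len(nrow(plan$origins))) {
        o <- plan$origins[k, ]
        cover[(o[1] + 1):(o[1] + tp), (o[2] + 1):(o[2] + tp)] <-
          cover[(o[1] + 1):(o[1] + tp), (o[2] + 1):(o[2] + tp)] + 1L
      }
      expect_true(all(cover >= 1))
      ## origins advance by the stride except the clamped last one
      rows <- sort(unique(plan$origins[, 1]))
      if (length(rows) > 2)
        expect_true(all(diff(head(rows, -1)) == plan$stride))
    }
  })
})

test_that("stitching merges overlaps by mean (or max) and is idempotent", {
  ## constant tiles produce a constant map
  plan <- plan_tiles(c(10, 15), 10, 1 / 3)
  tiles_c <- lapply(seq_len(nrow(plan$origins)), function(i)
    list(origin = plan$origins[i, ], prediction = matrix(0.7, 10, 10)))
  expect_equal(stitch(tiles_c, plan), matrix(0.7, 10, 15))

  ## two overlapping tiles valued 0 and 1: overlap averages to 0.5
  expect_equal(nrow(plan$origins), 2)
  tiles01 <- list(
    list(origin = plan$origins[1, ], prediction = matrix(0, 10, 10)),
    list(origin = plan$origins[2, ], prediction = matrix(1, 10, 10))
  )
  sm <- stitch(tiles01, plan)
  expect_equal(sm[, 6:10], matrix(0.5, 10, 5)) # overlap region
  expect_equal(sm[, 1:5], matrix(0, 10, 5))
  expect_equal(sm[, 11:15], matrix(1, 10, 5))
  expect_equal(stitch(tiles01, plan, merge = "max")[, 6:10], matrix(1, 10, 5))

  ## single tile covering the image is the identity
  plan1 <- plan_tiles(c(12, 12), 12, 0)
  m <- matrix(runif(144), 12, 12)
  expect_equal(stitch(list(list(origin = c(0, 0), prediction = m)), plan1), m)

  ## tiles cut from one map stitch back to that map exactly
  withr::with_seed(3, {
    map <- matrix(runif(80 * 70), 80, 70)
    plan2 <- plan_tiles(c(80, 70), 32, 0.25)
    tiles <- lapply(seq_len(nrow(plan2$origins)), function(i) {
      o <- plan2$origins[i, ]
      list(origin = o, prediction = map[(o[1] + 1):(o[1] + 32),
                                        (o[2] + 1):(o[2] + 32)])
    })
    expect_equal(stitch(tiles, plan2), map, tolerance = 1e-12)
  })

  ## uncovered pixels are rejected
  expect_error(stitch(tiles01[1], plan), "uncovered")
})

test_that("predict_tiled with an identity stand-in reproduces the input", {
  withr::with_seed(5, {
    img <- matrix(runif(120 * 90), 120, 90)
    plan <- plan_tiles(dim(img), 40, 0.2)
    out <- predict_tiled(img, identity, plan)
    expect_equal(out, img, tolerance = 1e-12)
    ## translation-invariant model on a constant image: constant output
    cimg <- matrix(0.42, 96, 96)
    plan2 <- plan_tiles(dim(cimg), 32, 0.125)
    out2 <- predict_tiled(cimg, identity, plan2)
    expect_equal(out2, cimg, tolerance = 1e-12)
    ## rescale round trip stays close on a smooth image
    smooth <- rgcountr:::resize_matrix(matrix(runif(64), 8, 8), 128, 128)
    plan3 <- plan_tiles(dim(smooth), 64, 0.125)
    out3 <- predict_tiled(smooth, identity, plan3, tile_rescale = 0.5)
    expect_lt(max(abs(out3 - smooth)), 0.06)
  })
})

test_that("overlap shrinks tile-seam errors of a blur stand-in model", {
  ## fixed Gaussian-blur "model" (replicate boundary so image edges match
  ## the oracle): tiled prediction vs whole-image computation
  sigma <- 3
  blur_model <- function(tile)
    t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(tile)), sigma,
                                        boundary = "replicate")))
  withr::with_seed(11, {
    img <- rgcountr:::resize_matrix(matrix(runif(900), 30, 30), 240, 240)
    oracle <- blur_model(img)
    err <- sapply(c(0, 0.125, 0.25), function(ov) {
      plan <- plan_tiles(dim(img), 80, ov)
      max(abs(predict_tiled(img, blur_model, plan) - oracle))
    })
    ## away from internal tile boundaries the tiled result is exact; the
    ## error lives in a band of the kernel support around the seams
    plan <- plan_tiles(dim(img), 80, 0.125)
    band <- ceiling(3 * sigma) + 1
    seam <- matrix(FALSE, 240, 240)
    for (b in setdiff(unique(c(plan$origins[, 1], plan$origins[, 1] + 80)),
                      c(0, 240)))
      seam[pmax(1, b - band):pmin(240, b + band + 1), ] <- TRUE
    for (b in setdiff(unique(c(plan$origins[, 2], plan$origins[, 2] + 80)),
                      c(0, 240)))
      seam[, pmax(1, b - band):pmin(240, b + band + 1)] <- TRUE
    diff_away <- abs(predict_tiled(img, blur_model, plan) - oracle)
    expect_lt(max(diff_away[!seam]), 1e-8)
    ## overlap merging strictly reduces the seam error vs zero overlap
    expect_lt(err[2], err[1])
    expect_lt(err[3], err[1])
    ## seam error is non-increasing as overlap grows
    expect_lte(err[3], err[2] + 1e-12)
  })
})

test_that("binarize thresholds correctly and is monotone", {
  expect_equal(binarize(matrix(0.9, 3, 3), 0.5), matrix(1L, 3, 3))
  expect_equal(binarize(matrix(0.1, 3, 3), 0.5), matrix(0L, 3, 3))
  withr::with_seed(13, {
    map <- matrix(runif(400), 20, 20)
    counts <- sapply(seq(0.05, 0.95, length.out = 11),
                     function(th) sum(binarize(map, th)))
    expect_true(all(diff(counts) <= 0))
  })
  expect_error(binarize(matrix(0.5, 2, 2), 0), "threshold")
})
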