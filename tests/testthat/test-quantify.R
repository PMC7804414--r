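test_that("component labelling is 8-connected with exact centroids", {
  m <- matrix(0L, 7, 7)
  m[2, 2] <- 1L; m[3, 3] <- 1L # diagonal touch: one component
  m[6, 6] <- 1L
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  st <- component_stats(label_components(points_to_mask(
    data.frame(x_px = c(10, 40), y_px = c(12, 30)), c(64, 64), 4)))
  expect_equal(nrow(st), 2)
  expect_equal(st$x_px, c(10, 40), tolerance = 1e-9)
  expect_equal(st$y_px, c(12, 30), tolerance = 1e-9)
})

test_that("detect_cells counts disjoint discs injected past the model", {
  ## the "model" just passes the rendered mask through
  img <- points_to_mask(data.frame(x_px = c(60, 160), y_px = c(70, 150)),
                        c(256, 256), 6)
  fm <- flatmount(img * 0.9, pixel_scale = 2.17, id = "two-cells")
  cells <- detect_cells(fm, identity, tile_px = 128, overlap = 0.125,
                        tile_rescale = 1)
  expect_equal(cells$count, 2)
  expect_equal(sort(cells$components$x_px), c(60, 160), tolerance = 1)
  ## empty input: zero cells
  fm0 <- flatmount(matrix(0, 256, 256))
  expect_equal(detect_cells(fm0, identity, tile_px = 128,
                            tile_rescale = 1)$count, 0)
})

test_that("mask area converts to mm2 by the pixel scale", {
  ## 4,708,900 foreground pixels at 2.17 px/um equal exactly 1 mm2
  mask <- matrix(1L, 2170, 2170)
  fm <- flatmount(matrix(0, 2170, 2170), pixel_scale = 2.17)
  seg <- segmentation_from_mask(mask, fm)
  expect_equal(sum(mask), 4708900)
  expect_equal(seg$area_mm2, 1, tolerance = 1e-12)
})

test_that("filter_by_retina keeps exactly the centroids inside the mask", {
  comp <- data.frame(label = 1:40,
                     x_px = runif(40, 0, 199), y_px = runif(40, 0, 199),
                     area_px = 50L)
  cells <- detected_cells(comp)
  fm <- flatmount(matrix(0, 200, 200))
  ## full-frame mask: identity
  full <- segmentation_from_mask(matrix(1L, 200, 200), fm)
  expect_equal(filter_by_retina(cells, full)$count, 40)
  ## empty mask: nothing survives
  empty <- segmentation_from_mask(matrix(0L, 200, 200), fm)
  expect_equal(filter_by_retina(cells, empty)$count, 0)
  ## half-frame mask at half resolution: brute-force point-in-mask oracle
  half <- matrix(0L, 100, 100)
  half[, 1:50] <- 1L
  seg <- segmentation_from_mask(half, fm)
  got <- filter_by_retina(cells, seg)
  want <- sum(floor(comp$x_px / 2) + 1 <= 50)
  expect_equal(got$count, want)
})

test_that("quantification composes count, area and density", {
  ## synthetic image whose "probability map" is its own mask
  pts <- data.frame(x_px = c(50, 120, 200, 80), y_px = c(60, 40, 180, 200))
  img <- points_to_mask(pts, c(256, 256), 5) * 0.8
  fm <- flatmount(img, pixel_scale = 2.17, id = "toy")
  seg <- segmentation_from_mask(matrix(1L, 256, 256), fm)
  q <- quantify_retina(fm, identity, seg = seg, tile_px = 128,
                       tile_rescale = 1)
  expect_s3_class(q, "quant_result")
  expect_equal(q$count, 4)
  expect_equal(q$density, q$count / q$area_mm2, tolerance = 1e-12)
  ## an all-background image with a zero-returning model is flagged
  fm0 <- flatmount(matrix(0, 512, 512))
  zmodel <- function(tile) tile * 0
  seg0 <- segment_retina(fm0, zmodel, working_px = 256, tile_px = 128)
  expect_true(seg0$empty)
  q0 <- quantify_retina(fm0, zmodel, seg = seg0, tile_px = 128,
                        tile_rescale = 1)
  expect_true(q0$flagged)
  expect_true(is.na(q0$density))
})

test_that("segment_retina cleans the prediction to one filled component", {
  ## a stand-in model that passes the downscaled image through; the image
  ## contains a bright blob, a hole inside it, and a small distant speck
  img <- matrix(0, 512, 512)
  img[100:400, 120:420] <- 0.9
  img[200:220, 200:220] <- 0 # interior hole
  img[30:34, 30:34] <- 0.9 # artefact away from the retina
  fm <- flatmount(img, pixel_scale = 2.17)
  seg <- segment_retina(fm, identity, working_px = 256, tile_px = 128,
                        overlap = 0.25)
  expect_false(seg$empty)
  lab <- label_components(seg$mask)
  expect_equal(max(lab), 1) # single component
  ## the interior hole was filled and the speck discarded: the mask area is
  ## close to the blob area at working resolution (301^2 px / 2^2)
  expect_equal(sum(seg$mask), 301^2 / 4, tolerance = 0.05)
  ## the speck region is background
  expect_equal(sum(seg$mask[1:25, 1:25]), 0)
})

test_that("isodensity maps conserve mass and match the closed-form peak", {
  ## single cell: peak value is 1e6 / (2 pi h^2) cells/mm2 at the cell
  one <- detected_cells(data.frame(label = 1L, x_px = 217, y_px = 217,
                                   area_px = 60L))
  dm <- isodensity_map(one, pixel_scale = 2.17, bandwidth_um = 150,
                       grid_spacing_um = 50)
  peak <- 1e6 / (2 * pi * 150^2)
  expect_equal(max(dm$grid), peak, tolerance = 1e-9)
  ix <- which(dm$grid == max(dm$grid), arr.ind = TRUE)
  expect_equal(dm$x_um[ix[2]], 217 / 2.17, tolerance = 1e-9)
  expect_equal(dm$y_um[ix[1]], 217 / 2.17, tolerance = 1e-9)
  ## mass conservation: integral over the unmasked plane equals the count
  withr::with_seed(21, {
    comp <- data.frame(label = 1:50, x_px = runif(50, 0, 2000),
                       y_px = runif(50, 0, 2000), area_px = 60L)
    dm50 <- isodensity_map(detected_cells(comp), pixel_scale = 2.17)
    expect_equal(rgcountr:::density_map_mass(dm50), 50, tolerance = 1e-3)
  })
  ## zero cells: an all-zero map
  none <- detected_cells(data.frame(label = integer(0), x_px = numeric(0),
                                    y_px = numeric(0), area_px = integer(0)))
  expect_equal(sum(isodensity_map(none)$grid), 0)
})

test_that("interior KDE values recover a uniform density", {
  withr::with_seed(33, {
    d <- 3000 # cells/mm2
    R <- 1000 # um
    n <- rpois(1, d * pi * R^2 / 1e6)
    r <- R * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    comp <- data.frame(label = seq_len(n), x_px = (r * cos(th) + R) * 2.17,
                       y_px = (r * sin(th) + R) * 2.17, area_px = 60L)
    dm <- isodensity_map(detected_cells(comp), pixel_scale = 2.17)
    gx <- matrix(dm$x_um, nrow(dm$grid), ncol(dm$grid), byrow = TRUE)
    gy <- matrix(dm$y_um, nrow(dm$grid), ncol(dm$grid))
    interior <- sqrt((gx - R)^2 + (gy - R)^2) < R - 3 * dm$bandwidth_um
    vals <- dm$grid[interior]
    expect_lt(abs(mean(vals) / d - 1), 0.05)
    expect_lt(max(abs(vals / d - 1)), 0.2)
  })
})

test_that("the KDE agrees with an independent bivariate implementation", {
  withr::with_seed(8, {
    n <- 25
    comp <- data.frame(label = 1:n, x_px = runif(n, 0, 500),
                       y_px = runif(n, 0, 500), area_px = 60L)
    dm <- isodensity_map(detected_cells(comp), pixel_scale = 1,
                         bandwidth_um = 100, grid_spacing_um = 25)
    ## MASS::kde2d uses a normal kernel with sd = h/4
    k <- MASS::kde2d(comp$x_px, comp$y_px, h = 4 * 100,
                     n = c(length(dm$x_um), length(dm$y_um)),
                     lims = c(range(dm$x_um), range(dm$y_um)))
    ## kde2d returns z[x, y]; our grid is [y, x]
    expect_equal(dm$grid, t(k$z) * n * 1e6, tolerance = 1e-8)
  })
})

test_that("overlays carry markers and contours at the image size", {
  ret <- tiny_retina()
  fm <- flatmount(ret$image, ret$pixel_scale, "tiny")
  seg <- segmentation_from_mask(ret$mask, fm)
  cells <- detected_cells(data.frame(label = 1:3,
                                     x_px = ret$centres$x_px[1:3],
                                     y_px = ret$centres$y_px[1:3],
                                     area_px = 60L))
  ov <- render_overlay(fm, cells, seg)
  expect_equal(dim(ov), c(dim(fm$image), 3))
  red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  expect_gt(sum(red), 0) # markers present
  ov0 <- render_overlay(fm, NULL, seg)
  red0 <- ov0[, , 1] == 1 & ov0[, , 2] == 0 & ov0[, , 3] == 0
  expect_equal(sum(red0), 0) # contour only
  green <- ov0[, , 2] == 1 & ov0[, , 1] == 0
  expect_gt(sum(green), 0)
})
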