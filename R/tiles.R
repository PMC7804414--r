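## Overlapping-tile inference: plan tile origins over an arbitrarily large
## image, predict per tile, and stitch the overlapping predictions back into
## a full-image probability map. Overlap suppresses edge artefacts at tile
## seams; the published settings are 256-px tiles at 12.5% overlap for
## counting and 512-px tiles at 25% overlap for segmentation.

#' Plan overlapping tiles over an image
#'
#' Per dimension, origins advance by `stride = round(tile_px * (1 -
#' overlap_fraction))` starting at 0, with the final origin clamped flush to
#' the image edge (no padding), so the tiles always cover every pixel.
#'
#' @param image_shape (h, w) in pixels.
#' @param tile_px tile side in pixels; must not exceed either dimension.
#' @param overlap_fraction fractional overlap between consecutive tiles in
#'   \[0, 1).
#' @return a `tile_plan`: list with `image_shape`, `tile_px`,
#'   `overlap_fraction`, `stride` and `origins` (two-column matrix of 0-based
#'   row/col tile origins).
#' @examples
#' nrow(plan_tiles(c(2048, 2048), 512, 0.25)$origins) # 25 tiles
#' @export
plan_tiles <- function(image_shape, tile_px, overlap_fraction = 0) {
  stopifnot(length(image_shape) == 2, overlap_fraction >= 0, overlap_fraction < 1)
  if (tile_px > min(image_shape))
    stop("tile_px exceeds an image dimension")
  stride <- max(1L, round(tile_px * (1 - overlap_fraction)))
  axis_origins <- function(len) {
    o <- seq(0L, len - tile_px, by = stride)
    if (o[length(o)] != len - tile_px) o <- c(o, len - tile_px)
    unique(o)
  }
  rows <- axis_origins(image_shape[1])
  cols <- axis_origins(image_shape[2])
  origins <- cbind(row = rep(rows, times = length(cols)),
                   col = rep(cols, each = length(rows)))
  structure(list(image_shape = as.integer(image_shape),
                 tile_px = as.integer(tile_px),
                 overlap_fraction = overlap_fraction,
                 stride = as.integer(stride), origins = origins),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("Tile plan: %d tiles of %d px (stride %d, overlap %.1f%%) over %d x %d\n",
              nrow(x$origins), x$tile_px, x$stride, 100 * x$overlap_fraction,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Stitch per-tile predictions into a full-image map
#'
#' Overlapping predictions are merged per pixel by their mean (default) or
#' maximum. Every pixel must be covered by at least one tile.
#'
#' @param tiles list of `list(origin = c(row, col), prediction = matrix)` with
#'   0-based origins.
#' @param plan the `tile_plan` the tiles were cut with (supplies the output
#'   shape; tile sizes are taken from the predictions themselves).
#' @param merge `"mean"` or `"max"`.
#' @return matrix of the planned image shape.
#' @export
stitch <- function(tiles, plan, merge = c("mean", "max")) {
  merge <- match.arg(merge)
  h <- plan$image_shape[1]; w <- plan$image_shape[2]
  acc <- matrix(if (merge == "mean") 0 else -Inf, h, w)
  cnt <- matrix(0L, h, w)
  for (tl in tiles) {
    p <- tl$prediction
    r <- tl$origin[1] + seq_len(nrow(p))
    cc <- tl$origin[2] + seq_len(ncol(p))
    if (max(r) > h || max(cc) > w) stop("tile extends beyond the image")
    if (merge == "mean") acc[r, cc] <- acc[r, cc] + p
    else acc[r, cc] <- pmax(acc[r, cc], p)
    cnt[r, cc] <- cnt[r, cc] + 1L
  }
  if (any(cnt == 0)) stop("tile plan leaves uncovered pixels")
  if (merge == "mean") acc / cnt else acc
}

## Dispatch a model over a stack of tiles: either a `unet` or any function
## taking a matrix tile and returning a same-shape matrix.
apply_model <- function(model, tiles_array) {
  if (inherits(model, "unet")) return(predict(model, tiles_array))
  out <- array(0, dim(tiles_array))
  for (i in seq_len(dim(tiles_array)[3]))
    out[, , i] <- model(tiles_array[, , i])
  out
}

#' Predict a probability map over a large image by overlapping tiles
#'
#' Tiles are cut according to `plan`, optionally rescaled by `tile_rescale`
#' (the counting path feeds 256-px tiles to a 128-px model, i.e. rescale
#' 0.5), predicted, stitched at the model's working resolution, and the
#' stitched map is scaled back to the source image size.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param model a trained `unet`, or a function mapping a tile matrix to a
#'   same-shape prediction matrix (useful as an inference stand-in).
#' @param plan a [plan_tiles()] plan for `dim(image)`.
#' @param tile_rescale scale factor applied to tiles before prediction.
#' @param merge stitch merge rule.
#' @param batch_size tiles per model call.
#' @return probability map matrix, same shape as `image`, values in \[0, 1\].
#' @export
predict_tiled <- function(image, model, plan, tile_rescale = 1,
                          merge = "mean", batch_size = 16L) {
  stopifnot(inherits(plan, "tile_plan"),
            all(dim(image) == plan$image_shape))
  tp <- plan$tile_px
  mp <- round(tp * tile_rescale)
  if (inherits(model, "unet") && model$config$input_px != mp)
    stop(sprintf("model input %d px does not match tile_px x tile_rescale = %d px",
                 model$config$input_px, mp))
  n <- nrow(plan$origins)
  preds <- vector("list", n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    stack <- array(0, c(mp, mp, e - s + 1L))
    for (i in s:e) {
      o <- plan$origins[i, ]
      tile <- image[(o[1] + 1):(o[1] + tp), (o[2] + 1):(o[2] + tp)]
      stack[, , i - s + 1L] <- if (tile_rescale != 1)
        resize_matrix(tile, mp, mp) else tile
    }
    out <- apply_model(model, stack)
    for (i in s:e) preds[[i]] <- out[, , i - s + 1L]
  }
  if (tile_rescale != 1) {
    ## stitch on the rescaled grid, then scale the map back up
    sshape <- round(plan$image_shape * tile_rescale)
    splan <- plan
    splan$image_shape <- as.integer(sshape)
    sorig <- round(plan$origins * tile_rescale)
    ## clamp so rounded origins keep tiles inside the rescaled canvas
    sorig[, 1] <- pmin(sorig[, 1], sshape[1] - mp)
    sorig[, 2] <- pmin(sorig[, 2], sshape[2] - mp)
    tiles <- lapply(seq_len(n), function(i)
      list(origin = sorig[i, ], prediction = preds[[i]]))
    small <- stitch(tiles, splan, merge)
    clamp01(resize_matrix(small, plan$image_shape[1], plan$image_shape[2]))
  } else {
    tiles <- lapply(seq_len(n), function(i)
      list(origin = plan$origins[i, ], prediction = preds[[i]]))
    stitch(tiles, plan, merge)
  }
}

#' Threshold a probability map into a binary mask
#'
#' @param map numeric matrix in \[0, 1\].
#' @param threshold cut-off in (0, 1); pixels `>= threshold` become 1.
#' @return integer matrix in \{0, 1\}.
#' @export
binarize <- function(map, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  m <- (map >= threshold) * 1L
  dim(m) <- dim(map)
  m
}
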