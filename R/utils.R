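## Small shared helpers: image resizing, unit conversion, seeded evaluation.

#' Convert pixels to micrometres
#'
#' @param px length in pixels.
#' @param pixel_scale pixels per micrometre (default 2.17, the epifluorescence
#'   mosaic resolution the pipeline is calibrated for).
#' @return length in micrometres.
#' @examples
#' px_to_um(768) # side of a counting frame, ~354 um
#' @export
px_to_um <- function(px, pixel_scale = 2.17) {
  stopifnot(pixel_scale > 0)
  px / pixel_scale
}

#' Convert micrometres to pixels
#'
#' @inheritParams px_to_um
#' @param um length in micrometres.
#' @return length in pixels (not rounded).
#' @export
um_to_px <- function(um, pixel_scale = 2.17) {
  stopifnot(pixel_scale > 0)
  um * pixel_scale
}

#' Percent change between two densities
#'
#' Relative loss (positive) or gain (negative) of `value` with respect to
#' `reference`, in percent: `100 * (reference - value) / reference`.
#'
#' @param reference baseline value (e.g. naive mean density, cells/mm2).
#' @param value comparison value (e.g. injured mean density).
#' @return percent loss relative to `reference`.
#' @export
density_loss_percent <- function(reference, value) {
  stopifnot(reference != 0)
  100 * (reference - value) / reference
}

## Resize a 2D matrix with EBImage; `binary = TRUE` uses nearest neighbour so
## masks stay in {0,1}, otherwise bilinear.
resize_matrix <- function(x, h, w, binary = FALSE) {
  stopifnot(is.matrix(x))
  if (nrow(x) == h && ncol(x) == w) return(x)
  filt <- if (binary) "none" else "bilinear"
  ## EBImage images are indexed (x, y) = (column, row); transpose in and out
  ## so that the package convention (row = y, col = x) is preserved.
  img <- EBImage::Image(t(x))
  out <- EBImage::resize(img, w = w, h = h, filter = filt)
  t(EBImage::imageData(out))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Read a single-channel image (TIFF or PNG) as a numeric matrix in [0,1],
## row = y. Multi-channel inputs are averaged.
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  x
}

write_image <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  x <- clamp01(x)
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 16L),
    png = png::writePNG(x, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}
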