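## End-to-end quantification: retina segmentation, cell detection by
## connected components, restriction to the retina, area / density, and
## kernel-density isodensity maps.

#' Flatmount image container
#'
#' @param image single-channel numeric matrix in \[0, 1\] (row = y), or a
#'   path to a TIFF/PNG read with the same convention.
#' @param pixel_scale pixels per um (default 2.17).
#' @param id retina identifier (defaults to the file stem or "retina").
#' @return an object of class `flatmount`.
#' @export
flatmount <- function(image, pixel_scale = 2.17, id = NULL) {
  if (is.character(image)) {
    if (is.null(id)) id <- tools::file_path_sans_ext(basename(image))
    image <- read_image(image)
  }
  stopifnot(is.matrix(image), pixel_scale > 0)
  structure(list(image = image, pixel_scale = pixel_scale,
                 id = if (is.null(id)) "retina" else id),
            class = "flatmount")
}

#' @export
print.flatmount <- function(x, ...) {
  cat(sprintf("Flatmount '%s': %d x %d px at %g px/um\n", x$id,
              nrow(x$image), ncol(x$image), x$pixel_scale))
  invisible(x)
}

#' Label connected components (8-connectivity)
#'
#' Foreground pixels touching edge- or corner-wise belong to one component.
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask))))
  lab <- t(lab)
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  ## bwlabel is 4-connected; merge labels that touch diagonally
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1] # down-right diagonal
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1] # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) > 0) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

## Centroids (0-based pixel coordinates) and pixel areas per labelled
## component.
component_stats <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0)))
  h <- nrow(labels)
  lab <- labels[idx]
  y <- (idx - 1) %% h
  x <- (idx - 1) %/% h
  area <- as.integer(rowsum(rep(1L, length(idx)), lab))
  ux <- rowsum(x, lab) / area
  uy <- rowsum(y, lab) / area
  data.frame(label = sort(unique(lab)), x_px = as.numeric(ux),
             y_px = as.numeric(uy), area_px = area)
}

#' Construct a cell-detection result
#'
#' @param components data.frame with `label`, `x_px`, `y_px` (0-based
#'   centroids at source resolution) and `area_px`.
#' @return an object of class `detected_cells` with a `count` field.
#' @export
detected_cells <- function(components) {
  stopifnot(all(c("label", "x_px", "y_px", "area_px") %in% names(components)))
  if (anyDuplicated(components$label)) stop("component labels must be unique")
  structure(list(components = components, count = nrow(components)),
            class = "detected_cells")
}

#' @export
print.detected_cells <- function(x, ...) {
  cat(sprintf("Detected cells: %d components\n", x$count))
  invisible(x)
}

#' Detect cells on a whole flatmount
#'
#' Runs the counting model over the image with overlapping tiles (256-px
#' tiles, 12.5% overlap, rescaled 0.5 to the 128-px model), binarizes the
#' stitched and up-scaled probability map, labels 8-connected components,
#' removes specks below a minimum area, and reports centroids at source
#' resolution.
#'
#' @param fm a [flatmount()].
#' @param model trained counting `unet` (or a stand-in function; see
#'   [predict_tiled()]).
#' @param tile_px,overlap,tile_rescale tiling settings (published defaults).
#' @param threshold binarization threshold.
#' @param min_area_um2 minimum component area; the default is the area of a
#'   4-um-diameter disc, removing binarization specks well below any soma
#'   size. Set 0 to disable.
#' @return a `detected_cells`.
#' @export
detect_cells <- function(fm, model, tile_px = 256, overlap = 0.125,
                         tile_rescale = 0.5, threshold = 0.5,
                         min_area_um2 = pi * 2^2) {
  stopifnot(inherits(fm, "flatmount"))
  plan <- plan_tiles(dim(fm$image), tile_px, overlap)
  pmap <- predict_tiled(fm$image, model, plan, tile_rescale)
  mask <- binarize(pmap, threshold)
  labels <- label_components(mask)
  comp <- component_stats(labels)
  min_px <- min_area_um2 * fm$pixel_scale^2
  comp <- comp[comp$area_px >= min_px, , drop = FALSE]
  rownames(comp) <- NULL
  detected_cells(comp)
}

#' Segment the retina silhouette
#'
#' The flatmount is scaled down to a square working resolution (published:
#' 2048 px, covered by 25 overlapping 512-px tiles at 25% overlap), the
#' segmentation model is applied tile-wise, and the binarized prediction is
#' cleaned by keeping the largest connected component and filling interior
#' holes. Retinal area follows from the mask pixel count and the pixel scale.
#'
#' @param fm a [flatmount()].
#' @param model trained segmentation `unet` (or a stand-in function).
#' @param working_px working resolution (default 2048).
#' @param tile_px tile side at working resolution (default 512).
#' @param overlap tile overlap fraction (default 0.25).
#' @param threshold binarization threshold.
#' @return an object of class `retina_segmentation`: `mask` (working
#'   resolution), `downscale_factor` (source px per working px, per axis),
#'   `area_mm2`, `empty` flag.
#' @export
segment_retina <- function(fm, model, working_px = 2048, tile_px = 512,
                           overlap = 0.25, threshold = 0.5) {
  stopifnot(inherits(fm, "flatmount"))
  small <- resize_matrix(fm$image, working_px, working_px)
  tile_rescale <- if (inherits(model, "unet"))
    model$config$input_px / tile_px else 1
  plan <- plan_tiles(c(working_px, working_px), tile_px, overlap)
  pmap <- predict_tiled(small, model, plan, tile_rescale)
  mask <- binarize(pmap, threshold)
  down <- dim(fm$image) / working_px
  if (sum(mask) == 0) {
    return(structure(list(mask = mask, downscale_factor = down,
                          area_mm2 = NA_real_, empty = TRUE),
                     class = "retina_segmentation"))
  }
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0])
  keep <- which.max(areas)
  mask <- (labels == keep) * 1L
  mask <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(mask)))))
  storage.mode(mask) <- "integer"
  area_mm2 <- sum(mask) * prod(down) / fm$pixel_scale^2 / 1e6
  structure(list(mask = mask, downscale_factor = down, area_mm2 = area_mm2,
                 empty = FALSE),
            class = "retina_segmentation")
}

#' Segmentation result from a known mask
#'
#' Wraps a ground-truth or externally produced silhouette mask (at source
#' resolution or any working resolution) as a `retina_segmentation`, e.g. to
#' quantify with a manual outline.
#'
#' @param mask binary matrix.
#' @param fm the corresponding [flatmount()].
#' @return a `retina_segmentation`.
#' @export
segmentation_from_mask <- function(mask, fm) {
  down <- dim(fm$image) / dim(mask)
  area_mm2 <- sum(mask > 0) * prod(down) / fm$pixel_scale^2 / 1e6
  structure(list(mask = (mask > 0) * 1L, downscale_factor = down,
                 area_mm2 = area_mm2, empty = sum(mask > 0) == 0),
            class = "retina_segmentation")
}

#' @export
print.retina_segmentation <- function(x, ...) {
  if (x$empty) cat("Retina segmentation: EMPTY (flagged)\n")
  else cat(sprintf("Retina segmentation: %.3f mm2 (mask %d x %d)\n",
                   x$area_mm2, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Discard detected cells outside the segmented retina
#'
#' A cell is kept when its centroid falls on a foreground pixel of the
#' segmentation mask (coordinates mapped through the segmentation's
#' downscale factor).
#'
#' @param cells a `detected_cells` (centroids at source resolution).
#' @param seg a `retina_segmentation`.
#' @return filtered `detected_cells`.
#' @export
filter_by_retina <- function(cells, seg) {
  stopifnot(inherits(cells, "detected_cells"),
            inherits(seg, "retina_segmentation"))
  if (cells$count == 0 || seg$empty)
    return(detected_cells(cells$components[0, , drop = FALSE]))
  comp <- cells$components
  r <- pmin(pmax(floor(comp$y_px / seg$downscale_factor[1]) + 1, 1), nrow(seg$mask))
  cc <- pmin(pmax(floor(comp$x_px / seg$downscale_factor[2]) + 1, 1), ncol(seg$mask))
  keep <- seg$mask[cbind(r, cc)] > 0
  out <- comp[keep, , drop = FALSE]
  rownames(out) <- NULL
  detected_cells(out)
}

#' Quantify a whole flatmount
#'
#' The full pipeline deliverable: segment the retina, detect cells, discard
#' detections outside the retina, and report count, area and density.
#'
#' @param fm a [flatmount()].
#' @param counting_model trained counting `unet`.
#' @param seg_model trained segmentation `unet`, or `NULL` to skip
#'   segmentation (count only; area and density are `NA`).
#' @param seg optional precomputed `retina_segmentation` (overrides
#'   `seg_model`).
#' @param ... passed to [detect_cells()].
#' @param working_px,tile_px,overlap segmentation settings, see
#'   [segment_retina()].
#' @return an object of class `quant_result`: `retina_id`, `count`,
#'   `area_mm2`, `density` (cells/mm2), `cells`, `segmentation`, `flagged`.
#' @export
quantify_retina <- function(fm, counting_model, seg_model = NULL, seg = NULL,
                            working_px = 2048, tile_px = 512, overlap = 0.25,
                            ...) {
  stopifnot(inherits(fm, "flatmount"))
  if (is.null(seg) && !is.null(seg_model))
    seg <- segment_retina(fm, seg_model, working_px, tile_px, overlap)
  cells <- detect_cells(fm, counting_model, ...)
  flagged <- FALSE
  if (!is.null(seg)) {
    if (seg$empty) {
      flagged <- TRUE
      area <- NA_real_
      density <- NA_real_
    } else {
      cells <- filter_by_retina(cells, seg)
      area <- seg$area_mm2
      density <- cells$count / area
    }
  } else {
    area <- NA_real_
    density <- NA_real_
  }
  structure(list(retina_id = fm$id, count = cells$count, area_mm2 = area,
                 density = density, cells = cells, segmentation = seg,
                 flagged = flagged),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Retina '%s': %d cells, %s mm2, %s cells/mm2%s\n", x$retina_id,
              x$count,
              ifelse(is.na(x$area_mm2), "NA", sprintf("%.3f", x$area_mm2)),
              ifelse(is.na(x$density), "NA", sprintf("%.0f", x$density)),
              if (x$flagged) " [flagged: empty segmentation]" else ""))
  invisible(x)
}

#' Isodensity map by Gaussian kernel density estimation
#'
#' A bivariate Gaussian KDE over the detected cell centroids (bandwidth in
#' um, default 150) is evaluated on a regular grid and multiplied by the
#' total cell count, giving true local densities in cells/mm2. Grid cells
#' outside the retina are set `NA` when a segmentation is supplied and
#' `mask = TRUE`.
#'
#' @param cells a `detected_cells`.
#' @param seg optional `retina_segmentation` used for masking.
#' @param pixel_scale pixels per um of the source image.
#' @param bandwidth_um Gaussian kernel bandwidth (sigma) in um.
#' @param grid_spacing_um grid spacing in um (map resolution).
#' @param pad_um grid margin beyond the centroid bounding box; the default
#'   (4 bandwidths) makes the unmasked map carry the full kernel mass.
#' @param mask mask grid points outside the retina?
#' @return an object of class `density_map`: `grid` (cells/mm2; rows = y),
#'   `x_um`, `y_um` grid coordinates, `grid_spacing_um`, `bandwidth_um`,
#'   `count`.
#' @export
isodensity_map <- function(cells, seg = NULL, pixel_scale = 2.17,
                           bandwidth_um = 150, grid_spacing_um = 50,
                           pad_um = 4 * bandwidth_um, mask = !is.null(seg)) {
  stopifnot(inherits(cells, "detected_cells"))
  comp <- cells$components
  n <- cells$count
  if (n == 0) {
    g <- matrix(0, 1, 1)
    return(structure(list(grid = g, x_um = 0, y_um = 0,
                          grid_spacing_um = grid_spacing_um,
                          bandwidth_um = bandwidth_um, count = 0L),
                     class = "density_map"))
  }
  x <- comp$x_px / pixel_scale
  y <- comp$y_px / pixel_scale
  h <- bandwidth_um
  gx <- seq(min(x) - pad_um, max(x) + pad_um, by = grid_spacing_um)
  gy <- seq(min(y) - pad_um, max(y) + pad_um, by = grid_spacing_um)
  ## separable Gaussian: grid = Ay %*% t(Ax) summed over cells via the
  ## matrix product of the per-axis kernel factor matrices
  Ax <- exp(-0.5 * (outer(gx, x, "-") / h)^2) # |gx| x n
  Ay <- exp(-0.5 * (outer(gy, y, "-") / h)^2) # |gy| x n
  grid <- (Ay %*% t(Ax)) / (2 * pi * h^2) # per-um2 kernel sum (= pdf * n)
  grid <- grid * 1e6 # cells/mm2
  if (mask && !is.null(seg) && !seg$empty) {
    mh <- nrow(seg$mask)
    mw <- ncol(seg$mask)
    px_per_work <- seg$downscale_factor
    r <- floor(outer(gy, rep(1, length(gx))) * pixel_scale / px_per_work[1]) + 1
    cc <- floor(outer(rep(1, length(gy)), gx) * pixel_scale / px_per_work[2]) + 1
    inside <- r >= 1 & r <= mh & cc >= 1 & cc <= mw
    vals <- matrix(FALSE, length(gy), length(gx))
    vals[inside] <- seg$mask[cbind(r[inside], cc[inside])] > 0
    grid[!vals] <- NA_real_
  }
  structure(list(grid = grid, x_um = gx, y_um = gy,
                 grid_spacing_um = grid_spacing_um, bandwidth_um = h,
                 count = n),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Isodensity map: %d x %d grid at %g um, bandwidth %g um, %d cells\n",
              nrow(x$grid), ncol(x$grid), x$grid_spacing_um, x$bandwidth_um,
              x$count))
  invisible(x)
}

## Total mass of an (unmasked) density map in cells.
density_map_mass <- function(dm) {
  sum(dm$grid, na.rm = TRUE) * dm$grid_spacing_um^2 / 1e6
}

#' Render an overlay image of detections and segmentation contour
#'
#' @param fm a [flatmount()].
#' @param cells optional `detected_cells`; centroids drawn as crosses.
#' @param seg optional `retina_segmentation`; contour drawn.
#' @param marker_px half-size of the centroid crosses.
#' @return (h, w, 3) RGB array in \[0, 1\].
#' @export
render_overlay <- function(fm, cells = NULL, seg = NULL, marker_px = 4) {
  img <- clamp01(fm$image)
  h <- nrow(img); w <- ncol(img)
  rgb <- array(rep(img, 3), c(h, w, 3))
  if (!is.null(seg) && !seg$empty) {
    m <- EBImage::Image(t(seg$mask))
    contour <- seg$mask - t(EBImage::imageData(
      EBImage::erode(m, EBImage::makeBrush(3, "box"))))
    big <- resize_matrix(contour, h, w, binary = TRUE)
    sel <- big > 0
    rgb[, , 1][sel] <- 0; rgb[, , 2][sel] <- 1; rgb[, , 3][sel] <- 0
  }
  if (!is.null(cells) && cells$count > 0) {
    for (i in seq_len(cells$count)) {
      cx <- round(cells$components$x_px[i]) + 1
      cy <- round(cells$components$y_px[i]) + 1
      xs <- max(1, cx - marker_px):min(w, cx + marker_px)
      ys <- max(1, cy - marker_px):min(h, cy + marker_px)
      rgb[cy, xs, 1] <- 1; rgb[cy, xs, 2] <- 0; rgb[cy, xs, 3] <- 0
      rgb[ys, cx, 1] <- 1; rgb[ys, cx, 2] <- 0; rgb[ys, cx, 3] <- 0
    }
  }
  rgb
}
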