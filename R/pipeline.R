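## Training-data pipeline: counting-rule filtering, point->mask targets,
## sub-frame cropping/rescaling, augmentation and train/validation splits.

#' Apply the manual counting rules to candidate cells
#'
#' Retains only candidates a trained counter would annotate: (i) boundary
#' cells with more than half the soma visible, (ii) cells at least 9 um in
#' diameter, (iii) cells that are not very weakly stained (below a fraction of
#' the frame's 99th-percentile intensity).
#'
#' @param candidates data.frame with columns `x_px`, `y_px`, `diameter_um`,
#'   `visible_fraction` (in \[0,1\]) and `intensity`.
#' @param pixel_scale pixels per um (kept with the annotations).
#' @param frame_shape (h, w) of the frame in pixels.
#' @param min_diameter_um minimum soma diameter counted (default 9 um).
#' @param weak_stain_fraction threshold for rule (iii): candidates with
#'   intensity below this fraction of the 99th percentile of candidate
#'   intensities are dropped.
#' @return a `point_annotations` object: data.frame of retained points with
#'   attributes `frame_shape` and `pixel_scale`.
#' @export
apply_counting_rules <- function(candidates, pixel_scale = 2.17,
                                 frame_shape = NULL,
                                 min_diameter_um = 9,
                                 weak_stain_fraction = 0.1) {
  need <- c("x_px", "y_px", "diameter_um", "visible_fraction", "intensity")
  stopifnot(all(need %in% names(candidates)))
  stopifnot(all(candidates$visible_fraction >= 0 & candidates$visible_fraction <= 1))
  thr <- if (nrow(candidates) > 0)
    weak_stain_fraction * stats::quantile(candidates$intensity, 0.99, names = FALSE)
  else 0
  keep <- candidates$visible_fraction > 0.5 &
    candidates$diameter_um >= min_diameter_um &
    candidates$intensity >= thr
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, frame_shape = frame_shape, pixel_scale = pixel_scale,
            class = c("point_annotations", "data.frame"))
}

#' Rasterize point annotations into a binary training mask
#'
#' The mask is the union of discs of `radius_px` centred at each point
#' (pixel centres at integer coordinates, 0-based), clipped to the frame.
#'
#' @param points data.frame with `x_px`, `y_px` (0-based, x = column).
#' @param shape (h, w) of the mask in pixels.
#' @param radius_px disc radius in pixels (>= 1).
#' @return integer matrix in \{0, 1\}.
#' @export
points_to_mask <- function(points, shape, radius_px = 4) {
  stopifnot(radius_px >= 1, length(shape) == 2)
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0L, h, w)
  if (is.null(points) || nrow(points) == 0) return(mask)
  r <- radius_px
  off <- -ceiling(r):ceiling(r)
  for (i in seq_len(nrow(points))) {
    cx <- round(points$x_px[i]); cy <- round(points$y_px[i])
    xs <- cx + off; ys <- cy + off
    keep_x <- xs >= 0 & xs < w; keep_y <- ys >= 0 & ys < h
    if (!any(keep_x) || !any(keep_y)) next
    dx <- matrix(xs[keep_x] - points$x_px[i], sum(keep_y), sum(keep_x), byrow = TRUE)
    dy <- matrix(ys[keep_y] - points$y_px[i], sum(keep_y), sum(keep_x))
    disc <- (dx^2 + dy^2 <= r^2) * 1L
    sub <- mask[ys[keep_y] + 1L, xs[keep_x] + 1L, drop = FALSE]
    mask[ys[keep_y] + 1L, xs[keep_x] + 1L] <- pmax(sub, disc)
  }
  mask
}

#' Crop a frame into a grid of sub-frames and optionally rescale
#'
#' Splits an (image, mask) pair into a non-overlapping grid of square crops of
#' `crop_px` and rescales each by `rescale` (bilinear for the image, nearest
#' neighbour for the mask). The counting path crops 768-px frames into nine
#' 256-px sub-frames rescaled to half size (128 px); the segmentation path
#' crops 2048-px images into sixteen 512-px sub-frames with no rescale.
#'
#' @param image numeric matrix (intensities in \[0,1\]).
#' @param mask integer matrix of the same shape (binary target), or `NULL`.
#' @param crop_px crop side; must divide both image dimensions.
#' @param rescale scale factor applied after cropping (default 1).
#' @return list of `training_pair`s: lists with `image` and `target`.
#' @export
crop_subframes <- function(image, mask = NULL, crop_px, rescale = 1) {
  h <- nrow(image); w <- ncol(image)
  if (h %% crop_px != 0 || w %% crop_px != 0)
    stop("image side not divisible by crop_px")
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(image)))
  out_px <- round(crop_px * rescale)
  pairs <- list()
  for (r0 in seq(0, h - crop_px, by = crop_px)) {
    for (c0 in seq(0, w - crop_px, by = crop_px)) {
      im <- image[(r0 + 1):(r0 + crop_px), (c0 + 1):(c0 + crop_px)]
      tg <- if (!is.null(mask))
        mask[(r0 + 1):(r0 + crop_px), (c0 + 1):(c0 + crop_px)]
      if (rescale != 1) {
        im <- resize_matrix(im, out_px, out_px)
        if (!is.null(tg)) {
          tg <- resize_matrix(tg, out_px, out_px, binary = TRUE)
          storage.mode(tg) <- "integer"
        }
      }
      pairs[[length(pairs) + 1L]] <-
        structure(list(image = im, target = tg), class = "training_pair")
    }
  }
  pairs
}

#' Augment a training pair
#'
#' Applies an identical random geometric transform (x/y shifts, flips,
#' rotations by multiples of 90 degrees, optional small-angle rotation and
#' shear) to image and target, and a multiplicative brightness factor to the
#' image only. Deterministic given `seed`.
#'
#' @param pair a `training_pair` (image + binary target).
#' @param params list of ranges: `shift_px` (max |shift| per axis, default 0),
#'   `flip` (logical: random horizontal/vertical flips), `rot90` (logical:
#'   random rotation by 0/90/180/270), `angle_max` (max small-angle rotation,
#'   degrees), `shear_max` (max shear angle, degrees; capped at
#'   `max_shear_deg`), `brightness` (length-2 multiplicative range).
#' @param seed RNG seed (`NULL` = use current stream).
#' @param max_shear_deg hard cap on shear (default 20 degrees).
#' @return augmented `training_pair`.
#' @export
augment_pair <- function(pair, params = list(), seed = NULL,
                         max_shear_deg = 20) {
  p <- modifyList(list(shift_px = 0, flip = FALSE, rot90 = FALSE,
                       angle_max = 0, shear_max = 0,
                       brightness = c(1, 1)), params)
  if (p$shear_max > max_shear_deg)
    stop("shear_max exceeds the configured maximum of ", max_shear_deg, " degrees")
  with_seed(seed, {
    img <- pair$image; tgt <- pair$target
    if (p$shift_px > 0) {
      dx <- sample(-p$shift_px:p$shift_px, 1)
      dy <- sample(-p$shift_px:p$shift_px, 1)
      img <- shift_matrix(img, dy, dx)
      if (!is.null(tgt)) tgt <- shift_matrix(tgt, dy, dx)
    }
    if (isTRUE(p$flip)) {
      if (runif(1) < 0.5) { img <- img[, ncol(img):1]; if (!is.null(tgt)) tgt <- tgt[, ncol(tgt):1] }
      if (runif(1) < 0.5) { img <- img[nrow(img):1, ]; if (!is.null(tgt)) tgt <- tgt[nrow(tgt):1, ] }
    }
    if (isTRUE(p$rot90)) {
      k <- sample(0:3, 1)
      img <- rot90_matrix(img, k)
      if (!is.null(tgt)) tgt <- rot90_matrix(tgt, k)
    }
    if (p$angle_max > 0) {
      ang <- runif(1, -p$angle_max, p$angle_max)
      img <- rotate_free(img, ang, binary = FALSE)
      if (!is.null(tgt)) tgt <- rotate_free(tgt, ang, binary = TRUE)
    }
    if (p$shear_max > 0) {
      sh <- runif(1, -p$shear_max, p$shear_max)
      img <- shear_matrix(img, sh, binary = FALSE)
      if (!is.null(tgt)) tgt <- shear_matrix(tgt, sh, binary = TRUE)
    }
    if (!all(p$brightness == 1)) {
      f <- runif(1, p$brightness[1], p$brightness[2])
      img <- clamp01(img * f)
    }
    if (!is.null(tgt)) storage.mode(tgt) <- "integer"
    structure(list(image = img, target = tgt), class = "training_pair")
  })
}

shift_matrix <- function(x, dy, dx) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w); storage.mode(out) <- storage.mode(x)
  src_r <- max(1, 1 - dy):min(h, h - dy)
  src_c <- max(1, 1 - dx):min(w, w - dx)
  out[src_r + dy, src_c + dx] <- x[src_r, src_c]
  out
}

rot90_matrix <- function(x, k) {
  k <- k %% 4
  for (i in seq_len(k)) x <- t(x[nrow(x):1, , drop = FALSE]) # 90 deg clockwise
  x
}

rotate_free <- function(x, angle_deg, binary = FALSE) {
  filt <- if (binary) "none" else "bilinear"
  img <- EBImage::Image(t(as.matrix(x)))
  out <- EBImage::rotate(img, angle_deg, filter = filt,
                         output.dim = rev(dim(x)), bg.col = 0)
  m <- t(EBImage::imageData(out))
  if (binary) storage.mode(m) <- "integer"
  m
}

shear_matrix <- function(x, shear_deg, binary = FALSE) {
  filt <- if (binary) "none" else "bilinear"
  m <- matrix(c(1, 0, tan(shear_deg * pi / 180), 1, 0, 0), 3, 2)
  img <- EBImage::Image(t(as.matrix(x)))
  out <- EBImage::affine(img, m, filter = filt, output.dim = rev(dim(x)),
                         bg.col = 0)
  r <- t(EBImage::imageData(out))
  if (binary) storage.mode(r) <- "integer"
  r
}

#' Split training pairs into train and validation sets
#'
#' Disjoint, exhaustive, shuffled split; deterministic given `seed`. The
#' counting model uses a 50/50 split (to represent edge cases equally in both
#' sets), the segmentation model 75/25.
#'
#' @param pairs list of training pairs.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `train` and `val` lists.
#' @export
split_train_val <- function(pairs, fraction = 0.5, seed = 1L) {
  n <- length(pairs)
  if (n < 2) stop("need at least 2 pairs to split")
  stopifnot(fraction > 0, fraction < 1)
  n_train <- min(max(round(n * fraction), 1L), n - 1L)
  with_seed(seed, {
    idx <- sample.int(n)
    list(train = pairs[idx[seq_len(n_train)]],
         val = pairs[idx[(n_train + 1):n]])
  })
}

#' Build counting training pairs from annotated frames
#'
#' Convenience composition of the counting-model data path: per-frame min-max
#' intensity normalisation, point->disc target at full frame resolution
#' (radius `2 * radius_px` so the rescaled target has radius `radius_px`),
#' cropping into `crop_px` sub-frames and rescaling to half size.
#'
#' @param frames list of frames (`image`, `points`) as from [sample_frames()].
#' @param crop_px crop side at frame resolution (default 256).
#' @param rescale scale factor (default 0.5).
#' @param radius_px target disc radius at the rescaled resolution (default 4).
#' @return list of `training_pair`s at the model input resolution.
#' @export
make_training_pairs <- function(frames, crop_px = 256, rescale = 0.5,
                                radius_px = 4) {
  out <- list()
  for (fr in frames) {
    img <- normalize_frame(fr$image)
    mask <- points_to_mask(fr$points, dim(img), radius_px / rescale)
    out <- c(out, crop_subframes(img, mask, crop_px, rescale))
  }
  out
}

## Per-frame min-max normalisation to [0,1]; constant frames map to 0.
normalize_frame <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' Write training pairs to an image-pair directory
#'
#' Each pair becomes `<stem>_NNN.tif` (image) and `<stem>_NNN_mask.tif`
#' (binary target), the layout consumed by the training entry points.
#'
#' @param pairs list of `training_pair`s.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return invisibly, the image paths.
#' @export
write_training_pairs <- function(pairs, dir, stem = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(pairs))
  for (i in seq_along(pairs)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.tif", stem, i))
    write_image(pairs[[i]]$image, paths[i])
    if (!is.null(pairs[[i]]$target))
      write_image(pairs[[i]]$target,
                  file.path(dir, sprintf("%s_%03d_mask.tif", stem, i)))
  }
  invisible(paths)
}
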