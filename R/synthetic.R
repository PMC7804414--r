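## Synthetic flatmount generator.
##
## Emulates the statistical structure of RBPMS-style flatmount mosaics with
## exact ground truth: a clover-shaped retina silhouette (relief-cut lobes),
## cytoplasmically labelled somata rendered as soft-edged anisotropic Gaussian
## blobs, a central-to-peripheral density gradient, injury-induced density
## reduction, multiplicative staining/brightness heterogeneity and sensor
## noise. Every quantity downstream of the generator (cell centres, retina
## mask, area) is known exactly, so the whole pipeline is trainable and
## testable without real data.

#' Specification of a synthetic flatmount
#'
#' Default values are the study conditions the generator emulates: naive mean
#' density ~3,000 cells/mm2, soma diameters 10-35 um, epifluorescence pixel
#' scale 2.17 px/um, a four-lobed flatmount silhouette whose default radius
#' gives ~14 mm2 of retina, and a 2:1 central-to-peripheral density gradient.
#'
#' @param mean_density mean cell density over the retina, cells/mm2.
#' @param gradient_ratio centre-to-periphery density ratio (>= 1); the radial
#'   intensity falls off linearly from the centre and is normalised so the
#'   spatial mean equals `mean_density`.
#' @param injury_factor multiplicative survival fraction in \[0, 1\]; 1 =
#'   naive, 0.4 emulates severe (crush-like) loss, 0 = no cells.
#' @param soma_diameter_range (min, max) soma diameter in um.
#' @param retina_radius nominal silhouette radius in um (before lobing).
#' @param n_lobes number of relief-cut lobes of the silhouette.
#' @param lobe_depth relative amplitude of the lobe modulation.
#' @param pixel_scale pixels per um.
#' @param background_level,noise_sd,brightness_field_amplitude intensity
#'   parameters in \[0, 1\]: constant off-tissue background (glass/mounting
#'   medium plus camera offset), Gaussian pixel noise SD, and amplitude of
#'   the smooth multiplicative staining-heterogeneity field.
#' @param tissue_level tissue autofluorescence added inside the silhouette:
#'   flatmounted tissue is visibly brighter than the surrounding glass even
#'   where no labelled soma sits.
#' @param min_distance_factor hard-core inhibition distance as a fraction of
#'   the mean soma diameter (centres closer than this are not placed, but
#'   rendered somata may still overlap).
#' @param soma_intensity_range (min, max) of the per-cell peak intensity
#'   jitter. The default emulates moderately heterogeneous immunostaining; a
#'   wider range reaching much lower values emulates retrograde-tracer
#'   labelling with both bright and very faint cells.
#' @param seed integer seed making generation fully reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mean_density = 3000,
                           gradient_ratio = 2,
                           injury_factor = 1,
                           soma_diameter_range = c(10, 35),
                           retina_radius = 2060,
                           n_lobes = 4,
                           lobe_depth = 0.12,
                           pixel_scale = 2.17,
                           background_level = 0.05,
                           tissue_level = 0.06,
                           noise_sd = 0.02,
                           brightness_field_amplitude = 0.15,
                           min_distance_factor = 0.5,
                           soma_intensity_range = c(0.55, 1),
                           seed = 1L) {
  spec <- list(
    mean_density = mean_density, gradient_ratio = gradient_ratio,
    injury_factor = injury_factor,
    soma_diameter_range = as.numeric(soma_diameter_range),
    retina_radius = retina_radius, n_lobes = as.integer(n_lobes),
    lobe_depth = lobe_depth, pixel_scale = pixel_scale,
    background_level = background_level, tissue_level = tissue_level,
    noise_sd = noise_sd,
    brightness_field_amplitude = brightness_field_amplitude,
    min_distance_factor = min_distance_factor,
    soma_intensity_range = as.numeric(soma_intensity_range),
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (mean_density <= 0) stop("mean_density must be positive")
    if (pixel_scale <= 0) stop("pixel_scale must be positive")
    if (injury_factor < 0 || injury_factor > 1)
      stop("injury_factor must lie in [0, 1]")
    if (gradient_ratio < 1) stop("gradient_ratio must be >= 1")
    if (length(soma_diameter_range) != 2 ||
        soma_diameter_range[1] <= 0 ||
        soma_diameter_range[1] > soma_diameter_range[2])
      stop("soma_diameter_range must be an increasing positive pair")
    if (retina_radius <= 0) stop("retina_radius must be positive")
    if (lobe_depth < 0 || lobe_depth >= 1) stop("lobe_depth must be in [0, 1)")
    if (tissue_level < 0 || tissue_level > 1)
      stop("tissue_level must be in [0, 1]")
    if (length(soma_intensity_range) != 2 ||
        soma_intensity_range[1] <= 0 ||
        soma_intensity_range[1] > soma_intensity_range[2] ||
        soma_intensity_range[2] > 1)
      stop("soma_intensity_range must be an increasing pair in (0, 1]")
  })
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic flatmount spec:\n")
  cat(sprintf("  density %g cells/mm2 x injury %g, gradient ratio %g\n",
              x$mean_density, x$injury_factor, x$gradient_ratio))
  cat(sprintf("  soma %g-%g um, radius %g um (%d lobes), %g px/um, seed %d\n",
              x$soma_diameter_range[1], x$soma_diameter_range[2],
              x$retina_radius, x$n_lobes, x$pixel_scale, x$seed))
  invisible(x)
}

## Boundary radius of the lobed silhouette at polar angle theta (um).
silhouette_radius <- function(spec, theta) {
  spec$retina_radius * (1 + spec$lobe_depth * cos(spec$n_lobes * theta))
}

## Normalised radial density profile: linear falloff from `gradient_ratio` at
## the centre to 1 at the boundary, scaled so its area average over the
## silhouette is exactly 1 (u = radial fraction of the local boundary radius).
gradient_profile <- function(spec, u) {
  g <- spec$gradient_ratio
  (g - (g - 1) * u) * 3 / (g + 2)
}

#' Generate a synthetic retina flatmount
#'
#' Cells are placed by an inhomogeneous spatial point process (target count
#' Poisson with mean `density x area x injury_factor`, positions by rejection
#' sampling from the radial gradient, with hard-core inhibition at
#' `min_distance_factor x mean soma diameter`; each soma lies fully inside
#' the tissue silhouette), rendered as anisotropic
#' Gaussian blobs clipped at two sigma with per-cell intensity jitter, then
#' modulated by a smooth brightness field and Gaussian noise. Fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param render render the image? `FALSE` skips soma rendering, brightness
#'   field and noise (the image is left blank), which is useful for fast
#'   point-process checks; mask, centres and area are unaffected.
#' @return an object of class `synthetic_retina`: list with `image` (matrix in
#'   \[0,1\], row = y), `mask` (integer matrix, ground-truth silhouette),
#'   `centres` (data.frame `x_px`, `y_px`, 0-based, x = column; plus
#'   `diameter_um`, `intensity`), `area_mm2`, `pixel_scale`, `spec`.
#' @export
generate_retina <- function(spec, render = TRUE) {
  validate_spec(spec)
  with_seed(spec$seed, {
    ps <- spec$pixel_scale
    rmax_um <- spec$retina_radius * (1 + spec$lobe_depth)
    pad_um <- 50
    half_px <- ceiling((rmax_um + pad_um) * ps)
    n <- 2L * half_px + 1L
    c0 <- half_px + 1L # centre pixel (1-based row/col)

    ## ground-truth mask from the analytic silhouette
    d_px <- seq_len(n) - c0
    dx <- matrix(d_px, n, n, byrow = TRUE)
    dy <- matrix(d_px, n, n)
    r_um <- sqrt(dx^2 + dy^2) / ps
    theta <- atan2(dy, dx)
    mask <- (r_um <= silhouette_radius(spec, theta)) * 1L
    storage.mode(mask) <- "integer"
    area_mm2 <- sum(mask) / ps^2 / 1e6

    ## cell centres (um coordinates relative to centre)
    pts <- place_cells(spec, area_mm2)

    if (render) {
      ## render somata, then brightness heterogeneity + background + noise
      img <- render_cells(spec, pts, n, c0)
      if (spec$brightness_field_amplitude > 0) {
        coarse <- matrix(runif(64, -1, 1), 8, 8)
        field <- 1 + spec$brightness_field_amplitude * resize_matrix(coarse, n, n)
      } else {
        field <- 1
      }
      img <- (spec$background_level + spec$tissue_level * mask + img) * field
      if (spec$noise_sd > 0) img <- img + rnorm(n * n, sd = spec$noise_sd)
      img <- clamp01(img)
    } else {
      img <- matrix(0, n, n)
    }

    centres <- data.frame(
      x_px = pts$x * ps + (c0 - 1), # 0-based pixel coordinates
      y_px = pts$y * ps + (c0 - 1),
      diameter_um = pts$diameter,
      intensity = pts$intensity
    )
    structure(
      list(image = img, mask = mask, centres = centres, area_mm2 = area_mm2,
           pixel_scale = ps, spec = spec),
      class = "synthetic_retina"
    )
  })
}

#' @export
print.synthetic_retina <- function(x, ...) {
  cat(sprintf("Synthetic retina: %d x %d px, %.3f mm2, %d cells (%.0f cells/mm2)\n",
              nrow(x$image), ncol(x$image), x$area_mm2, nrow(x$centres),
              nrow(x$centres) / x$area_mm2))
  invisible(x)
}

## Inhomogeneous hard-core point process inside the silhouette.
## Returns data.frame x, y (um, centred), diameter, intensity, aspect, angle.
place_cells <- function(spec, area_mm2) {
  lambda <- spec$mean_density * spec$injury_factor * area_mm2
  n_target <- rpois(1, lambda)
  empty <- data.frame(x = numeric(0), y = numeric(0), diameter = numeric(0),
                      intensity = numeric(0), aspect = numeric(0),
                      angle = numeric(0))
  if (n_target == 0) return(empty)

  rmax <- spec$retina_radius * (1 + spec$lobe_depth)
  dmin <- spec$min_distance_factor * mean(spec$soma_diameter_range)
  gmax <- gradient_profile(spec, 0)

  ## grid hash for the hard-core check
  cell <- max(dmin, 1e-6)
  ng <- ceiling(2 * rmax / cell) + 2L
  grid <- vector("list", ng * ng)
  gidx <- function(x, y) {
    gi <- floor((x + rmax) / cell) + 2L
    gj <- floor((y + rmax) / cell) + 2L
    (gj - 1L) * ng + gi
  }

  xs <- ys <- ds <- numeric(n_target)
  accepted <- 0L
  max_batches <- 200L
  for (b in seq_len(max_batches)) {
    m <- max(2L * (n_target - accepted), 200L)
    px <- runif(m, -rmax, rmax)
    py <- runif(m, -rmax, rmax)
    pd <- runif(m, spec$soma_diameter_range[1], spec$soma_diameter_range[2])
    r <- sqrt(px^2 + py^2)
    bnd <- silhouette_radius(spec, atan2(py, px))
    ## the whole soma must lie inside the tissue silhouette
    keep <- r <= bnd - pd / 2
    ## gradient thinning
    u <- ifelse(bnd > 0, pmin(r / bnd, 1), 0)
    keep <- keep & (runif(m) < gradient_profile(spec, u) / gmax)
    px <- px[keep]; py <- py[keep]; pd <- pd[keep]
    for (i in seq_along(px)) {
      gi <- floor((px[i] + rmax) / cell) + 2L
      gj <- floor((py[i] + rmax) / cell) + 2L
      ok <- TRUE
      for (dj in -1L:1L) {
        for (di in -1L:1L) {
          nb <- grid[[(gj + dj - 1L) * ng + gi + di]]
          if (!is.null(nb) &&
              any((xs[nb] - px[i])^2 + (ys[nb] - py[i])^2 < dmin^2)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        accepted <- accepted + 1L
        xs[accepted] <- px[i]; ys[accepted] <- py[i]; ds[accepted] <- pd[i]
        k <- (gj - 1L) * ng + gi
        grid[[k]] <- c(grid[[k]], accepted)
        if (accepted == n_target) break
      }
    }
    if (accepted == n_target) break
  }
  if (accepted < n_target)
    warning(sprintf("hard-core packing saturated: placed %d of %d cells",
                    accepted, n_target))
  nc <- accepted
  if (nc == 0) return(empty)
  data.frame(
    x = xs[seq_len(nc)], y = ys[seq_len(nc)], diameter = ds[seq_len(nc)],
    intensity = runif(nc, spec$soma_intensity_range[1],
                      spec$soma_intensity_range[2]),
    aspect = runif(nc, 0.8, 1.25),
    angle = runif(nc, 0, pi)
  )
}

## Render somata as anisotropic Gaussian blobs clipped at 2 sigma.
render_cells <- function(spec, pts, n, c0) {
  img <- matrix(0, n, n)
  if (nrow(pts) == 0) return(img)
  ps <- spec$pixel_scale
  for (i in seq_len(nrow(pts))) {
    sig <- pts$diameter[i] / 4 # um; 2*sigma = soma radius
    sx <- sig * sqrt(pts$aspect[i]) * ps
    sy <- sig / sqrt(pts$aspect[i]) * ps
    cx <- pts$x[i] * ps + c0 # 1-based fractional pixel centre (column)
    cy <- pts$y[i] * ps + c0
    hs <- ceiling(2 * max(sx, sy)) + 1L
    xr <- max(1L, floor(cx) - hs):min(n, floor(cx) + hs)
    yr <- max(1L, floor(cy) - hs):min(n, floor(cy) + hs)
    if (length(xr) == 0 || length(yr) == 0) next
    lx <- matrix(xr - cx, length(yr), length(xr), byrow = TRUE)
    ly <- matrix(yr - cy, length(yr), length(xr))
    ca <- cos(pts$angle[i]); sa <- sin(pts$angle[i])
    xrr <- lx * ca + ly * sa
    yrr <- -lx * sa + ly * ca
    q <- (xrr / sx)^2 + (yrr / sy)^2
    blob <- pts$intensity[i] * exp(-0.5 * q)
    blob[q > 4] <- 0 # clip at 2 sigma
    img[yr, xr] <- img[yr, xr] + blob
  }
  img
}

#' Non-overlapping frame partition of a retina image
#'
#' Tiles the whole image into a non-overlapping grid of frames (edge frames
#' may be smaller), each carrying the ground-truth centres that fall inside
#' it, re-expressed in frame coordinates. The frames partition the plane, so
#' the union of their annotations is exactly the retina's centre list.
#'
#' @param retina a `synthetic_retina`.
#' @param frame_px frame side in pixels.
#' @return list of frames: `image`, `points` (x_px, y_px, 0-based), `origin`
#'   (0-based row/col of the frame's top-left pixel).
#' @export
frame_grid <- function(retina, frame_px) {
  h <- nrow(retina$image); w <- ncol(retina$image)
  stopifnot(frame_px >= 1)
  frames <- list()
  for (r0 in seq(0L, h - 1L, by = frame_px)) {
    for (c0 in seq(0L, w - 1L, by = frame_px)) {
      hh <- min(frame_px, h - r0); ww <- min(frame_px, w - c0)
      frames[[length(frames) + 1L]] <-
        extract_frame(retina, r0, c0, hh, ww)
    }
  }
  frames
}

extract_frame <- function(retina, r0, c0, h, w) {
  img <- retina$image[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), drop = FALSE]
  cen <- retina$centres
  ## pixel-centre convention: a centre at coordinate x belongs to the frame
  ## when it rounds into its pixel range
  inside <- cen$x_px >= c0 - 0.5 & cen$x_px < c0 + w - 0.5 &
    cen$y_px >= r0 - 0.5 & cen$y_px < r0 + h - 0.5
  pts <- cen[inside, , drop = FALSE]
  pts$x_px <- pts$x_px - c0
  pts$y_px <- pts$y_px - r0
  rownames(pts) <- NULL
  list(image = img, points = pts, origin = c(row = r0, col = c0))
}

#' Sample annotation frames from predefined radial regions
#'
#' Frames are drawn at random positions whose centre falls in radial bands
#' around the mask centroid, mirroring region-stratified frame sampling over
#' optic-nerve-head, central, mid-peripheral, peripheral and border regions.
#' Border-region frames may lie partly or fully outside the retina and can
#' carry zero annotations.
#'
#' @param retina a `synthetic_retina`.
#' @param frame_px frame side in pixels; must fit inside the image.
#' @param regions character vector of region labels among `"onh"`,
#'   `"central"`, `"mid_peripheral"`, `"peripheral"`, `"border"`.
#' @param n_per_region frames per region.
#' @param seed RNG seed.
#' @return list of frames as in [frame_grid()], each with a `region` field.
#' @export
sample_frames <- function(retina, frame_px,
                          regions = c("onh", "central", "mid_peripheral",
                                      "peripheral", "border"),
                          n_per_region = 1, seed = 1L) {
  h <- nrow(retina$image); w <- ncol(retina$image)
  if (frame_px > h || frame_px > w)
    stop("frame_px larger than the retina image")
  bands <- list(onh = c(0, 0.15), central = c(0.15, 0.45),
                mid_peripheral = c(0.45, 0.7), peripheral = c(0.7, 0.95),
                border = c(0.95, 1.15))
  regions <- match.arg(regions, names(bands), several.ok = TRUE)
  idx <- which(retina$mask > 0)
  cy <- mean((idx - 1) %% h); cx <- mean((idx - 1) %/% h)
  rmax <- sqrt(max(((idx - 1) %% h - cy)^2 + ((idx - 1) %/% h - cx)^2))
  with_seed(seed, {
    out <- list()
    for (reg in regions) {
      band <- bands[[reg]]
      got <- 0L
      tries <- 0L
      while (got < n_per_region && tries < 20000L) {
        tries <- tries + 1L
        r0 <- floor(runif(1, 0, h - frame_px + 1))
        c0 <- floor(runif(1, 0, w - frame_px + 1))
        fc_r <- sqrt((r0 + frame_px / 2 - cy)^2 + (c0 + frame_px / 2 - cx)^2) / rmax
        if (fc_r >= band[1] && fc_r < band[2]) {
          fr <- extract_frame(retina, r0, c0, frame_px, frame_px)
          fr$region <- reg
          out[[length(out) + 1L]] <- fr
          got <- got + 1L
        }
      }
      if (got < n_per_region)
        warning("could not place ", n_per_region, " frames in region ", reg)
    }
    out
  })
}

#' Write a synthetic retina to disk
#'
#' Writes the image and mask as TIFF, the centre list as CSV (`x_px`, `y_px`,
#' 0-based, x = column) and the generating spec as YAML.
#'
#' @param retina a `synthetic_retina`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return invisibly, the paths written.
#' @export
write_retina <- function(retina, dir, stem = "retina") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(stem, ".tif")),
    mask = file.path(dir, paste0(stem, "_mask.tif")),
    centres = file.path(dir, paste0(stem, "_centres.csv")),
    spec = file.path(dir, paste0(stem, "_spec.yml"))
  )
  write_image(retina$image, paths["image"])
  write_image(retina$mask, paths["mask"])
  write.csv(retina$centres, paths["centres"], row.names = FALSE)
  write_spec(retina$spec, paths["spec"])
  invisible(paths)
}

#' Serialize / read a synthetic spec as YAML
#' @param spec a `synthetic_spec`.
#' @param path file path.
#' @return `write_spec` returns the path invisibly; `read_spec` the spec.
#' @export
write_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  do.call(synthetic_spec, yaml::read_yaml(path))
}
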