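## Batch front end: quantify every flatmount in a folder, write the results
## table and optional per-retina artifacts (masks, overlays, coordinates,
## isodensity maps).

#' Batch run configuration
#'
#' @param input_dir folder of single-channel flatmount images (TIFF/PNG).
#' @param output_dir folder for results and artifacts (created if needed).
#' @param counting_weights path to counting-model weights
#'   ([save_weights()] checkpoint).
#' @param segmentation_weights path to segmentation-model weights, or `NULL`.
#' @param pixel_scale pixels per um (default 2.17).
#' @param skip_segmentation count only; area and density left empty.
#' @param emit_masks,emit_overlay,emit_coordinates,emit_isodensity artifact
#'   flags.
#' @param isodensity_grid_um isodensity map resolution in um.
#' @param threshold binarization threshold.
#' @param seed RNG seed (the inference path is deterministic; kept for
#'   reproducibility of any stochastic extension).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       counting_weights, segmentation_weights = NULL,
                       pixel_scale = 2.17, skip_segmentation = FALSE,
                       emit_masks = FALSE, emit_overlay = FALSE,
                       emit_coordinates = FALSE, emit_isodensity = FALSE,
                       isodensity_grid_um = 50, threshold = 0.5, seed = 1L) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  stopifnot(pixel_scale > 0)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 counting_weights = counting_weights,
                 segmentation_weights = segmentation_weights,
                 pixel_scale = pixel_scale,
                 skip_segmentation = isTRUE(skip_segmentation),
                 emit_masks = isTRUE(emit_masks),
                 emit_overlay = isTRUE(emit_overlay),
                 emit_coordinates = isTRUE(emit_coordinates),
                 emit_isodensity = isTRUE(emit_isodensity),
                 isodensity_grid_um = isodensity_grid_um,
                 threshold = threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Quantify a folder of flatmounts in batch mode
#'
#' One results row per readable image (columns `retina_id`, `count`,
#' `area_mm2`, `density`, `status`); per-image failures are logged and
#' skipped so the run continues. The table is written to
#' `output_dir/results.csv`.
#'
#' @param config a [run_config()].
#' @param models optional pre-loaded list `list(counting =, segmentation =)`
#'   overriding the weight paths.
#' @return the results data.frame, invisibly with attribute `exit_status`
#'   (0 = all ok, 1 = partial failures).
#' @export
run_batch <- function(config, models = NULL) {
  stopifnot(inherits(config, "run_config"))
  paths <- sort(list.files(config$input_dir, "\\.(tif|tiff|png)$",
                           full.names = TRUE, ignore.case = TRUE))
  ## mask artifacts from a previous run are not inputs
  paths <- paths[!grepl("_(mask|overlay)\\.", basename(paths))]
  if (length(paths) == 0) stop("no readable images in ", config$input_dir)
  counting <- if (!is.null(models)) models$counting
  else load_weights(config$counting_weights)
  seg_model <- if (config$skip_segmentation) NULL
  else if (!is.null(models)) models$segmentation
  else if (!is.null(config$segmentation_weights))
    load_weights(config$segmentation_weights)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  for (p in paths) {
    id <- tools::file_path_sans_ext(basename(p))
    res <- tryCatch({
      fm <- flatmount(p, config$pixel_scale, id)
      q <- quantify_retina(fm, counting, seg_model,
                           threshold = config$threshold)
      emit_artifacts(config, fm, q)
      data.frame(retina_id = id, count = q$count, area_mm2 = q$area_mm2,
                 density = q$density,
                 status = if (q$flagged) "flagged" else "ok")
    }, error = function(e) {
      message("skipping ", id, ": ", conditionMessage(e))
      data.frame(retina_id = id, count = NA_integer_, area_mm2 = NA_real_,
                 density = NA_real_, status = "error")
    })
    rows[[id]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$retina_id), , drop = FALSE]
  write.csv(out, file.path(config$output_dir, "results.csv"),
            row.names = FALSE)
  attr(out, "exit_status") <- if (any(out$status == "error")) 1L else 0L
  invisible(out)
}

emit_artifacts <- function(config, fm, q) {
  od <- config$output_dir
  id <- fm$id
  if (config$emit_masks && !is.null(q$segmentation) && !q$segmentation$empty)
    write_image(q$segmentation$mask, file.path(od, paste0(id, "_mask.tif")))
  if (config$emit_overlay)
    png::writePNG(render_overlay(fm, q$cells, q$segmentation),
                  file.path(od, paste0(id, "_overlay.png")))
  if (config$emit_coordinates)
    write.csv(q$cells$components[, c("x_px", "y_px")],
              file.path(od, paste0(id, "_coordinates.csv")),
              row.names = FALSE)
  if (config$emit_isodensity && q$count > 0 && !is.null(q$segmentation) &&
      !q$segmentation$empty) {
    dm <- isodensity_map(q$cells, q$segmentation, fm$pixel_scale,
                         grid_spacing_um = config$isodensity_grid_um)
    write.csv(dm$grid, file.path(od, paste0(id, "_isodensity.csv")),
              row.names = FALSE)
    g <- dm$grid
    g[is.na(g)] <- 0
    if (max(g) > 0) g <- g / max(g)
    png::writePNG(g, file.path(od, paste0(id, "_isodensity.png")))
  }
  invisible(NULL)
}
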