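## Desk-scale reference experiment: a reduced U-Net pair trained entirely on
## synthetic flatmounts, sized so the whole cycle (data generation, training,
## whole-retina inference) runs in minutes on a single CPU core. This is the
## recipe the package's validation (tests and acceptance script) runs.

#' Train the desk-scale counting and segmentation models
#'
#' Generates synthetic training retinas, builds counting-model training pairs
#' (regional 768-px frames, cropped into 256-px sub-frames rescaled to the
#' 128-px model input, disc targets of radius 4 px) and segmentation pairs
#' (whole retinas at a 512-px working resolution, cropped into 16 tiles of
#' 128 px), and trains a reduced U-Net for each task (3 levels, 16 base
#' filters for counting / 8 for segmentation, Adam at 1e-3, flip/rotation
#' augmentation on the fly). All randomness derives from `seed`.
#'
#' @param seed base seed; data generation, weight initialisation and training
#'   use fixed offsets from it.
#' @param retina_radius nominal training-retina radius in um (desk scale).
#' @param epochs_counting,epochs_segmentation training epochs.
#' @param verbose print per-epoch losses.
#' @return list with `counting` and `segmentation` (trained `unet`s) and
#'   `train_retina` (the counting-model training retina).
#' @export
desk_models <- function(seed = 1L, retina_radius = 520,
                        epochs_counting = 12, epochs_segmentation = 14,
                        verbose = FALSE) {
  seed <- as.integer(seed)
  ## counting model ----------------------------------------------------
  ret <- generate_retina(synthetic_spec(retina_radius = retina_radius,
                                        seed = seed + 100L))
  frames <- sample_frames(ret, 768, n_per_region = 1, seed = seed + 1L)
  pairs <- make_training_pairs(frames)
  sp <- split_train_val(pairs, 0.5, seed = seed + 2L)
  cnet <- build_unet(unet_config_desk(epochs = epochs_counting),
                     seed = seed + 3L)
  cnet <- train_unet(cnet, sp$train, sp$val, seed = seed + 4L,
                     augment_params = list(flip = TRUE, rot90 = TRUE),
                     verbose = verbose)

  ## segmentation model ------------------------------------------------
  seg_pairs <- list()
  for (k in 1:3) {
    r <- generate_retina(synthetic_spec(
      retina_radius = retina_radius - 50 * (k - 1),
      injury_factor = c(1, 0.6, 0.4)[k], seed = seed + 110L + k))
    img <- resize_matrix(r$image, 512, 512)
    msk <- resize_matrix(r$mask, 512, 512, binary = TRUE)
    seg_pairs <- c(seg_pairs, crop_subframes(img, msk, 128))
  }
  ssp <- split_train_val(seg_pairs, 0.75, seed = seed + 5L)
  snet <- build_unet(unet_config_desk(base_filters = 8,
                                      epochs = epochs_segmentation,
                                      steps_per_epoch = NULL),
                     seed = seed + 6L)
  snet <- train_unet(snet, ssp$train, ssp$val, seed = seed + 7L,
                     augment_params = list(flip = TRUE, rot90 = TRUE),
                     verbose = verbose)

  list(counting = cnet, segmentation = snet, train_retina = ret)
}

#' Evaluate desk-scale counting accuracy on held-out synthetic frames
#'
#' Samples annotation frames from a held-out synthetic retina, counts each
#' frame with the tiled counting pipeline, and reports the mean absolute
#' percentage error against the exact ground truth.
#'
#' @param model trained counting `unet`.
#' @param seed seed of the held-out retina (should differ from the training
#'   seed).
#' @param n_frames number of held-out frames (sampled over the non-border
#'   regions).
#' @param retina_radius held-out retina radius in um.
#' @return list with `mape` (percent), `truth` and `predicted` counts.
#' @export
desk_counting_error <- function(model, seed = 2L, n_frames = 20,
                                retina_radius = 520) {
  ret <- generate_retina(synthetic_spec(retina_radius = retina_radius,
                                        seed = as.integer(seed) + 200L))
  regions <- c("onh", "central", "mid_peripheral", "peripheral")
  frames <- sample_frames(ret, 768, regions = regions,
                          n_per_region = ceiling(n_frames / length(regions)),
                          seed = as.integer(seed) + 201L)[seq_len(n_frames)]
  truth <- vapply(frames, function(f) nrow(f$points), integer(1))
  pred <- vapply(frames, function(f)
    detect_cells(flatmount(f$image, ret$pixel_scale), model)$count,
    integer(1))
  list(mape = 100 * mean(abs(pred - truth) / truth), truth = truth,
       predicted = pred)
}

#' Evaluate desk-scale segmentation accuracy on a held-out synthetic retina
#'
#' @param model trained segmentation `unet`.
#' @param seed seed of the held-out retina.
#' @param retina_radius held-out retina radius in um.
#' @return list with `iou` against the ground-truth silhouette and the
#'   `segmentation` result.
#' @export
desk_segmentation_iou <- function(model, seed = 2L, retina_radius = 470) {
  ret <- generate_retina(synthetic_spec(retina_radius = retina_radius,
                                        seed = as.integer(seed) + 300L))
  fm <- flatmount(ret$image, ret$pixel_scale)
  seg <- segment_retina(fm, model, working_px = 512, tile_px = 128)
  truth <- resize_matrix(ret$mask, 512, 512, binary = TRUE)
  list(iou = jaccard(seg$mask, truth), segmentation = seg)
}
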