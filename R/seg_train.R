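#' Train the U-Net epithelium segmenter
#'
#' Standard supervised training: randomly initialised weights, Adam, the
#' BCE-Dice loss, minibatches of `config$batch_size` crops; the validation
#' loss is evaluated at the end of every epoch and the returned model is
#' the checkpoint with the minimum validation loss. Fully seeded: two runs
#' with the same data and config produce identical parameters.
#'
#' @param train,val lists of `list(crop = <fragment_crop or HxWx3 array>,
#'   mask = <binary matrix>)`; masks are aligned with the crops.
#' @param config a [seg_config()].
#' @param verbose print one line per epoch.
#' @return object of class `cg_seg_model` with fields `params`, `config`,
#'   `train_log` (data frame: epoch, train_loss, val_loss), `best_epoch`.
#' @export
train_segmenter <- function(train, val, config, verbose = FALSE) {
  stopifnot(length(train) >= 1, length(val) >= 1)
  prep <- function(items) lapply(items, function(it) {
    x <- to_input_channels(it$crop, config$input_mode)
    stopifnot(all(dim(x)[1:2] == dim(it$mask)))
    if (any(dim(x)[1:2] %% 2^config$depth != 0))
      stop("crop side must be divisible by 2^depth")
    list(x = x, y = (it$mask > 0) + 0)
  })
  tr <- prep(train); va <- prep(val)
  withr::with_seed(config$seed, {
    params <- cg_unet_init(config)
    opt <- cg_adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      train_dice_loss = numeric(), val_loss = numeric())
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(tr))
      ep_loss <- 0; ep_dice <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        gacc <- NULL
        for (i in bi) {
          fwd <- cg_unet_forward(params, tr[[i]]$x, keep = TRUE)
          p <- cg_sigmoid(fwd$logits)
          lt <- bce_dice_loss(p, tr[[i]]$y, config$lambda_smooth)
          if (!is.finite(lt$total))
            stop("NaN/Inf training loss at epoch ", ep,
                 " (item ", i, "); lower the learning rate")
          ep_loss <- ep_loss + lt$total; ep_dice <- ep_dice + lt$dice_loss
          g <- cg_unet_backward(params, fwd,
                                cg_bce_dice_grad(p, tr[[i]]$y,
                                                 config$lambda_smooth))
          gacc <- cg_grad_axpy(gacc, g, 1 / length(bi))
        }
        upd <- cg_adam_step(params, gacc, opt, config$learning_rate)
        params <- upd$params; opt <- upd$state
      }
      vl <- mean(vapply(va, function(it) {
        p <- cg_sigmoid(cg_unet_forward(params, it$x))
        bce_dice_loss(p, it$y, config$lambda_smooth)$total
      }, numeric(1)))
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = ep_loss / length(tr),
                                   train_dice_loss = ep_dice / length(tr),
                                   val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        ep_loss / length(tr), vl))
    }
    structure(list(params = best$params, config = config, train_log = log,
                   best_epoch = best$epoch, val_loss = best$loss),
              class = "cg_seg_model")
  })
}

#' Predict an epithelium mask for a fragment crop
#'
#' The crop is converted to the model's input channels, passed through the
#' network and thresholded. Dispatches on the model class, so a
#' ground-truth [oracle_segmenter()] can stand in for a trained model.
#'
#' @param model a `cg_seg_model` (or oracle).
#' @param crop a [fragment_crop()] or an H x W x 3 array.
#' @param threshold probability cut; `threshold = 0` marks everything
#'   foreground.
#' @return binary matrix in crop coordinates.
#' @export
predict_mask <- function(model, crop, threshold = NULL)
  UseMethod("predict_mask")

#' @export
predict_mask.cg_seg_model <- function(model, crop, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$threshold
  x <- to_input_channels(crop, model$config$input_mode)
  p <- cg_sigmoid(cg_unet_forward(model$params, x))
  (p >= threshold) + 0L
}

#' Ground-truth oracle segmenter
#'
#' Holds a level-0 reference mask (e.g. a phantom's ground truth) and
#' answers [predict_mask()] queries by nearest-neighbour sampling of that
#' mask through the crop transform. Used to evaluate the pipeline's
#' downstream stages independently of segmentation quality.
#'
#' @param mask0 level-0 binary mask.
#' @export
oracle_segmenter <- function(mask0)
  structure(list(mask0 = mask0), class = "cg_oracle_segmenter")

#' @export
predict_mask.cg_oracle_segmenter <- function(model, crop, threshold = NULL) {
  if (inherits(crop, "fragment_crop"))
    cg_mask_to_crop(model$mask0, crop)
  else
    stop("oracle segmenter needs a fragment_crop")
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the full configuration (including the seed) alongside
#' the weights and the training log.
#'
#' @param model a `cg_seg_model` or `cg_cls_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
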