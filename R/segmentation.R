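#' Segmentation model configuration
#'
#' A standard U-Net: `depth` encoder levels of double 3x3 convolutions with
#' ReLU and 2x2 max-pooling, a double-conv bottleneck, a decoder of 2x2
#' transposed convolutions with skip concatenation, and a 1x1 sigmoid head.
#' Trained with the combined binary cross-entropy + Dice loss
#' ([bce_dice_loss()]) and Adam. The defaults mirror the full-scale recipe
#' (depth 4, 64 base filters, learning rate 1e-4, batches of 4, 250
#' epochs); the reduced `depth = 2`, `base_filters = 8` configuration is
#' sized for CPU training on phantom crops.
#'
#' @param input_mode `"rgb"` (3 channels), `"gray"` or `"saturation"`
#'   (1 channel); see [to_input_channels()].
#' @param depth encoder levels.
#' @param base_filters filters at the first level (doubles per level).
#' @param lambda_smooth Dice smoothing term (rescues the empty-mask case).
#' @param learning_rate,batch_size,epochs Adam training schedule.
#' @param threshold probability cut for [predict_mask()], in (0, 1).
#' @param seed seed for weight initialisation and batch shuffling.
#' @export
seg_config <- function(input_mode = c("rgb", "gray", "saturation"),
                       depth = 4L, base_filters = 64L, lambda_smooth = 1,
                       learning_rate = 1e-4, batch_size = 4L, epochs = 250L,
                       threshold = 0.5, seed = 1L) {
  input_mode <- match.arg(input_mode)
  stopifnot(depth >= 1, base_filters >= 1, lambda_smooth > 0,
            threshold > 0, threshold < 1, learning_rate > 0,
            batch_size >= 1, epochs >= 1)
  structure(list(input_mode = input_mode, depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 lambda_smooth = lambda_smooth,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), threshold = threshold,
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Combined binary cross-entropy and Dice loss
#'
#' `total = bce + dice_loss`, where `bce` is the pixel-mean binary
#' cross-entropy and the Dice term is computed on whole-image sums,
#' `1 - (2*sum(y*yhat) + lambda) / (sum(y) + sum(yhat) + lambda)`.
#' Predictions are clamped to `[1e-7, 1 - 1e-7]` for the log terms; the
#' smoothing term `lambda` makes the empty-vs-empty case a perfect score.
#'
#' @param pred probability map in \[0, 1\].
#' @param target binary map of the same shape.
#' @param lambda_smooth Dice smoothing factor (default 1).
#' @return list with `bce`, `dice_loss` and `total`.
#' @export
bce_dice_loss <- function(pred, target, lambda_smooth = 1) {
  stopifnot(all(dim(pred) == dim(target)) ||
              length(pred) == length(target))
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  t <- as.numeric(target > 0)
  bce <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  dice_loss <- 1 - (2 * sum(t * pred) + lambda_smooth) /
    (sum(t) + sum(pred) + lambda_smooth)
  list(bce = bce, dice_loss = dice_loss, total = bce + dice_loss)
}

# gradient of bce_dice_loss w.r.t. the logits (pred = sigmoid(logit))
cg_bce_dice_grad <- function(pred, target, lambda_smooth = 1) {
  t <- as.numeric(target > 0)
  n <- length(pred)
  g_bce <- (pred - t) / n
  S <- sum(t * pred); Sy <- sum(t); Sp <- sum(pred)
  den <- (Sy + Sp + lambda_smooth)
  g_dice_p <- -(2 * t * den - (2 * S + lambda_smooth)) / den^2
  g <- g_bce + g_dice_p * pred * (1 - pred)
  dim(g) <- dim(pred)
  g
}

#' Convert a fragment crop to the model input tensor
#'
#' `"rgb"` keeps the three colour channels; `"gray"` reduces to the luma
#' combination `0.299 R + 0.587 G + 0.114 B`; `"saturation"` takes the HSV
#' saturation channel `(max - min) / max` (0 on black). Values are in
#' \[0, 1\].
#'
#' @param crop a [fragment_crop()] or an H x W x 3 array in \[0, 1\].
#' @param mode one of `"rgb"`, `"gray"`, `"saturation"`.
#' @return an H x W x C array (C = 3 for rgb, 1 otherwise).
#' @export
to_input_channels <- function(crop, mode = c("rgb", "gray", "saturation")) {
  mode <- match.arg(mode)
  x <- if (inherits(crop, "fragment_crop")) crop$image else crop
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  if (mode == "rgb") return(x)
  out <- switch(mode,
    gray = 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3],
    saturation = {
      mx <- pmax(x[, , 1], x[, , 2], x[, , 3])
      mn <- pmin(x[, , 1], x[, , 2], x[, , 3])
      s <- ifelse(mx > 0, (mx - mn) / mx, 0)
      dim(s) <- dim(x)[1:2]
      s
    })
  array(out, c(dim(x)[1:2], 1))
}

cg_unet_init <- function(config) {
  cin <- if (config$input_mode == "rgb") 3L else 1L
  d <- config$depth
  filt <- config$base_filters * 2^(0:(d - 1))
  enc <- list(); c_prev <- cin
  for (k in seq_len(d)) {
    enc[[k]] <- list(a = cg_init_conv3(c_prev, filt[k]),
                     b = cg_init_conv3(filt[k], filt[k]))
    c_prev <- filt[k]
  }
  bott <- list(a = cg_init_conv3(filt[d], 2 * filt[d]),
               b = cg_init_conv3(2 * filt[d], 2 * filt[d]))
  up <- list(); dec <- list()
  for (k in d:1) {
    c_above <- 2 * filt[k]
    up[[k]] <- cg_init_tconv2(c_above, filt[k])
    dec[[k]] <- list(a = cg_init_conv3(2 * filt[k], filt[k]),
                     b = cg_init_conv3(filt[k], filt[k]))
  }
  head <- cg_init_dense(filt[1], 1)
  list(enc = enc, bott = bott, up = up, dec = dec, head = head)
}

cg_conv_block_fwd <- function(p, x) {
  h1 <- cg_relu(cg_conv3_fwd(x, p$a$w, p$a$b))
  h2 <- cg_relu(cg_conv3_fwd(h1, p$b$w, p$b$b))
  list(out = h2, x = x, h1 = h1)
}

cg_conv_block_bwd <- function(p, cache, gout) {
  gout <- gout * (cache$out > 0)
  bb <- cg_conv3_bwd(cache$h1, p$b$w, gout)
  g1 <- bb$gx * (cache$h1 > 0)
  ba <- cg_conv3_bwd(cache$x, p$a$w, g1)
  list(gx = ba$gx, g = list(a = list(w = ba$gw, b = ba$gb),
                            b = list(w = bb$gw, b = bb$gb)))
}

cg_unet_forward <- function(params, x, keep = FALSE) {
  d <- length(params$enc)
  caches <- list(enc = vector("list", d), pool = vector("list", d),
                 dec = vector("list", d), up_in = vector("list", d))
  h <- x
  for (k in seq_len(d)) {
    bl <- cg_conv_block_fwd(params$enc[[k]], h)
    bl$out -> e
    caches$enc[[k]] <- bl
    pl <- cg_maxpool2_fwd(e)
    caches$pool[[k]] <- pl
    h <- pl$out
  }
  bott <- cg_conv_block_fwd(params$bott, h)
  caches$bott <- bott
  h <- bott$out
  for (k in d:1) {
    caches$up_in[[k]] <- h
    u <- cg_tconv2_fwd(h, params$up[[k]]$w, params$up[[k]]$b)
    skip <- caches$enc[[k]]$out
    cat_ <- array(c(skip, u), c(dim(u)[1], dim(u)[2],
                                dim(skip)[3] + dim(u)[3]))
    bl <- cg_conv_block_fwd(params$dec[[k]], cat_)
    caches$dec[[k]] <- bl
    h <- bl$out
  }
  hw <- dim(h)[1] * dim(h)[2]
  feat <- matrix(h, hw, dim(h)[3])
  logits <- matrix(feat %*% params$head$w + params$head$b,
                   dim(h)[1], dim(h)[2])
  if (keep) list(logits = logits, caches = caches, feat = h) else logits
}

cg_unet_backward <- function(params, fwd, glogits) {
  caches <- fwd$caches
  d <- length(params$enc)
  h <- fwd$feat
  hw <- dim(h)[1] * dim(h)[2]
  feat <- matrix(h, hw, dim(h)[3])
  gl <- as.numeric(glogits)
  g_head <- list(w = matrix(crossprod(feat, gl), ncol = 1), b = sum(gl))
  gh <- array(outer(gl, as.numeric(params$head$w)),
              c(dim(h)[1], dim(h)[2], dim(h)[3]))
  g <- list(enc = vector("list", d), bott = NULL,
            up = vector("list", d), dec = vector("list", d), head = g_head)
  for (k in seq_len(d)) {   # decoder, shallow to deep
    bl <- cg_conv_block_bwd(params$dec[[k]], caches$dec[[k]], gh)
    g$dec[[k]] <- bl$g
    nsk <- dim(caches$enc[[k]]$out)[3]
    g_skip <- bl$gx[, , seq_len(nsk), drop = FALSE]
    g_up <- bl$gx[, , (nsk + 1):dim(bl$gx)[3], drop = FALSE]
    tb <- cg_tconv2_bwd(caches$up_in[[k]], params$up[[k]]$w, g_up)
    g$up[[k]] <- list(w = tb$gw, b = tb$gb)
    # stash: gradient flowing into level k's encoder output via the skip,
    # and into the layer above via the transposed conv input
    caches$enc[[k]]$g_skip <- g_skip
    gh <- tb$gx
  }
  # gh now reaches the bottleneck output
  bb <- cg_conv_block_bwd(params$bott, caches$bott, gh)
  g$bott <- bb$g
  gpool <- bb$gx
  for (k in d:1) {   # encoder, deep to shallow
    e <- caches$enc[[k]]$out
    ge <- cg_maxpool2_bwd(gpool, caches$pool[[k]]$idx,
                          dim(e)[1], dim(e)[2]) + caches$enc[[k]]$g_skip
    bl <- cg_conv_block_bwd(params$enc[[k]], caches$enc[[k]], ge)
    g$enc[[k]] <- bl$g
    gpool <- bl$gx
  }
  g
}
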