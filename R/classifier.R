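#' Tile classifier configuration
#'
#' A compact residual-style CNN head is overkill at phantom scale, so the
#' classifier is a plain block CNN: `blocks` stages of 3x3 convolution,
#' ReLU and 2x2 max-pooling with doubling filters, global average pooling
#' and a dense softmax over the three grades. Trained with Adam under the
#' ordinal quadratic-weighted-kappa loss ([qwk_loss()]), weights randomly
#' initialised (deterministic given the seed). Tiles are resized to
#' `input_size` before entering the network.
#'
#' @param blocks number of conv/pool stages.
#' @param base_filters filters of the first stage (doubles per stage).
#' @param input_size network input side in pixels.
#' @param learning_rate,batch_size,epochs Adam schedule; the full-scale
#'   recipe uses 1e-5 / 16 / 300, the default here is sized for CPU
#'   training on phantom tiles.
#' @param restarts independent random restarts; the ordinal kappa loss has
#'   a rare degenerate optimum that collapses the most severe class, so
#'   training runs from `restarts` seeds and keeps the restart with the
#'   best validation balanced accuracy.
#' @param seed seed for initialisation and shuffling (restart r uses
#'   `seed + 7919 * (r - 1)`).
#' @export
cls_config <- function(blocks = 4L, base_filters = 8L, input_size = 64L,
                       learning_rate = 1e-3, batch_size = 16L,
                       epochs = 30L, restarts = 2L, seed = 1L) {
  stopifnot(blocks >= 1, input_size %% 2^blocks == 0, base_filters >= 1,
            learning_rate > 0, batch_size >= 2, epochs >= 1, restarts >= 1)
  structure(list(blocks = as.integer(blocks),
                 base_filters = as.integer(base_filters),
                 input_size = as.integer(input_size),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "cls_config")
}

cg_cnn_init <- function(config) {
  filt <- config$base_filters * 2^(0:(config$blocks - 1))
  convs <- list(); cin <- 3L
  for (k in seq_len(config$blocks)) {
    convs[[k]] <- cg_init_conv3(cin, filt[k])
    cin <- filt[k]
  }
  list(convs = convs, dense = cg_init_dense(cin, 3L))
}

cg_cnn_forward <- function(params, x, keep = FALSE) {
  caches <- list()
  h <- x
  for (k in seq_along(params$convs)) {
    pre <- cg_conv3_fwd(h, params$convs[[k]]$w, params$convs[[k]]$b)
    act <- cg_relu(pre)
    pl <- cg_maxpool2_fwd(act)
    caches[[k]] <- list(x = h, act = act, idx = pl$idx)
    h <- pl$out
  }
  feat <- apply(h, 3, mean)
  logits <- as.numeric(feat %*% params$dense$w + params$dense$b)
  p <- cg_softmax(logits)
  if (keep) list(p = p, logits = logits, feat = feat, h = h,
                 caches = caches) else p
}

# backward from dL/dp (chain through softmax inside)
cg_cnn_backward <- function(params, fwd, gp) {
  p <- fwd$p
  glog <- p * (gp - sum(gp * p))       # softmax jacobian
  g <- list(convs = vector("list", length(params$convs)),
            dense = list(w = outer(fwd$feat, glog), b = glog))
  gfeat <- as.numeric(params$dense$w %*% glog)
  hd <- dim(fwd$h)
  gh <- array(rep(gfeat, each = hd[1] * hd[2]) / (hd[1] * hd[2]), hd)
  for (k in rev(seq_along(params$convs))) {
    ca <- fwd$caches[[k]]
    ga <- cg_maxpool2_bwd(gh, ca$idx, dim(ca$act)[1], dim(ca$act)[2])
    ga <- ga * (ca$act > 0)
    bw <- cg_conv3_bwd(ca$x, params$convs[[k]]$w, ga)
    g$convs[[k]] <- list(w = bw$gw, b = bw$gb)
    gh <- bw$gx
  }
  g
}

# tile image -> network input tensor (resize to input_size)
cg_tile_tensor <- function(tile, input_size) {
  img <- if (is.list(tile) && !is.null(tile$image)) tile$image else tile
  if (all(dim(img)[1:2] == input_size)) return(img)
  cg_resize(img, input_size, input_size)
}

#' Classify tiles
#'
#' Returns an N x 3 matrix of class probabilities (columns NNeo, LSIL,
#' HSIL). Dispatches on the model class so that a ground-truth
#' [oracle_classifier()] can stand in for a trained network.
#'
#' @param model a `cg_cls_model` or oracle.
#' @param tiles list of tiles (or arrays).
#' @export
classify_tiles <- function(model, tiles) UseMethod("classify_tiles")

#' @export
classify_tiles.cg_cls_model <- function(model, tiles) {
  out <- t(vapply(tiles, function(tl)
    cg_cnn_forward(model$params,
                   cg_tile_tensor(tl, model$config$input_size)),
    numeric(3)))
  colnames(out) <- cg_classes()
  out
}

#' Ground-truth oracle classifier
#'
#' Holds a phantom's per-pixel region-label map and classifies each tile
#' as the worst ground-truth label within a small window around the tile
#' center (one-hot probabilities). Used to test the slide aggregation
#' logic independently of classifier quality.
#'
#' @param label_map level-0 integer matrix of region labels (0 = none).
#' @param window half-side of the window inspected around the center.
#' @export
oracle_classifier <- function(label_map, window = 16L)
  structure(list(label_map = label_map, window = as.integer(window)),
            class = "cg_oracle_classifier")

#' @export
classify_tiles.cg_oracle_classifier <- function(model, tiles) {
  lm <- model$label_map
  out <- t(vapply(tiles, function(tl) {
    cx <- tl$center[1]; cy <- tl$center[2]
    xs <- max(0, cx - model$window):min(ncol(lm) - 1, cx + model$window)
    ys <- max(0, cy - model$window):min(nrow(lm) - 1, cy + model$window)
    lab <- max(lm[ys + 1, xs + 1], 0)
    p <- rep(0, 3)
    p[max(lab, 1)] <- 1
    p
  }, numeric(3)))
  colnames(out) <- cg_classes()
  out
}

#' Train the ordinal MIL tile classifier
#'
#' Each epoch has two phases, following the top-instance ranking scheme:
#' (i) an inference pass ranks every multi-tile (LS/AE) bag with the
#' current weights and selects its worst tile, labelled with the bag
#' label; (ii) a gradient pass runs over the selected tiles together with
#' all fully-supervised AT tiles, in shuffled minibatches, under the
#' quadratic-weighted-kappa loss. The returned checkpoint maximises the
#' bag-level validation balanced accuracy (bags scored by their worst
#' tile's argmax class).
#'
#' @param bags,val_bags bags from [build_bags()].
#' @param config a [cls_config()].
#' @param verbose print one line per epoch.
#' @return object of class `cg_cls_model` with `params`, `config`,
#'   `train_log`, `best_epoch`.
#' @export
train_classifier <- function(bags, val_bags, config, verbose = FALSE) {
  stopifnot(length(bags) >= 1, length(val_bags) >= 1)
  prep_bag <- function(b) {
    b$tensors <- lapply(b$tiles, cg_tile_tensor, config$input_size)
    b
  }
  bags <- lapply(bags, prep_bag)
  val_bags <- lapply(val_bags, prep_bag)
  at <- bags[vapply(bags, function(b) b$supervision == "AT", logical(1))]
  multi <- bags[vapply(bags, function(b) b$supervision != "AT", logical(1))]
  runs <- lapply(seq_len(config$restarts), function(r)
    cg_train_classifier_once(at, multi, val_bags, config,
                             config$seed + 7919L * (r - 1L), verbose))
  best_run <- which.max(vapply(runs, `[[`, numeric(1), "val_balacc"))
  out <- runs[[best_run]]
  out$restart <- best_run
  out
}

# one seeded training run; train_classifier keeps the best restart
cg_train_classifier_once <- function(at, multi, val_bags, config, seed,
                                     verbose) {
  withr::with_seed(as.integer(seed), {
    params <- cg_cnn_init(config)
    opt <- cg_adam_init(params)
    best <- list(metric = -Inf, params = params, epoch = 0L)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_balacc = numeric())
    model <- structure(list(params = params, config = config),
                       class = "cg_cls_model")
    for (ep in seq_len(config$epochs)) {
      model$params <- params
      inst <- lapply(multi, function(b) {
        sel <- cg_rank_tensors(model, b$tensors)
        list(x = b$tensors[[sel]], y = b$label)
      })
      inst <- c(inst, lapply(at, function(b)
        list(x = b$tensors[[1]], y = b$label)))
      ord <- sample(length(inst))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        fwds <- lapply(bi, function(i)
          cg_cnn_forward(params, inst[[i]]$x, keep = TRUE))
        probs <- do.call(rbind, lapply(fwds, `[[`, "p"))
        labs <- vapply(bi, function(i) inst[[i]]$y, integer(1))
        lt <- qwk_loss(probs, labs)
        if (!is.finite(lt$loss)) stop("NaN loss at epoch ", ep)
        ep_loss <- ep_loss + lt$loss; nb <- nb + 1
        if (lt$degenerate) next   # no defined gradient on such a batch
        gp <- cg_qwk_grad(probs, labs)
        gacc <- NULL
        for (j in seq_along(bi))
          gacc <- cg_grad_axpy(gacc,
                               cg_cnn_backward(params, fwds[[j]], gp[j, ]))
        upd <- cg_adam_step(params, gacc, opt, config$learning_rate)
        params <- upd$params; opt <- upd$state
      }
      model$params <- params
      vb <- cg_bag_balanced_accuracy(model, val_bags)
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = ep_loss / max(nb, 1),
                                   val_balacc = vb))
      if (vb > best$metric) best <- list(metric = vb, params = params,
                                         epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val balacc %.3f", ep,
                        ep_loss / max(nb, 1), vb))
    }
    structure(list(params = best$params, config = config, train_log = log,
                   best_epoch = best$epoch, val_balacc = best$metric),
              class = "cg_cls_model")
  })
}

# index of the worst tile among pre-resized tensors
cg_rank_tensors <- function(model, tensors) {
  probs <- t(vapply(tensors, function(x)
    cg_cnn_forward(model$params, x), numeric(3)))
  scores <- probs %*% seq_len(3)
  order(-scores, -probs[, 3], seq_len(nrow(probs)))[1]
}

# bag-level balanced accuracy: each bag predicted by its worst tile's class
cg_bag_balanced_accuracy <- function(model, bags) {
  pred <- vapply(bags, function(b) {
    probs <- t(vapply(b$tensors, function(x)
      cg_cnn_forward(model$params, x), numeric(3)))
    scores <- probs %*% seq_len(3)
    sel <- order(-scores, -probs[, 3], seq_len(nrow(probs)))[1]
    which.max(probs[sel, ])
  }, integer(1))
  actual <- vapply(bags, `[[`, integer(1), "label")
  cls <- sort(unique(actual))
  mean(vapply(cls, function(c) mean(pred[actual == c] == c), numeric(1)))
}
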