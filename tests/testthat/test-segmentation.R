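test_that("bce_dice_loss matches its closed forms", {
  ones <- matrix(1, 4, 4)
  lt <- bce_dice_loss(ones, ones)
  expect_equal(lt$dice_loss, 0)
  expect_lt(lt$bce, 1e-5)
  expect_equal(lt$total, lt$bce + lt$dice_loss)

  zeros <- matrix(0, 4, 4)
  lt0 <- bce_dice_loss(zeros, zeros)
  expect_equal(lt0$dice_loss, 0)   # lambda rescues the empty case
  expect_lt(lt0$total, 1e-5)

  # hand-evaluated mixed case
  lt2 <- bce_dice_loss(c(0.5, 0.5), c(1, 0), lambda_smooth = 1)
  expect_equal(lt2$dice_loss, 1 / 3)
  expect_equal(lt2$bce, log(2))
  expect_equal(lt2$total, 1 / 3 + log(2))
})

test_that("bce_dice_loss is non-negative, exact at equality, dice symmetric", {
  set.seed(4)
  for (i in 1:20) {
    t <- matrix(rbinom(64, 1, 0.4), 8, 8)
    p <- matrix(runif(64), 8, 8)
    lt <- bce_dice_loss(p, t)
    expect_gte(lt$bce, 0)
    expect_gte(lt$dice_loss, 0)
    expect_lt(bce_dice_loss(t, t)$total, 1e-5)
    # dice term is symmetric in (pred, target) for binary arguments
    t2 <- matrix(rbinom(64, 1, 0.5), 8, 8)
    expect_equal(bce_dice_loss(t2, t)$dice_loss,
                 bce_dice_loss(t, t2)$dice_loss)
    # permutation invariance
    perm <- sample(64)
    expect_equal(bce_dice_loss(p[perm], t[perm])$total, lt$total)
  }
})

test_that("input channel conversion follows the colour definitions", {
  x <- array(0, c(2, 2, 3))
  x[1, 1, ] <- c(0.5, 0.5, 0.5)   # pure gray -> saturation 0
  x[1, 2, ] <- c(1, 0, 0)         # pure red -> saturation 1
  s <- to_input_channels(x, "saturation")
  expect_equal(dim(s), c(2, 2, 1))
  expect_equal(s[1, 1, 1], 0)
  expect_equal(s[1, 2, 1], 1)
  set.seed(9)
  r <- array(runif(48), c(4, 4, 3))
  g <- to_input_channels(r, "gray")
  luma <- vapply(1:16, function(k) {
    i <- (k - 1) %% 4 + 1; j <- (k - 1) %/% 4 + 1
    0.299 * r[i, j, 1] + 0.587 * r[i, j, 2] + 0.114 * r[i, j, 3]
  }, numeric(1))
  expect_equal(as.numeric(g[, , 1]), luma)
  expect_equal(dim(to_input_channels(r, "rgb")), c(4, 4, 3))
  expect_error(to_input_channels(r, "hue"))
})

test_that("network gradients agree with numerical differentiation", {
  set.seed(12)
  cfg <- seg_config(depth = 2, base_filters = 2, seed = 3)
  params <- withr::with_seed(3, cervigrade:::cg_unet_init(cfg))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  fwd <- cervigrade:::cg_unet_forward(params, x, keep = TRUE)
  p <- cervigrade:::cg_sigmoid(fwd$logits)
  g <- cervigrade:::cg_unet_backward(
    params, fwd, cervigrade:::cg_bce_dice_grad(p, y, 1))
  loss_at <- function(pp) {
    f <- cervigrade:::cg_unet_forward(pp, x)
    bce_dice_loss(cervigrade:::cg_sigmoid(f), y, 1)$total
  }
  base <- loss_at(params)
  eps <- 1e-6
  # spot-check a handful of weights across layers
  probes <- list(c("enc", 1, "a"), c("bott", NA, "b"), c("dec", 2, "a"))
  for (pr in probes) {
    pp <- params
    if (pr[1] == "bott") {
      pp$bott[[pr[3]]]$w[1, 1] <- pp$bott[[pr[3]]]$w[1, 1] + eps
      ana <- g$bott[[pr[3]]]$w[1, 1]
    } else {
      k <- as.integer(pr[2])
      pp[[pr[1]]][[k]][[pr[3]]]$w[2, 1] <-
        pp[[pr[1]]][[k]][[pr[3]]]$w[2, 1] + eps
      ana <- g[[pr[1]]][[k]][[pr[3]]]$w[2, 1]
    }
    num <- (loss_at(pp) - base) / eps
    expect_equal(ana, num, tolerance = 1e-3)
  }
})

test_that("the segmenter overfits one sample and selects the best epoch", {
  ph <- generate_phantom_slide(
    phantom_config(image_size = c(64, 64), fragments_per_slide = c(1, 1),
                   ribbon_thickness = c(8, 12), seed = 5), "HSIL", 5)
  item <- list(crop = ph$image, mask = ph$epithelium_mask)
  cfg <- seg_config(depth = 2, base_filters = 8, learning_rate = 2e-3,
                    batch_size = 1, epochs = 200, seed = 11)
  m <- train_segmenter(list(item), list(item), cfg)
  dl <- m$train_log$train_dice_loss
  # decreasing over any 10-epoch window, allowing plateaus and the small
  # oscillation of an adaptive optimiser at its noise floor
  for (i in seq_len(length(dl) - 10))
    expect_lte(dl[i + 10], dl[i] + 0.05)
  expect_lt(tail(dl, 1), 0.05)    # the single sample is truly memorised
  # argmin selection: returned model no worse than the final epoch
  expect_lte(m$val_loss, tail(m$train_log$val_loss, 1))
  # determinism: same seed, same weights
  m2 <- train_segmenter(list(item), list(item),
                        seg_config(depth = 2, base_filters = 4,
                                   learning_rate = 2e-3, batch_size = 1,
                                   epochs = 3, seed = 11))
  m3 <- train_segmenter(list(item), list(item),
                        seg_config(depth = 2, base_filters = 4,
                                   learning_rate = 2e-3, batch_size = 1,
                                   epochs = 3, seed = 11))
  expect_identical(m2$params, m3$params)
})

test_that("predict_mask respects thresholds and the oracle path", {
  cfg <- seg_config(depth = 1, base_filters = 2, seed = 2)
  params <- withr::with_seed(2, cervigrade:::cg_unet_init(cfg))
  # force an all-negative head
  params$head$w[] <- 0
  params$head$b <- -10
  model <- structure(list(params = params, config = cfg),
                     class = "cg_seg_model")
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(sum(predict_mask(model, x)), 0)
  expect_equal(sum(predict_mask(model, x, threshold = 1e-9)), 32 * 32)
  # oracle segmenter reproduces the truth through the crop transform
  ph <- cached_phantom("LSIL", 3)
  sl <- slide_image(ph$image)
  box <- find_tissue_fragments(sl)[[1]]
  crop <- crop_and_resize(sl, box, 256)
  om <- predict_mask(oracle_segmenter(ph$epithelium_mask), crop)
  back <- cervigrade:::cg_mask_to_level0(om, crop, dim(ph$epithelium_mask))
  truth_in_box <- ph$epithelium_mask
  truth_in_box[-((box[["y0"]] + 1):box[["y1"]]), ] <- 0L
  truth_in_box[, -((box[["x0"]] + 1):box[["x1"]])] <- 0L
  expect_gt(segmentation_metrics(back, truth_in_box)$dice, 0.9)
})
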