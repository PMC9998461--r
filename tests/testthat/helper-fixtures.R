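# Shared fixtures: small phantom configurations sized for fast CPU tests,
# cached per session so several test files can reuse the same slides.

phantom_cfg_small <- function(seed = 1L)
  phantom_config(image_size = c(768, 576), fragments_per_slide = c(1, 2),
                 ribbon_thickness = c(28, 44), seed = seed)

phantom_cfg_crop <- function(seed = 1L)
  phantom_config(image_size = c(256, 256), fragments_per_slide = c(1, 1),
                 ribbon_thickness = c(16, 26), seed = seed)

.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(label, seed, cfg = phantom_cfg_small()) {
  key <- paste0(label, "_", seed, "_", paste(cfg$image_size, collapse = "x"))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_phantom_slide(cfg, label, seed)
  .fixture_cache[[key]]
}

# pipeline settings matching the small phantom scale
pipeline_cfg_small <- function()
  pipeline_config(seg_input_size = 256, tile_size = 96, tile_interval = 48)

# in-memory AT bags for a set of phantom slides (tiles along the truth mask)
phantom_at_bags <- function(phantoms, tile_size = 96, interval = 32) {
  tiles <- list(); ann <- list(); mf <- NULL
  for (ph in phantoms) {
    id <- ph$manifest_row$slide_id
    sl <- slide_image(ph$image)
    tiles <- c(tiles, tile_epithelium(sl, ph$epithelium_mask, tile_size,
                                      interval, slide_id = id))
    ann[[id]] <- c(ph$region_labels, ph$rois)
    mf <- rbind(mf, data.frame(slide_id = id, label = ph$slide_label))
  }
  build_bags(mf, ann, tiles, supervision = "AT")
}

# a classifier stub that returns fixed probabilities (for rank/selection
# logic tests); tiles are matched by their list position
fixed_classifier <- function(probs) {
  structure(list(probs = probs), class = "cg_fixed_classifier")
}
local({
  registerS3method("classify_tiles", "cg_fixed_classifier",
                   function(model, tiles) {
                     out <- model$probs[seq_along(tiles), , drop = FALSE]
                     colnames(out) <- cg_classes()
                     out
                   },
                   envir = asNamespace("cervigrade"))
})

# reference confusion matrices from the published clinical evaluation,
# used as worked examples throughout the metrics tests
# (rows = predicted, columns = actual)
validation_cm_ae_at <- function() as_confusion_matrix(matrix(
  c(10, 7, 0,
    3, 45, 5,
    2, 11, 28), 3, 3, byrow = TRUE,
  dimnames = list(cg_classes(), cg_classes())))

validation_cm_ae_at_ls <- function() as_confusion_matrix(matrix(
  c(9, 5, 0,
    4, 52, 7,
    2, 6, 26), 3, 3, byrow = TRUE,
  dimnames = list(cg_classes(), cg_classes())))

test_cohort_cm <- function() as_confusion_matrix(matrix(
  c(126, 21, 0, 22,
    73, 202, 24, 16,
    5, 25, 56, 0,
    0, 2, 0, 28), 4, 4, byrow = TRUE,
  dimnames = list(cg_all_classes(), cg_all_classes())))
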