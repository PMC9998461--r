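#' Inference pipeline configuration
#'
#' @param seg_input_size side of the square segmentation input.
#' @param tile_size tile side at 20x.
#' @param tile_interval center spacing along the centerline in 20x pixels.
#' @param min_epithelium_area level-0 pixel count at or below which the
#'   segmentation counts as empty and the slide is called `"OTHERS"`
#'   (default 0: strictly empty).
#' @param min_centerline_length see [extract_centerline()].
#' @param min_fragment_area_frac see [find_tissue_fragments()].
#' @param overview_max_side see [find_tissue_fragments()].
#' @export
pipeline_config <- function(seg_input_size = 1024L, tile_size = 512L,
                            tile_interval = 256, min_epithelium_area = 0L,
                            min_centerline_length = 15L,
                            min_fragment_area_frac = 5e-4,
                            overview_max_side = 2048L) {
  structure(list(seg_input_size = as.integer(seg_input_size),
                 tile_size = as.integer(tile_size),
                 tile_interval = tile_interval,
                 min_epithelium_area = as.integer(min_epithelium_area),
                 min_centerline_length = as.integer(min_centerline_length),
                 min_fragment_area_frac = min_fragment_area_frac,
                 overview_max_side = as.integer(overview_max_side)),
            class = "pipeline_config")
}

#' Diagnose one slide
#'
#' Full inference chain: Otsu tissue mask, fragment detection, per-fragment
#' epithelium segmentation merged into a level-0 mask, centerline tiling,
#' tile classification, and the worst-tile rule — the slide label is the
#' argmax class of the tile with the highest expected severity. When the
#' merged segmentation is empty (area `<= min_epithelium_area`) or yields
#' no tiles, the slide is called `"OTHERS"` and no tile is classified.
#'
#' @param slide a [slide_image()].
#' @param seg_model segmentation model ([train_segmenter()] result or
#'   [oracle_segmenter()]).
#' @param cls_model tile classifier ([train_classifier()] result or
#'   [oracle_classifier()]).
#' @param config a [pipeline_config()].
#' @param slide_id identifier for the report.
#' @return object of class `slide_diagnosis`: `slide_id`, `label`,
#'   `worst_tile`, `worst_score`, `n_fragments`, `n_epithelium_pixels`,
#'   `n_tiles`.
#' @export
diagnose_slide <- function(slide, seg_model, cls_model,
                           config = pipeline_config(), slide_id = "slide") {
  boxes <- find_tissue_fragments(slide, config$overview_max_side,
                                 config$min_fragment_area_frac)
  d0 <- slide_dims(slide, 1)
  mask0 <- matrix(0L, d0[["height"]], d0[["width"]])
  for (b in boxes) {
    crop <- crop_and_resize(slide, b, config$seg_input_size)
    mk <- predict_mask(seg_model, crop)
    m0 <- cg_mask_to_level0(mk, crop, dim(mask0))
    mask0[m0 > 0] <- 1L
  }
  n_pix <- sum(mask0)
  others <- function() structure(
    list(slide_id = slide_id, label = "OTHERS", worst_tile = NULL,
         worst_score = NULL, n_fragments = length(boxes),
         n_epithelium_pixels = n_pix, n_tiles = 0L),
    class = "slide_diagnosis")
  if (n_pix <= config$min_epithelium_area) return(others())
  tiles <- tile_epithelium(slide, mask0, config$tile_size,
                           config$tile_interval,
                           config$min_centerline_length, slide_id)
  if (!length(tiles)) return(others())
  sel <- rank_and_select(cls_model, tiles)
  structure(list(slide_id = slide_id,
                 label = cg_classes()[which.max(sel$worst_probs)],
                 worst_tile = sel$worst_tile,
                 worst_score = sel$worst_score,
                 n_fragments = length(boxes),
                 n_epithelium_pixels = n_pix,
                 n_tiles = length(tiles)),
            class = "slide_diagnosis")
}

#' @export
print.slide_diagnosis <- function(x, ...) {
  cat(sprintf("%s: %s (%d fragments, %d epithelium px, %d tiles%s)\n",
              x$slide_id, x$label, x$n_fragments, x$n_epithelium_pixels,
              x$n_tiles,
              if (is.null(x$worst_score)) ""
              else sprintf(", worst score %.2f", x$worst_score)))
  invisible(x)
}

#' Run the pipeline over a cohort
#'
#' One diagnosis per manifest row; failures are logged and marked, the
#' run continues. Produces the predictions table, the 4-class confusion
#' matrix (`"OTHERS"` last), the metric suite on all classes and after
#' excluding `"OTHERS"`, and the epithelium-detection balanced accuracy.
#'
#' @param manifest data frame with `slide_id`, `label` and (unless a
#'   custom `models` function provides slides) `path` to a PNG.
#' @param models either `list(seg = <seg model>, cls = <cls model>)`, or a
#'   function `(row) -> list(slide, seg, cls)` (e.g. per-slide oracles).
#' @param config a [pipeline_config()].
#' @param out_dir optional; writes `predictions.csv` and `metrics.json`.
#' @return list with `predictions`, `confusion`, `metrics_all`,
#'   `metrics_graded`, `detection_balanced_accuracy`.
#' @export
run_cohort <- function(manifest, models, config = pipeline_config(),
                       out_dir = NULL) {
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      if (is.function(models)) {
        mm <- models(row)
        dg <- diagnose_slide(mm$slide, mm$seg, mm$cls, config,
                             slide_id = row$slide_id)
      } else {
        dg <- diagnose_slide(slide_from_png(row$path), models$seg,
                             models$cls, config, slide_id = row$slide_id)
      }
      data.frame(slide_id = row$slide_id, predicted = dg$label,
                 actual = row$label,
                 worst_score = if (is.null(dg$worst_score)) NA_real_
                               else dg$worst_score,
                 n_tiles = dg$n_tiles, status = "ok")
    }, error = function(e) {
      warning("slide ", row$slide_id, " failed: ", conditionMessage(e))
      data.frame(slide_id = row$slide_id, predicted = NA_character_,
                 actual = row$label, worst_score = NA_real_,
                 n_tiles = NA_integer_, status = "failed")
    })
    rows[[i]] <- res
  }
  pred <- do.call(rbind, rows)
  ok <- pred$status == "ok"
  cm <- confusion_matrix(pred$predicted[ok], pred$actual[ok],
                         classes = cg_all_classes())
  has_all <- all(colSums(cm) > 0)
  metrics_all <- if (has_all) metrics_report(cm) else NULL
  cm3 <- exclude_class(cm, "OTHERS")
  metrics_graded <- if (all(colSums(cm3) > 0)) metrics_report(cm3) else NULL
  det <- if (any(pred$actual[ok] == "OTHERS") &&
             any(pred$actual[ok] != "OTHERS"))
    detection_balanced_accuracy(pred$predicted[ok] != "OTHERS",
                                pred$actual[ok] != "OTHERS") else NA_real_
  out <- list(predictions = pred, confusion = cm,
              metrics_all = metrics_all, metrics_graded = metrics_graded,
              detection_balanced_accuracy = det)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(pred, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    drop_pc <- function(m) if (is.null(m)) NULL else
      m[setdiff(names(m), "per_class")]
    jsonlite::write_json(list(confusion = unclass(cm),
                              metrics_all = drop_pc(metrics_all),
                              metrics_graded = drop_pc(metrics_graded),
                              detection_balanced_accuracy = det),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
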