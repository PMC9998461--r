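#' Otsu tissue mask
#'
#' Locates tissue on a slide overview: the image is reduced to its luma
#' channel and thresholded with Otsu's method; tissue is darker than the
#' glass background, so the foreground is everything below the threshold.
#' A (near-)constant image yields an empty mask rather than an error.
#'
#' @param image H x W x 3 RGB array in \[0, 1\], or a gray matrix.
#' @return integer 0/1 matrix of the same height/width.
#' @export
otsu_tissue_mask <- function(image) {
  g <- if (length(dim(image)) == 3)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else image
  if (diff(range(g)) < 1 / 256) return(matrix(0L, nrow(g), ncol(g)))
  thr <- EBImage::otsu(g, range = c(0, 1), levels = 256)
  out <- matrix(0L, nrow(g), ncol(g))
  out[g < thr] <- 1L
  out
}

#' Detect tissue fragments in a binary mask
#'
#' Applies a morphological closing (5-px disc) to bridge small gaps, labels
#' 8-connected components and returns one bounding box per component with
#' area at least `min_area`, sorted by `(y0, x0)`.
#'
#' @param mask binary matrix.
#' @param min_area minimum component area in pixels; the default keeps
#'   components covering at least 0.05 percent of the mask.
#' @return list of 0-based half-open boxes `c(x0, y0, x1, y1)`.
#' @export
detect_fragments <- function(mask, min_area = 0.0005 * length(mask)) {
  m <- EBImage::closing(mask > 0, EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n == 0) return(list())
  boxes <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    boxes[[length(boxes) + 1]] <-
      c(x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
        x1 = max(idx[, 2]), y1 = max(idx[, 1]))
  }
  ord <- order(vapply(boxes, `[`, numeric(1), 2),
               vapply(boxes, `[`, numeric(1), 1))
  boxes[ord]
}

#' Locate tissue fragments on a slide
#'
#' Convenience composition of [otsu_tissue_mask()] and [detect_fragments()]
#' on a slide overview (the highest pyramid level whose longest side does
#' not exceed `max_side`), with the boxes mapped back to level-0
#' coordinates.
#'
#' @param slide a [slide_image()].
#' @param max_side overview size cap in pixels.
#' @param min_area_frac minimum fragment area as a fraction of the
#'   overview.
#' @return list of level-0 boxes `c(x0, y0, x1, y1)`.
#' @export
find_tissue_fragments <- function(slide, max_side = 2048,
                                  min_area_frac = 5e-4) {
  lev <- 1L
  while (max(slide_dims(slide, lev)) > max_side &&
         lev < length(slide$levels)) lev <- lev + 1L
  ds <- slide$level_downsamples[lev]
  ov <- slide$levels[[lev]]
  mask <- otsu_tissue_mask(ov)
  boxes <- detect_fragments(mask, min_area_frac * length(mask))
  lapply(boxes, function(b) {
    d0 <- slide_dims(slide, 1)
    c(x0 = b[["x0"]] * ds, y0 = b[["y0"]] * ds,
      x1 = min(d0[["width"]], b[["x1"]] * ds),
      y1 = min(d0[["height"]], b[["y1"]] * ds))
  })
}

#' Crop a fragment and resize it to the segmentation input size
#'
#' The level-0 box is cropped, padded with white to a square (right/bottom)
#' to avoid anisotropic distortion of the thin epithelium ribbon, and
#' resized to `size x size`. The scale factors mapping crop pixels back to
#' level-0 are recorded exactly: `level0 = crop_px * scale + box origin`.
#'
#' @param slide a [slide_image()].
#' @param box level-0 half-open box `c(x0, y0, x1, y1)` with positive area.
#' @param size output side in pixels.
#' @return object of class `fragment_crop` with fields `image`,
#'   `source_box`, `pad_side`, `scale_x`, `scale_y`.
#' @export
crop_and_resize <- function(slide, box, size = 1024L) {
  box <- round(as.numeric(box))
  w <- box[3] - box[1]; h <- box[4] - box[2]
  if (w <= 0 || h <= 0) stop("degenerate box (zero area)")
  side <- max(w, h)
  sq <- array(1, c(side, side, 3))
  sq[seq_len(h), seq_len(w), ] <- read_region(slide, 1, box[1], box[2], w, h)
  img <- cg_resize(sq, size, size)
  structure(list(image = img, source_box = box, pad_side = side,
                 scale_x = side / size, scale_y = side / size),
            class = "fragment_crop")
}

# bilinear resize of an HxWxC array (EBImage operates on the first two dims)
cg_resize <- function(x, h, w) {
  out <- EBImage::resize(x, w = h, h = w)   # EBImage's w is the first dim
  if (length(dim(x)) == 3 && length(dim(out)) == 2)
    out <- array(out, c(h, w, dim(x)[3]))
  out
}

#' Map crop coordinates back to level 0
#'
#' @param crop a [crop_and_resize()] result.
#' @param xy matrix (or length-2 vector) of 0-based crop coordinates.
#' @return matrix of level-0 coordinates.
#' @export
crop_to_level0 <- function(crop, xy) {
  xy <- rbind(xy)
  cbind(x = xy[, 1] * crop$scale_x + crop$source_box[1],
        y = xy[, 2] * crop$scale_y + crop$source_box[2])
}

# nearest-neighbour transfer of a level-0 truth mask into crop space
# (used to build training targets aligned with a fragment_crop)
cg_mask_to_crop <- function(mask0, crop, size = dim(crop$image)[1]) {
  xs <- floor(((seq_len(size) - 0.5) * crop$scale_x) + crop$source_box[1])
  ys <- floor(((seq_len(size) - 0.5) * crop$scale_y) + crop$source_box[2])
  out <- matrix(0L, size, size)
  okx <- xs >= 0 & xs < ncol(mask0)
  oky <- ys >= 0 & ys < nrow(mask0)
  out[oky, okx] <- (mask0[ys[oky] + 1, xs[okx] + 1, drop = FALSE] > 0) + 0L
  out
}

# nearest-neighbour projection of a crop-space mask onto the level-0 canvas
cg_mask_to_level0 <- function(mask_crop, crop, dims0) {
  out <- matrix(0L, dims0[1], dims0[2])   # H x W
  b <- crop$source_box
  x0 <- max(0, b[1]); y0 <- max(0, b[2])
  x1 <- min(dims0[2], b[3]); y1 <- min(dims0[1], b[4])
  if (x1 <= x0 || y1 <= y0) return(out)
  xs <- x0:(x1 - 1); ys <- y0:(y1 - 1)
  cx <- pmin(dim(mask_crop)[2], floor((xs + 0.5 - b[1]) / crop$scale_x) + 1)
  cy <- pmin(dim(mask_crop)[1], floor((ys + 0.5 - b[2]) / crop$scale_y) + 1)
  out[ys + 1, xs + 1] <- (mask_crop[cy, cx, drop = FALSE] > 0) + 0L
  out
}

#' Read and write binary masks as PNG
#'
#' Masks round-trip bit-exactly: foreground is written as 255, background
#' as 0.
#'
#' @param mask binary matrix.
#' @param path PNG file path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(x > 0.5), nrow(x), ncol(x))
}

#' Read and write polygon annotations (GeoJSON)
#'
#' Annotations are a GeoJSON `FeatureCollection` of `Polygon` features in
#' level-0 pixel coordinates with properties `label` (one of `NNeo`,
#' `LSIL`, `HSIL`, or `uncertain`) and `role` (`"epithelium"` for labelled
#' epithelium outlines, `"roi"` for small fully-supervised regions).
#'
#' @param annotations list of features, each
#'   `list(polygon = <n x 2 matrix>, label = <chr>, role = <chr>)`.
#' @param path GeoJSON file path.
#' @export
write_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    ring <- rbind(a$polygon, a$polygon[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(label = a$label,
                           role = if (is.null(a$role)) "epithelium" else a$role))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed GeoJSON in ", path, ": ",
                         conditionMessage(e)))
  if (!identical(obj$type, "FeatureCollection") || is.null(obj$features))
    stop("malformed GeoJSON in ", path,
         ": expected a FeatureCollection with a features array")
  lapply(obj$features, function(f) {
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("malformed GeoJSON in ", path, ": features must be Polygons")
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
      poly <- poly[-nrow(poly), , drop = FALSE]
    list(polygon = poly,
         label = f$properties$label,
         role = if (is.null(f$properties$role)) "epithelium"
                else f$properties$role)
  })
}

#' Rasterize polygons to a binary mask
#'
#' Even-odd fill with pixel-center inclusion: pixel `(x, y)` is foreground
#' when its center `(x + 0.5, y + 0.5)` lies inside the polygon. Multiple
#' features are combined with OR; rings within a feature follow the
#' even-odd rule (holes).
#'
#' @param polygons list of features as in [read_annotations()], or a list
#'   of bare n x 2 coordinate matrices.
#' @param shape mask shape `c(height, width)`.
#' @export
rasterize_polygons <- function(polygons, shape) {
  out <- matrix(0L, shape[1], shape[2])
  for (p in polygons) {
    rings <- if (is.matrix(p)) list(p) else list(p$polygon)
    m <- cg_rasterize(rings, shape[1], shape[2])
    out[m > 0] <- 1L
  }
  out
}

# even-odd point-in-polygon test for 0-based (x, y) points
cg_points_in_polygon <- function(pts, poly) {
  pts <- rbind(pts)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi <= pts[, 2]) & (pts[, 2] < yj)) |
             ((yj <= pts[, 2]) & (pts[, 2] < yi))
    if (any(cross)) {
      xc <- xi + (pts[cross, 2] - yi) / (yj - yi) * (xj - xi)
      inside[cross] <- xor(inside[cross], pts[cross, 1] < xc)
    }
    j <- i
  }
  inside
}
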