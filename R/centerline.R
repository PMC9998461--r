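#' Extract epithelium centerlines
#'
#' Each 8-connected component of the mask is reduced to its morphological
#' skeleton by iterative thinning, and the component's centerline is the
#' longest simple path across the skeleton (double breadth-first traversal
#' over the skeleton's spanning tree; exact for tree-shaped skeletons).
#' Because thinning retracts the skeleton from the ribbon ends by about
#' half a thickness, both path ends are then extended along their local
#' direction until they leave the mask, so the centerline spans the full
#' ribbon length. Components whose path is shorter than `min_length`
#' points are dropped.
#'
#' @param mask binary matrix (level-0 orientation: rows = y, cols = x).
#' @param min_length minimum number of path points to keep a component.
#' @return list of centerlines, each an n x 2 matrix of 0-based `(x, y)`
#'   points where consecutive points are 8-neighbours; attribute
#'   `component` holds the component id.
#' @export
extract_centerline <- function(mask, min_length = 15L) {
  if (!any(mask > 0)) return(list())
  lab <- EBImage::bwlabel(mask > 0)
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
    x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
    sub <- matrix(0L, y1 - y0 + 1, x1 - x0 + 1)
    sub[cbind(idx[, 1] - y0 + 1, idx[, 2] - x0 + 1)] <- 1L
    sk <- cg_thin(sub)
    path <- cg_longest_path(sk)
    if (nrow(path) == 0) next
    path[, 1] <- path[, 1] + (x0 - 1)   # back to 0-based mask coords
    path[, 2] <- path[, 2] + (y0 - 1)
    path <- cg_extend_path(path, mask)
    if (nrow(path) < min_length) next
    colnames(path) <- c("x", "y")
    attr(path, "component") <- k
    out[[length(out) + 1]] <- path
  }
  out
}

# extend both path ends along their local direction while still on mask
cg_extend_path <- function(path, mask) {
  H <- nrow(mask); W <- ncol(mask)
  step_of <- function(d) {
    d <- d / max(abs(d), 1e-9)
    c(ifelse(abs(d[1]) > 0.38, sign(d[1]), 0),
      ifelse(abs(d[2]) > 0.38, sign(d[2]), 0))
  }
  extend <- function(p, head) {
    n <- nrow(p)
    if (n < 3) return(p)
    k <- min(8L, n - 1L)
    d <- if (head) p[1, ] - p[1 + k, ] else p[n, ] - p[n - k, ]
    s <- step_of(d)
    if (all(s == 0)) return(p)
    cur <- if (head) p[1, ] else p[n, ]
    add <- NULL
    for (i in seq_len(max(H, W))) {
      cur <- cur + s
      if (cur[1] < 0 || cur[1] >= W || cur[2] < 0 || cur[2] >= H) break
      if (mask[cur[2] + 1, cur[1] + 1] <= 0) break
      add <- rbind(add, cur)
    }
    if (is.null(add)) return(p)
    if (head) rbind(add[rev(seq_len(nrow(add))), , drop = FALSE], p)
    else rbind(p, add)
  }
  extend(extend(path, head = TRUE), head = FALSE)
}

#' Sample tile centers along a centerline
#'
#' Walks the path from its start, emitting the start point and then one
#' point each time the cumulative advance along the dominant axis since
#' the last emission reaches `interval`. The dominant axis is x unless the
#' path's overall extent is larger in y (vertical ribbons), in which case
#' the same rule is applied to the y-advance and the result carries
#' attribute `axis = "y"`. Every path yields at least one center.
#'
#' @param path an n x 2 centerline matrix of `(x, y)` points.
#' @param interval emission interval in path pixel units (256 by default:
#'   at 20x this gives 50 percent overlap between 512-px tiles).
#' @return m x 2 matrix of center points, attribute `axis`.
#' @export
sample_tile_centers <- function(path, interval = 256) {
  stopifnot(nrow(path) >= 1, interval > 0)
  ax <- if (abs(path[nrow(path), 2] - path[1, 2]) >
            abs(path[nrow(path), 1] - path[1, 1])) 2L else 1L
  keep <- 1L
  acc <- 0
  if (nrow(path) > 1) {
    adv <- abs(diff(path[, ax]))
    for (i in seq_along(adv)) {
      acc <- acc + adv[i]
      if (acc >= interval) {
        keep <- c(keep, i + 1L)
        acc <- 0
      }
    }
  }
  out <- path[keep, , drop = FALSE]
  attr(out, "axis") <- c("x", "y")[ax]
  out
}

#' Extract tiles at 20x around level-0 centers
#'
#' Tiles are read from the pyramid level whose downsample equals
#' `base_magnification / 20` (factor 2 for a 40x scan), centred on the
#' given level-0 points. Tiles crossing the slide border are padded with
#' white and flagged.
#'
#' @param slide a [slide_image()].
#' @param centers m x 2 matrix of level-0 `(x, y)` points.
#' @param size tile side in pixels at 20x.
#' @param slide_id,epithelium_id identifiers carried on each tile.
#' @return list of tiles: `list(image, center, size, level, padded,
#'   slide_id, epithelium_id)`.
#' @export
extract_tiles <- function(slide, centers, size = 512L, slide_id = "slide",
                          epithelium_id = 1L) {
  ds_target <- slide$base_magnification / 20
  lev <- match(ds_target, slide$level_downsamples)
  if (is.na(lev)) stop("slide pyramid has no 20x level (downsample ",
                       ds_target, ")")
  d0 <- slide_dims(slide, 1)
  centers <- rbind(centers)
  lapply(seq_len(nrow(centers)), function(i) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    if (cx < 0 || cx >= d0[["width"]] || cy < 0 || cy >= d0[["height"]])
      stop("tile center (", cx, ",", cy, ") outside slide bounds")
    lx <- floor(cx / ds_target) - size %/% 2
    ly <- floor(cy / ds_target) - size %/% 2
    img <- read_region(slide, lev, lx, ly, size, size)
    list(image = img, center = c(x = cx, y = cy), size = size, level = lev,
         padded = attr(img, "padded"), slide_id = slide_id,
         epithelium_id = epithelium_id)
  })
}

#' Tile a slide along its epithelium centerlines
#'
#' Composition used by both training and inference: centerlines of the
#' level-0 epithelium mask, centers sampled every `interval` 20x pixels
#' (i.e. `interval * downsample` level-0 pixels), tiles read at 20x.
#'
#' @param slide a [slide_image()].
#' @param mask level-0 epithelium mask.
#' @param size tile side at 20x.
#' @param interval center spacing in 20x pixels.
#' @param min_length see [extract_centerline()].
#' @param slide_id identifier stamped on the tiles.
#' @return list of tiles (possibly empty).
#' @export
tile_epithelium <- function(slide, mask, size = 512L, interval = 256,
                            min_length = 15L, slide_id = "slide") {
  ds <- slide$base_magnification / 20
  paths <- extract_centerline(mask, min_length)
  tiles <- list()
  for (k in seq_along(paths)) {
    centers <- sample_tile_centers(paths[[k]], interval * ds)
    tiles <- c(tiles, extract_tiles(slide, centers, size, slide_id,
                                    epithelium_id = k))
  }
  tiles
}
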