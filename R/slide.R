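#' In-memory slide with a magnification pyramid
#'
#' Wraps an RGB array as a pyramidal slide: level 0 is the native scan
#' (40x by convention) and each further level halves the resolution, so
#' `level_downsamples` are `1, 2, 4, ...`. Coordinates are 0-based with
#' `x` = column and `y` = row, and all boxes are half-open
#' `[x0, x1) x [y0, y1)`.
#'
#' @param image H x W x 3 array in \[0, 1\] (level 0).
#' @param base_magnification objective power of level 0.
#' @param n_levels number of pyramid levels to build.
#' @return an object of class `slide_image`.
#' @export
slide_image <- function(image, base_magnification = 40, n_levels = 3L) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, n_levels >= 1)
  levels <- vector("list", n_levels)
  levels[[1]] <- image
  for (k in seq_len(n_levels - 1))
    levels[[k + 1]] <- cg_downsample2(levels[[k]])
  structure(list(levels = levels,
                 base_magnification = base_magnification,
                 level_downsamples = 2^(0:(n_levels - 1))),
            class = "slide_image")
}

#' @rdname slide_image
#' @param path a PNG file holding the level-0 image.
#' @param ... passed on to `slide_image()`.
#' @export
slide_from_png <- function(path, ...) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3]
  slide_image(x, ...)
}

#' @rdname slide_image
#' @param slide a `slide_image`.
#' @param level pyramid level (1-based index into the pyramid).
#' @export
slide_dims <- function(slide, level = 1L) {
  d <- dim(slide$levels[[level]])
  c(width = d[2], height = d[1])
}

# mean-of-4 downsampling by a factor of 2 (odd trailing row/col dropped)
cg_downsample2 <- function(x) {
  H <- dim(x)[1] %/% 2 * 2; W <- dim(x)[2] %/% 2 * 2
  x <- x[seq_len(H), seq_len(W), , drop = FALSE]
  (x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
   x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
   x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
   x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
}

#' Read a region from a slide level
#'
#' Regions extending past the slide bounds are padded with white and the
#' result carries attribute `padded = TRUE`.
#'
#' @param slide a [slide_image()].
#' @param level pyramid level (1 = level 0 of the scan).
#' @param x,y 0-based top-left corner at that level.
#' @param w,h region size in pixels at that level.
#' @export
read_region <- function(slide, level, x, y, w, h) {
  img <- slide$levels[[level]]
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- array(1, c(h, w, 3))
  sx0 <- max(0, x); sy0 <- max(0, y)
  sx1 <- min(W, x + w); sy1 <- min(H, y + h)
  padded <- sx0 > x || sy0 > y || sx1 < x + w || sy1 < y + h
  if (sx1 > sx0 && sy1 > sy0)
    out[(sy0 - y + 1):(sy1 - y), (sx0 - x + 1):(sx1 - x), ] <-
      img[(sy0 + 1):sy1, (sx0 + 1):sx1, , drop = FALSE]
  else padded <- TRUE
  attr(out, "padded") <- padded
  out
}

#' @export
print.slide_image <- function(x, ...) {
  d <- slide_dims(x, 1)
  cat(sprintf("slide_image %dx%d px, %dx base magnification, %d levels\n",
              d[1], d[2], x$base_magnification, length(x$levels)))
  invisible(x)
}
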