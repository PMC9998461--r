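test_that("otsu mask finds dark tissue on a light background", {
  white <- array(1, c(32, 32, 3))
  expect_equal(sum(otsu_tissue_mask(white)), 0)

  img <- array(0.95, c(300, 300, 3))
  img[101:200, 51:150, ] <- 0.3
  m <- otsu_tissue_mask(img)
  truth <- matrix(0L, 300, 300); truth[101:200, 51:150] <- 1L
  iou <- sum(m & truth) / sum(m | truth)
  expect_gte(iou, 0.95)
})

test_that("otsu threshold matches exhaustive between-class-variance search", {
  # maximising set of cuts over all 256 bins: between two well-separated
  # modes every empty bin attains the same variance, so the exhaustive
  # answer is an interval and the threshold must land inside it
  otsu_brute_range <- function(g) {
    counts <- tabulate(pmin(255, floor(g * 256)) + 1, 256)
    p <- counts / sum(counts)
    mu <- cumsum(p * (seq_len(256) - 1))
    w <- cumsum(p)
    bcv <- (mu[256] * w - mu)^2 / (w * (1 - w))
    bcv[!is.finite(bcv)] <- 0
    best <- which(bcv >= max(bcv) - 1e-9 * max(bcv))
    range(best - 1, best) / 256
  }
  set.seed(3)
  for (sds in list(c(0.05, 0.05), c(0.12, 0.1), c(0.18, 0.15))) {
    g <- matrix(c(rnorm(4000, 0.3, sds[1]), rnorm(6000, 0.8, sds[2])),
                100, 100)
    g <- pmin(pmax(g, 0), 1)
    thr <- EBImage::otsu(g, range = c(0, 1), levels = 256)
    rng <- otsu_brute_range(g)
    expect_gte(thr, rng[1] - 1 / 256 - 1e-9)
    expect_lte(thr, rng[2] + 1 / 256 + 1e-9)
  }
})

test_that("fragment detection separates blobs and honours min_area", {
  m <- matrix(0L, 200, 200)
  m[20:60, 20:80] <- 1L
  m[120:180, 100:190] <- 1L
  boxes <- detect_fragments(m, min_area = 100)
  expect_length(boxes, 2)
  expect_equal(boxes[[1]][["y0"]], 19)   # sorted by (y0, x0), 0-based
  m[100, 100] <- 1L                      # speck below min_area
  expect_length(detect_fragments(m, min_area = 100), 2)
})

test_that("fragment detection on phantoms recovers the generator's layout", {
  for (seed in c(7, 11)) {
    ph <- cached_phantom("HSIL", seed)
    boxes <- find_tissue_fragments(slide_image(ph$image))
    expect_length(boxes, length(ph$fragments))
    truth <- lapply(ph$fragments, `[[`, "box")
    ord <- order(vapply(truth, `[`, numeric(1), 2),
                 vapply(truth, `[`, numeric(1), 1))
    for (k in seq_along(boxes)) {
      tb <- truth[[ord[k]]]; db <- boxes[[k]]
      ix <- max(0, min(tb[3], db[["x1"]]) - max(tb[1], db[["x0"]]))
      iy <- max(0, min(tb[4], db[["y1"]]) - max(tb[2], db[["y0"]]))
      cover <- ix * iy / ((tb[3] - tb[1]) * (tb[4] - tb[2]))
      expect_gte(cover, 0.9)
    }
  }
})

test_that("crop_and_resize records exact scale factors and inverts", {
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  sl <- slide_image(img, n_levels = 1)
  cr <- crop_and_resize(sl, c(0, 0, 512, 512), size = 1024)
  expect_equal(cr$scale_x, 0.5)
  expect_equal(cr$scale_y, 0.5)
  # non-square: padded to square then scaled
  cr2 <- crop_and_resize(sl, c(0, 0, 512, 256), size = 256)
  expect_equal(cr2$pad_side, 512)
  expect_equal(cr2$scale_x, 2)
  # round-trip of the output center through the recorded transform
  ctr <- crop_to_level0(cr2, c(128, 128))
  expect_lte(abs(ctr[1] - 256), 1)
  expect_lte(abs(ctr[2] - 256), 1)
  expect_error(crop_and_resize(sl, c(10, 10, 10, 50)), "degenerate")
})

test_that("masks round-trip bit-exactly through PNG", {
  set.seed(21)
  m <- matrix(rbinom(64 * 48, 1, 0.4), 48, 64)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(m, f)
  expect_identical(read_mask(f), matrix(as.integer(m), 48, 64))
})

test_that("polygon rasterization counts pixel centers with even-odd fill", {
  sq <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), 4, 2, byrow = TRUE)
  m <- rasterize_polygons(list(sq), c(20, 20))
  expect_equal(sum(m), 100)
  expect_equal(sum(m[1:10, 1:10]), 100)   # exactly the first 10x10 block
  # empty FeatureCollection
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(list(), f)
  expect_equal(sum(rasterize_polygons(read_annotations(f), c(20, 20))), 0)
})

test_that("annotations round-trip through GeoJSON and reject malformed input", {
  ann <- list(list(polygon = matrix(c(1, 2, 30, 4, 15, 25), 3, 2),
                   label = "LSIL", role = "epithelium"),
              list(polygon = matrix(c(5, 5, 9, 5, 9, 9), 3, 2, byrow = TRUE),
                   label = "HSIL", role = "roi"))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(ann, f)
  got <- read_annotations(f)
  expect_length(got, 2)
  expect_equal(got[[1]]$polygon, ann[[1]]$polygon)
  expect_equal(got[[2]]$label, "HSIL")
  expect_equal(got[[2]]$role, "roi")
  bad <- withr::local_tempfile(fileext = ".geojson")
  writeLines("{not json", bad)
  expect_error(read_annotations(bad), "malformed GeoJSON")
  writeLines('{"type": "Point"}', bad)
  expect_error(read_annotations(bad), "FeatureCollection")
})

test_that("slide regions pad with white outside the bounds", {
  img <- array(0.2, c(64, 64, 3))
  sl <- slide_image(img, n_levels = 2)
  r <- read_region(sl, 1, -16, -16, 32, 32)
  expect_true(attr(r, "padded"))
  expect_equal(r[1, 1, 1], 1)        # padding
  expect_equal(r[32, 32, 1], 0.2)    # in-bounds corner
  r2 <- read_region(sl, 1, 16, 16, 32, 32)
  expect_false(attr(r2, "padded"))
  expect_equal(slide_dims(sl, 2), c(width = 32, height = 32))
})
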