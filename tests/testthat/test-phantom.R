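test_that("phantom generation is deterministic and honours the label contract", {
  cfg <- phantom_cfg_small()
  a <- cached_phantom("HSIL", 7)
  b <- generate_phantom_slide(cfg, "HSIL", 7)
  expect_identical(a$image, b$image)
  expect_identical(a$epithelium_mask, b$epithelium_mask)

  others <- cached_phantom("OTHERS", 1)
  expect_equal(sum(others$epithelium_mask), 0)   # no epithelium at all
  expect_gt(length(others$fragments), 0)         # but tissue is present

  # slide label is the worst region label present
  for (s in 1:6) {
    ph <- cached_phantom(c("LSIL", "HSIL")[s %% 2 + 1], 30 + s)
    labs <- ordinal_label(vapply(ph$region_labels, `[[`, character(1),
                                 "label"))
    expect_equal(max(labs), ordinal_label(ph$slide_label))
  }
})

test_that("ribbon texture encodes the grade: basal-band nuclei for LSIL", {
  ph <- cached_phantom("LSIL", 3)
  basal <- ph$band_map == 1
  upper <- ph$band_map == 3
  frac_basal <- mean(ph$nucleus_map[basal])
  frac_upper <- mean(ph$nucleus_map[upper])
  expect_gt(frac_basal, frac_upper)
  expect_gt(frac_basal, 2 * frac_upper)   # clearly denser, not borderline
  # HSIL fills the thickness: upper-third density comparable to basal
  hs <- cached_phantom("HSIL", 3)
  expect_gt(mean(hs$nucleus_map[hs$band_map == 3]),
            0.5 * mean(hs$nucleus_map[hs$band_map == 1]))
})

test_that("annotation polygons rasterize inside the epithelium mask", {
  for (seed in c(3, 8)) {
    ph <- cached_phantom("HSIL", seed)
    r <- rasterize_polygons(c(ph$region_labels, ph$rois),
                            dim(ph$epithelium_mask))
    expect_equal(sum(r & !ph$epithelium_mask), 0)
    expect_gt(sum(r), 0)
  }
})

test_that("class counts follow largest-remainder apportionment", {
  mix <- c(NNeo = 0.3, LSIL = 0.4, HSIL = 0.2, OTHERS = 0.1)
  expect_equal(cervigrade:::cg_apportion(10, mix),
               c(NNeo = 3L, LSIL = 4L, HSIL = 2L, OTHERS = 1L))
  # independent oracle: largest remainder by direct search
  apportion_oracle <- function(n, mix) {
    q <- n * mix
    base <- floor(q)
    r <- q - base
    for (k in seq_len(n - sum(base)))
      { i <- which.max(r); base[i] <- base[i] + 1; r[i] <- -1 }
    as.integer(base)
  }
  set.seed(5)
  for (i in 1:25) {
    p <- runif(4); p <- p / sum(p); names(p) <- cg_all_classes()
    n <- sample(1:40, 1)
    got <- cervigrade:::cg_apportion(n, p)
    expect_equal(sum(got), n)
    expect_equal(unname(got), apportion_oracle(n, p))
  }
})

test_that("datasets on disk are complete and reproducible", {
  cfg <- phantom_config(image_size = c(320, 256),
                        fragments_per_slide = c(1, 1),
                        ribbon_thickness = c(16, 24), seed = 9)
  d1 <- withr::local_tempdir()
  mf <- generate_phantom_dataset(4, cfg, d1)
  expect_equal(nrow(mf), 4)
  expect_true(all(file.exists(mf$path)))
  expect_true(all(file.exists(mf$mask_path)))
  expect_true(all(file.exists(mf$annotation_path)))
  # masks round-trip the generator's ground truth labels
  lab_of <- function(i) mf$label[i]
  for (i in seq_len(4)) {
    m <- read_mask(mf$mask_path[i])
    if (lab_of(i) == "OTHERS") expect_equal(sum(m), 0) else
      expect_gt(sum(m), 0)
  }
  d2 <- withr::local_tempdir()
  generate_phantom_dataset(4, cfg, d2)
  for (f in basename(mf$path))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # single slide: exactly one image/mask/annotation triple
  d3 <- withr::local_tempdir()
  m1 <- generate_phantom_dataset(1, cfg, d3)
  expect_equal(nrow(m1), 1)
  expect_equal(length(list.files(d3, pattern = "png$|geojson$")), 3)
})

test_that("grades are linearly separable on epithelium-masked tile intensity", {
  phantoms <- c(lapply(1:5, function(s) cached_phantom("NNeo", 50 + s)),
                lapply(1:5, function(s) cached_phantom("HSIL", 50 + s)))
  vals <- NULL; labs <- NULL
  for (ph in phantoms) {
    sl <- slide_image(ph$image)
    tiles <- tile_epithelium(sl, ph$epithelium_mask, size = 96,
                             interval = 48,
                             slide_id = ph$manifest_row$slide_id)
    mask_half <- ph$epithelium_mask[seq(1, nrow(ph$epithelium_mask), 2),
                                    seq(1, ncol(ph$epithelium_mask), 2)]
    for (t in tiles) {
      cx <- floor(t$center[1] / 2); cy <- floor(t$center[2] / 2)
      x0 <- cx - t$size %/% 2; y0 <- cy - t$size %/% 2
      xs <- pmax(1, x0 + 1):pmin(ncol(mask_half), x0 + t$size)
      ys <- pmax(1, y0 + 1):pmin(nrow(mask_half), y0 + t$size)
      sub <- mask_half[ys, xs]
      gray <- 0.299 * t$image[, , 1] + 0.587 * t$image[, , 2] +
        0.114 * t$image[, , 3]
      gsub <- gray[ys - y0, xs - x0]
      if (sum(sub) < 50) next
      lab <- ph$label_map[floor(t$center[2]) + 1, floor(t$center[1]) + 1]
      if (!lab %in% c(1L, 3L)) next    # tiles on NNeo or HSIL ribbons only
      vals <- c(vals, mean(gsub[sub > 0]))
      labs <- c(labs, lab)
    }
  }
  expect_gt(length(vals), 40)
  # 1-D linear classifier: optimal threshold on the training values
  ths <- sort(unique(vals))
  acc <- max(vapply(ths, function(th)
    mean((vals <= th) == (labs == 3)), numeric(1)))
  expect_gt(acc, 0.9)
})
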