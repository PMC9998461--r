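#' Phantom slide configuration
#'
#' Parameters of the synthetic slide generator. A phantom slide emulates the
#' structure the pipeline exploits on real scans: one to four tissue
#' fragments of low-frequency pink stroma on a white background, each
#' (except on non-representative slides) carrying a thin curved epithelium
#' ribbon whose nuclear texture encodes the grade — sparse dark nuclei
#' confined to a thin basal band (NNeo), dense nuclei in the basal third
#' plus perinuclear vacuole rings above (LSIL), or dense nuclei across the
#' full ribbon thickness (HSIL). The generator also returns per-pixel
#' ground truth (epithelium mask, thickness-band map, region-label map)
#' used by the tests as oracles.
#'
#' @param image_size slide size in pixels, `c(width, height)`. The default
#'   2048 x 1536 stands for a level-0 (40x) scan overview.
#' @param fragments_per_slide integer range `c(min, max)` of tissue
#'   fragments per slide.
#' @param ribbon_thickness pixel range `c(min, max)` of the nominal ribbon
#'   thickness; the realised thickness varies +/-25 percent along the
#'   ribbon length.
#' @param class_mix named proportions over `NNeo`, `LSIL`, `HSIL`,
#'   `OTHERS`; must sum to 1.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param seed integer seed; all randomness of a slide flows through one
#'   generator seeded per slide, never through global state.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(2048, 1536),
                           fragments_per_slide = c(1, 4),
                           ribbon_thickness = c(40, 90),
                           class_mix = c(NNeo = 0.3, LSIL = 0.4,
                                         HSIL = 0.2, OTHERS = 0.1),
                           noise_sd = 0.02,
                           seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 64),
            length(fragments_per_slide) == 2,
            fragments_per_slide[1] >= 1,
            fragments_per_slide[1] <= fragments_per_slide[2],
            fragments_per_slide[2] <= 4,
            length(ribbon_thickness) == 2,
            ribbon_thickness[1] > 0,
            ribbon_thickness[1] <= ribbon_thickness[2],
            noise_sd >= 0)
  stopifnot(all(cg_all_classes() %in% names(class_mix)))
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1")
  # worst-case fragment minor axis: 2x2 cell grid, minor semi-axis >= 0.24
  # of the smaller cell side; the thickest ribbon (+25%) must fit inside
  cell <- image_size / ifelse(fragments_per_slide[2] > 1, 2, 1)
  min_minor_axis <- 0.48 * min(cell)
  if (ribbon_thickness[2] * 1.25 >= min_minor_axis)
    stop("ribbon_thickness too large for the fragment minor axis (max ",
         round(min_minor_axis / 1.25), " px for this image size)")
  structure(list(image_size = as.integer(image_size),
                 fragments_per_slide = as.integer(fragments_per_slide),
                 ribbon_thickness = ribbon_thickness,
                 class_mix = class_mix[cg_all_classes()],
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# smooth periodic wiggle used for ribbon radius and thickness modulation
cg_wiggle <- function(phi, n_terms, amp) {
  out <- numeric(length(phi))
  for (k in seq_len(n_terms))
    out <- out + runif(1, 0, amp / n_terms) * sin(k * phi + runif(1, 0, 2 * pi))
  out
}

#' Generate one phantom slide
#'
#' Deterministic for identical `(config, slide_label, seed)`. Slides
#' labelled `"OTHERS"` contain tissue fragments but zero epithelium pixels.
#' For graded slides every fragment carries a ribbon; one ribbon carries
#' the slide label and the remaining ribbons draw labels no worse than it,
#' so the slide label is the maximum region label present (the
#' multiple-instance assumption).
#'
#' @param config a [phantom_config()].
#' @param slide_label `"NNeo"`, `"LSIL"`, `"HSIL"` or `"OTHERS"`.
#' @param seed per-slide seed (defaults to `config$seed`).
#' @return an object of class `phantom_slide` with fields `image`
#'   (H x W x 3 array in \[0,1\]), `epithelium_mask`, `band_map` (1 basal /
#'   2 middle / 3 upper third), `nucleus_map`, `label_map` (per-pixel
#'   ordinal region label), `region_labels` (epithelium polygons + labels),
#'   `rois` (small fully-labelled polygons), `fragments` (ellipse
#'   parameters and level-0 bounding boxes), `slide_label`, `manifest_row`.
#' @export
generate_phantom_slide <- function(config, slide_label, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"),
            slide_label %in% cg_all_classes())
  withr::with_seed(as.integer(seed), {
    W <- config$image_size[1]; H <- config$image_size[2]
    img <- array(0.96, c(H, W, 3))
    mask <- matrix(0L, H, W)
    band_map <- matrix(0L, H, W)
    nucleus_map <- matrix(0L, H, W)
    label_map <- matrix(0L, H, W)

    n_frag <- if (config$fragments_per_slide[1] == config$fragments_per_slide[2])
      config$fragments_per_slide[1] else
      sample(config$fragments_per_slide[1]:config$fragments_per_slide[2], 1)
    cells <- cg_fragment_cells(W, H, n_frag)

    fragments <- vector("list", n_frag)
    for (f in seq_len(n_frag)) {
      fragments[[f]] <- cg_paint_fragment(img, cells[[f]])
      img <- fragments[[f]]$img
      fragments[[f]]$img <- NULL
    }

    region_labels <- list(); rois <- list(); ribbons <- list()
    if (slide_label != "OTHERS") {
      lab <- ordinal_label(slide_label)
      frag_labels <- if (lab > 1) sample(1:lab, n_frag, replace = TRUE) else
        rep(1L, n_frag)
      frag_labels[sample.int(n_frag, 1)] <- lab   # worst label must be present
      for (f in seq_len(n_frag)) {
        rb <- cg_paint_ribbon(img, mask, band_map, nucleus_map, label_map,
                              fragments[[f]], frag_labels[f], config)
        img <- rb$img; mask <- rb$mask; band_map <- rb$band_map
        nucleus_map <- rb$nucleus_map; label_map <- rb$label_map
        region_labels[[f]] <- list(polygon = rb$polygon,
                                   label = label_name(frag_labels[f]),
                                   role = "epithelium")
        rois <- c(rois, rb$rois)
        ribbons[[f]] <- list(spline = rb$spline, thickness = rb$thickness,
                             label = label_name(frag_labels[f]))
      }
    }

    if (config$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, config$noise_sd), dim(img))
    img[img < 0] <- 0; img[img > 1] <- 1

    structure(list(image = img, epithelium_mask = mask, band_map = band_map,
                   nucleus_map = nucleus_map, label_map = label_map,
                   region_labels = region_labels, rois = rois,
                   ribbons = ribbons,
                   fragments = fragments, slide_label = slide_label,
                   config = config, seed = as.integer(seed),
                   manifest_row = data.frame(slide_id = sprintf(
                     "phantom_s%d_%s", as.integer(seed), slide_label),
                     label = slide_label, seed = as.integer(seed))),
              class = "phantom_slide")
  })
}

# cell layout for up to 4 non-overlapping fragments
cg_fragment_cells <- function(W, H, n) {
  if (n == 1) return(list(c(0, 0, W, H)))
  if (n == 2) {
    if (W >= H) return(list(c(0, 0, W / 2, H), c(W / 2, 0, W, H)))
    return(list(c(0, 0, W, H / 2), c(0, H / 2, W, H)))
  }
  grid <- list(c(0, 0, W / 2, H / 2), c(W / 2, 0, W, H / 2),
               c(0, H / 2, W / 2, H), c(W / 2, H / 2, W, H))
  grid[sort(sample.int(4, n))]
}

# fill one elliptical stroma fragment with a low-frequency pink texture
cg_paint_fragment <- function(img, cell) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cw <- cell[3] - cell[1]; ch <- cell[4] - cell[2]
  cx <- (cell[1] + cell[3]) / 2 + runif(1, -0.04, 0.04) * cw
  cy <- (cell[2] + cell[4]) / 2 + runif(1, -0.04, 0.04) * ch
  rx <- runif(1, 0.60, 0.82) * cw / 2
  ry <- runif(1, 0.48, 0.66) * ch / 2
  theta <- runif(1, -0.4, 0.4)
  x0 <- max(0L, floor(cx - max(rx, ry))); x1 <- min(W, ceiling(cx + max(rx, ry)))
  y0 <- max(0L, floor(cy - max(rx, ry))); y1 <- min(H, ceiling(cy + max(rx, ry)))
  xs <- (x0:(x1 - 1)) + 0.5; ys <- (y0:(y1 - 1)) + 0.5
  gx <- outer(rep(1, length(ys)), xs) - cx
  gy <- outer(ys, rep(1, length(xs))) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  f1 <- runif(2, 0.5, 2) / 100; f2 <- runif(2, 2, 6) / 100
  tex <- 0.030 * sin(f1[1] * gx + f1[2] * gy + runif(1, 0, 6)) +
         0.018 * sin(f2[1] * gx - f2[2] * gy + runif(1, 0, 6))
  base <- c(0.88, 0.62, 0.72)   # eosin-pink stroma, clearly darker than glass
  idx2 <- which(inside, arr.ind = TRUE)
  iy <- y0 + idx2[, 1]; ix <- x0 + idx2[, 2]   # 1-based rows/cols
  for (ch3 in 1:3)
    img[cbind(iy, ix, ch3)] <- base[ch3] + tex[idx2] * c(1, 1.4, 0.8)[ch3]
  # tight bounding box of the rotated ellipse
  hx <- sqrt((rx * cos(theta))^2 + (ry * sin(theta))^2)
  hy <- sqrt((rx * sin(theta))^2 + (ry * cos(theta))^2)
  list(img = img, center = c(cx, cy), rx = rx, ry = ry, theta = theta,
       box = c(max(0, floor(cx - hx)), max(0, floor(cy - hy)),
               min(W, ceiling(cx + hx)), min(H, ceiling(cy + hy))))
}

# paint one epithelium ribbon along a wiggly arc near the fragment edge and
# return its ground truth (updated maps, outline polygon, ROI polygons)
cg_paint_ribbon <- function(img, mask, band_map, nucleus_map, label_map,
                            frag, label, config) {
  H <- dim(img)[1]; W <- dim(img)[2]
  phi0 <- runif(1, 0, 2 * pi)
  dphi <- runif(1, 2.8, 4.9)
  nphi <- 720
  phi <- seq(phi0, phi0 + dphi, length.out = nphi)
  rho <- 0.80 + cg_wiggle(phi, 3, 0.10)
  ct <- cos(frag$theta); st <- sin(frag$theta)
  ex <- frag$rx * rho * cos(phi); ey <- frag$ry * rho * sin(phi)
  cx <- frag$center[1] + ex * ct - ey * st
  cy <- frag$center[2] + ex * st + ey * ct
  # resample to ~0.5 px arc-length steps
  seg <- sqrt(diff(cx)^2 + diff(cy)^2)
  arc <- c(0, cumsum(seg))
  ns <- max(64L, ceiling(arc[nphi] / 0.5))
  s <- seq(0, arc[nphi], length.out = ns)
  cx <- approx(arc, cx, s)$y; cy <- approx(arc, cy, s)$y
  # tangent/normal, normal oriented away from the fragment center
  tx <- c(cx[2] - cx[1], diff(cx)); ty <- c(cy[2] - cy[1], diff(cy))
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  flip <- sign((cx - frag$center[1]) * nx + (cy - frag$center[2]) * ny)
  flip[flip == 0] <- 1
  nx <- nx * flip; ny <- ny * flip   # +u points outward; -u is the basal side
  t0 <- runif(1, config$ribbon_thickness[1], config$ribbon_thickness[2])
  tt <- t0 * (1 + 0.25 * sin(runif(1, 1, 3) * seq(0, 2 * pi, length.out = ns) +
                             runif(1, 0, 2 * pi)))
  base_col <- c(0.80, 0.72, 0.86)
  vs <- seq(0, 1, by = 0.5 / (max(tt) + 1))
  for (v in vs) {
    u <- (v - 0.5) * tt
    px <- floor(cx + u * nx); py <- floor(cy + u * ny)
    ok <- px >= 0 & px < W & py >= 0 & py < H
    idx <- py[ok] + px[ok] * H + 1L
    mask[idx] <- 1L
    band_map[idx] <- pmin(3L, floor(v * 3) + 1L)   # band 1 = basal (inner)
    label_map[idx] <- label
    shade <- 1 - 0.10 * (1 - v)
    for (ch3 in 1:3) img[idx + (ch3 - 1) * H * W] <- base_col[ch3] * shade
  }

  cls <- label_name(label)
  area <- sum(tt) * 0.5 * 2   # ~ribbon area in px (ds = s step)
  ds <- s[2] - s[1]
  draw_nuclei <- function(v_lo, v_hi, rate) {
    n <- rpois(1, max(0, rate * mean(tt) * (v_hi - v_lo) * arc[nphi]))
    if (n == 0) return(NULL)
    si <- sample.int(ns, n, replace = TRUE)
    v <- runif(n, v_lo, v_hi)
    u <- (v - 0.5) * tt[si]
    cbind(cx[si] + u * nx[si], cy[si] + u * ny[si])
  }
  cfg_nuc <- switch(cls,
    NNeo = list(c(0.00, 0.15, 0.030), c(0.15, 1.00, 0.0015)),
    LSIL = list(c(0.00, 0.33, 0.030), c(0.33, 1.00, 0.0030)),
    HSIL = list(c(0.00, 1.00, 0.028)))
  nuc <- do.call(rbind, lapply(cfg_nuc, function(p)
    draw_nuclei(p[1], p[2], p[3])))
  if (!is.null(nuc) && nrow(nuc) > 0) {
    r <- runif(nrow(nuc), 1.6, 2.6)
    off <- expand.grid(dx = -3:3, dy = -3:3)
    nuc_col <- c(0.30, 0.18, 0.45)
    for (k in seq_len(nrow(off))) {
      d2 <- off$dx[k]^2 + off$dy[k]^2
      sel <- d2 <= r^2
      if (!any(sel)) next
      px <- floor(nuc[sel, 1]) + off$dx[k]; py <- floor(nuc[sel, 2]) + off$dy[k]
      ok <- px >= 0 & px < W & py >= 0 & py < H
      idx <- py[ok] + px[ok] * H + 1L
      idx <- idx[mask[idx] == 1L]          # nuclei stay inside the epithelium
      nucleus_map[idx] <- 1L
      for (ch3 in 1:3) img[idx + (ch3 - 1) * H * W] <- nuc_col[ch3]
    }
  }
  if (cls == "LSIL") {                     # koilocyte-like vacuole rings
    vac <- draw_nuclei(0.45, 0.95, 0.0025)
    if (!is.null(vac) && nrow(vac) > 0) {
      rv <- runif(nrow(vac), 3.5, 5.5)
      off <- expand.grid(dx = -6:6, dy = -6:6)
      for (k in seq_len(nrow(off))) {
        d <- sqrt(off$dx[k]^2 + off$dy[k]^2)
        sel <- d <= rv & d >= rv - 1.6
        if (!any(sel)) next
        px <- floor(vac[sel, 1]) + off$dx[k]; py <- floor(vac[sel, 2]) + off$dy[k]
        ok <- px >= 0 & px < W & py >= 0 & py < H
        idx <- py[ok] + px[ok] * H + 1L
        idx <- idx[mask[idx] == 1L]
        for (ch3 in 1:3)
          img[idx + (ch3 - 1) * H * W] <- c(0.93, 0.90, 0.96)[ch3]
      }
    }
  }

  # outline polygon (inset so its rasterization stays inside the mask)
  pick <- unique(c(seq(1, ns, by = max(1, floor(ns / 80))), ns))
  inset <- pmax(tt / 2 - 1.5, 0.5)
  poly <- rbind(cbind(cx[pick] + inset[pick] * nx[pick],
                      cy[pick] + inset[pick] * ny[pick]),
                cbind(rev(cx[pick] - inset[pick] * nx[pick]),
                      rev(cy[pick] - inset[pick] * ny[pick])))
  # three fully-labelled ROI quads per ribbon, centred on the ribbon axis
  rois <- list()
  for (q in 1:3) {
    c0 <- round(ns * c(0.22, 0.5, 0.78)[q] + runif(1, -0.04, 0.04) * ns)
    half <- min(ns - c0 - 1, c0 - 1, max(8, floor(170 / ds)))
    ii <- round(c(c0 - half, c0 + half))
    jj <- unique(round(seq(ii[1], ii[2], length.out = 24)))
    uu <- tt[jj] / 4
    quad <- rbind(cbind(cx[jj] + uu * nx[jj], cy[jj] + uu * ny[jj]),
                  cbind(rev(cx[jj] - uu * nx[jj]), rev(cy[jj] - uu * ny[jj])))
    rois[[q]] <- list(polygon = quad, label = cls, role = "roi")
  }
  list(img = img, mask = mask, band_map = band_map,
       nucleus_map = nucleus_map, label_map = label_map,
       polygon = poly, rois = rois,
       spline = cbind(x = cx, y = cy), thickness = tt)
}

# largest-remainder apportionment of n items to the class_mix proportions
cg_apportion <- function(n, mix) {
  quota <- n * mix
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(mix))
}

#' Generate a phantom dataset on disk
#'
#' Writes one PNG image, one 0/255 mask PNG and one GeoJSON annotation file
#' per slide, plus a `manifest.csv` with columns
#' `slide_id, path, mask_path, annotation_path, label, seed`. Class counts
#' follow `config$class_mix` by largest-remainder apportionment, and the
#' label sequence plus per-slide seeds are drawn from `config$seed`, so a
#' rerun with the same configuration reproduces the dataset bit for bit.
#'
#' @param n_slides number of slides (>= 1).
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame, invisibly.
#' @export
generate_phantom_dataset <- function(n_slides, config, out_dir) {
  stopifnot(n_slides >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- cg_apportion(n_slides, config$class_mix)
  plan <- withr::with_seed(config$seed, {
    labels <- sample(rep(names(counts), counts))
    data.frame(label = labels, seed = sample.int(2^30, n_slides))
  })
  rows <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    ph <- generate_phantom_slide(config, plan$label[i], plan$seed[i])
    id <- sprintf("slide_%03d", i)
    paths <- file.path(out_dir, paste0(id, c(".png", "_mask.png", ".geojson")))
    png::writePNG(aperm(ph$image, c(1, 2, 3)), paths[1])
    write_mask(ph$epithelium_mask, paths[2])
    write_annotations(c(ph$region_labels, ph$rois), paths[3])
    rows[[i]] <- data.frame(slide_id = id, path = paths[1],
                            mask_path = paths[2], annotation_path = paths[3],
                            label = plan$label[i], seed = plan$seed[i])
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
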