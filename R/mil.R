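#' Quadratic kappa weight matrix
#'
#' `w[y, yhat] = (y - yhat)^2 / (n - 1)^2`: zero diagonal, symmetric,
#' values in \[0, 1\].
#'
#' @param n number of ordered classes (>= 2).
#' @export
qwk_weight_matrix <- function(n) {
  if (n < 2) stop("at least 2 classes required")
  outer(seq_len(n), seq_len(n), function(y, yh) (y - yh)^2) / (n - 1)^2
}

#' Expected severity score of a class distribution
#'
#' `sum(i * p_i)` over the ordered classes — the ranking score used to
#' pick the worst tile of a bag. Lies in `[1, n]` and is monotone under
#' shifts of probability mass toward more severe classes.
#'
#' @param p probability vector (sums to 1) over the ordered classes.
#' @export
expected_score <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-6, all(p >= -1e-9))
  sum(seq_along(p) * p)
}

#' Ordinal quadratic-weighted-kappa loss
#'
#' Differentiable agreement loss `L = 1 - kappa` over a batch: the
#' observed matrix collects soft counts `x[y, yhat] = sum of p_i(yhat)`
#' over batch items with actual label `y`, and the expected matrix is the
#' outer product of the actual and (soft) predicted marginals normalised
#' to the batch size. Perfect one-hot agreement gives loss 0. A batch
#' whose expected disagreement is zero (single class, all mass on it) has
#' no defined chance correction: kappa is set to 0, loss 1, and the
#' result is flagged `degenerate`.
#'
#' @param pred_probs N x n matrix of class probabilities (rows sum to 1).
#' @param labels integer actual classes in `1..n`.
#' @param n number of classes.
#' @return list with `loss`, `kappa`, `observed`, `expected`, `weights`,
#'   `degenerate`.
#' @export
qwk_loss <- function(pred_probs, labels, n = 3L) {
  pred_probs <- rbind(pred_probs)
  stopifnot(nrow(pred_probs) == length(labels), ncol(pred_probs) == n,
            all(labels %in% seq_len(n)))
  w <- qwk_weight_matrix(n)
  x <- matrix(0, n, n)
  for (y in seq_len(n))
    if (any(labels == y))
      x[y, ] <- colSums(pred_probs[labels == y, , drop = FALSE])
  a <- tabulate(labels, n)
  q <- colSums(pred_probs)
  m <- outer(a, q) / length(labels)   # same sum as x
  sm <- sum(w * m)
  if (sm < 1e-12)
    return(list(loss = 1, kappa = 0, observed = x, expected = m,
                weights = w, degenerate = TRUE))
  kappa <- 1 - sum(w * x) / sm
  list(loss = 1 - kappa, kappa = kappa, observed = x, expected = m,
       weights = w, degenerate = FALSE)
}

# analytic gradient of qwk_loss w.r.t. pred_probs (N x n)
cg_qwk_grad <- function(pred_probs, labels, n = 3L) {
  pred_probs <- rbind(pred_probs)
  N <- nrow(pred_probs)
  w <- qwk_weight_matrix(n)
  a <- tabulate(labels, n)
  q <- colSums(pred_probs)
  x <- matrix(0, n, n)
  for (y in seq_len(n))
    if (any(labels == y))
      x[y, ] <- colSums(pred_probs[labels == y, , drop = FALSE])
  sx <- sum(w * x)
  sm <- sum(w * outer(a, q)) / N
  if (sm < 1e-12) return(matrix(0, N, n))
  dsm <- as.numeric(crossprod(w, a)) / N   # d sm / d p_i(j), same for all i
  g <- matrix(0, N, n)
  for (i in seq_len(N))
    g[i, ] <- (w[labels[i], ] * sm - sx * dsm) / sm^2
  g
}

#' Rank a bag's tiles and select the worst
#'
#' All tiles are classified, sorted by decreasing expected severity
#' ([expected_score()]); the bag is represented by the first (worst) tile.
#' Ties break toward the higher HSIL probability, then stable tile order.
#'
#' @param model a classifier (`cg_cls_model` or [oracle_classifier()]).
#' @param bag a tile bag from [build_bags()], or any list of tiles.
#' @return list with `worst_index`, `worst_tile`, `worst_probs`,
#'   `worst_score` and the full `ranking` data frame.
#' @export
rank_and_select <- function(model, bag) {
  tiles <- if (!is.null(bag$tiles)) bag$tiles else bag
  stopifnot(length(tiles) >= 1)
  probs <- classify_tiles(model, tiles)
  scores <- apply(probs, 1, expected_score)
  ord <- order(-scores, -probs[, 3], seq_along(scores))
  list(worst_index = ord[1], worst_tile = tiles[[ord[1]]],
       worst_probs = probs[ord[1], ], worst_score = scores[ord[1]],
       ranking = data.frame(tile = ord, score = scores[ord]))
}

#' Build tile bags at the three supervision levels
#'
#' * `LS` (labelled slides): all tiles of a slide form one bag labelled
#'   with the slide diagnosis.
#' * `AE` (annotated epithelium): the tiles whose centers fall inside one
#'   labelled epithelium polygon form one bag with that label.
#' * `AT` (annotated tiles): each tile whose center falls inside a small
#'   fully-supervised ROI polygon becomes a single-tile bag.
#'
#' Tiles inside polygons labelled `"uncertain"` are excluded everywhere.
#' Slides labelled `"OTHERS"` never contribute bags (the classifier's
#' class set is strictly the three grades).
#'
#' @param manifest data frame with columns `slide_id`, `label`.
#' @param annotations named list (by slide_id) of feature lists as read by
#'   [read_annotations()]; needed for `AE`/`AT`.
#' @param tiles list of tiles (each carrying `slide_id` and `center`).
#' @param supervision subset of `c("LS", "AE", "AT")`.
#' @return list of bags: `list(tiles, label, supervision, bag_id)`.
#' @export
build_bags <- function(manifest, annotations = list(), tiles,
                       supervision = c("LS", "AE", "AT")) {
  supervision <- match.arg(supervision, several.ok = TRUE)
  sid <- vapply(tiles, function(t) t$slide_id, character(1))
  unknown <- setdiff(sid, manifest$slide_id)
  if (length(unknown))
    stop("tiles reference slides missing from the manifest: ",
         paste(unique(unknown), collapse = ", "))
  centers <- do.call(rbind, lapply(tiles, function(t) t$center + 0.5))
  uncertain <- rep(FALSE, length(tiles))
  for (s in names(annotations))
    for (f in annotations[[s]])
      if (identical(f$label, "uncertain")) {
        sel <- sid == s
        if (any(sel))
          uncertain[sel] <- uncertain[sel] |
            cg_points_in_polygon(centers[sel, , drop = FALSE], f$polygon)
      } else if (!f$label %in% cg_classes())
        stop("polygon with unknown label: ", f$label)
  bags <- list()
  if ("LS" %in% supervision) {
    for (s in unique(sid)) {
      lab <- manifest$label[match(s, manifest$slide_id)]
      if (lab == "OTHERS") next
      sel <- which(sid == s & !uncertain)
      if (!length(sel)) next
      bags[[length(bags) + 1]] <- list(tiles = tiles[sel],
                                       label = ordinal_label(lab),
                                       supervision = "LS", bag_id = s)
    }
  }
  for (s in names(annotations)) {
    feats <- annotations[[s]]
    sel_slide <- which(sid == s & !uncertain)
    if (!length(sel_slide)) next
    k <- 0
    for (f in feats) {
      if (identical(f$label, "uncertain")) next
      inside <- sel_slide[cg_points_in_polygon(
        centers[sel_slide, , drop = FALSE], f$polygon)]
      if (!length(inside)) next
      k <- k + 1
      if (f$role == "epithelium" && "AE" %in% supervision) {
        bags[[length(bags) + 1]] <- list(tiles = tiles[inside],
                                         label = ordinal_label(f$label),
                                         supervision = "AE",
                                         bag_id = paste0(s, "_ae", k))
      } else if (f$role == "roi" && "AT" %in% supervision) {
        for (i in inside)
          bags[[length(bags) + 1]] <- list(tiles = tiles[i],
                                           label = ordinal_label(f$label),
                                           supervision = "AT",
                                           bag_id = paste0(s, "_at", k,
                                                           "_", i))
      }
    }
  }
  bags
}
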