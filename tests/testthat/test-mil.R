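test_that("qwk weight matrix follows the quadratic-distance formula", {
  expect_equal(qwk_weight_matrix(3),
               matrix(c(0, 0.25, 1, 0.25, 0, 0.25, 1, 0.25, 0), 3, 3))
  expect_equal(qwk_weight_matrix(2), matrix(c(0, 1, 1, 0), 2, 2))
  for (n in 2:6) expect_equal(diag(qwk_weight_matrix(n)), rep(0, n))
  expect_error(qwk_weight_matrix(1))
})

test_that("expected score evaluates and is monotone in severity", {
  expect_equal(expected_score(c(1, 0, 0)), 1)
  expect_equal(expected_score(c(0, 0, 1)), 3)
  expect_equal(expected_score(c(0.2, 0.5, 0.3)), 2.1)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(3); p <- p / sum(p)
    # move mass from a lower class to a higher one
    eps <- min(p[1], 0.1)
    q <- p + c(-eps, 0, eps)
    expect_gt(expected_score(q), expected_score(p))
  }
})

test_that("qwk loss matches its closed forms and flags degenerate batches", {
  # perfect one-hot agreement on a mixed batch
  p <- diag(3)[c(1, 2, 3, 2), ]
  lt <- qwk_loss(p, c(1, 2, 3, 2))
  expect_equal(lt$kappa, 1)
  expect_equal(lt$loss, 0)
  # labels (1,2,3), all predictions one-hot class 2
  p2 <- matrix(rep(c(0, 1, 0), 3), 3, 3, byrow = TRUE)
  lt2 <- qwk_loss(p2, 1:3)
  expect_equal(sum(lt2$weights * lt2$observed), 0.5)
  expect_equal(sum(lt2$weights * lt2$expected), 0.5)
  expect_equal(lt2$kappa, 0)
  expect_equal(lt2$loss, 1)
  # observed and expected have the same mass
  expect_equal(sum(lt2$observed), sum(lt2$expected))
  # degenerate single-class batch with all mass on that class
  p3 <- matrix(rep(c(0, 1, 0), 2), 2, 3, byrow = TRUE)
  lt3 <- qwk_loss(p3, c(2, 2))
  expect_true(lt3$degenerate)
  expect_equal(lt3$kappa, 0)
})

test_that("hard-label qwk loss equals the confusion-matrix statistic", {
  set.seed(13)
  for (i in 1:25) {
    labels <- sample(1:3, 30, replace = TRUE)
    preds <- sample(1:3, 30, replace = TRUE)
    probs <- diag(3)[preds, ]
    lt <- qwk_loss(probs, labels)
    cm <- confusion_matrix(preds, labels, classes = cg_classes())
    expect_equal(lt$kappa, qwk_statistic(cm), tolerance = 1e-12)
  }
})

test_that("qwk loss is in [0,2] and its gradient matches finite differences", {
  set.seed(17)
  for (i in 1:10) {
    N <- sample(4:8, 1)
    labels <- c(1, 2, sample(1:3, N - 2, replace = TRUE))  # >= 2 classes
    raw <- matrix(runif(N * 3, 0.05, 1), N, 3)
    probs <- raw / rowSums(raw)
    lt <- qwk_loss(probs, labels)
    expect_gte(lt$loss, 0)
    expect_lte(lt$loss, 2)
    g <- cervigrade:::cg_qwk_grad(probs, labels)
    eps <- 1e-7
    for (probe in list(c(1, 1), c(2, 3), c(N, 2))) {
      p2 <- probs
      p2[probe[1], probe[2]] <- p2[probe[1], probe[2]] + eps
      num <- (qwk_loss(p2, labels)$loss - lt$loss) / eps
      expect_equal(g[probe[1], probe[2]], num, tolerance = 1e-4)
    }
  }
})

test_that("rank_and_select picks the highest expected score with stable ties", {
  tiles <- lapply(1:3, function(i) list(image = array(0, c(4, 4, 3)), id = i))
  probs <- rbind(c(0.8, 0.2, 0), c(0.05, 0, 0.95), c(0.2, 0.5, 0.3))
  sel <- rank_and_select(fixed_classifier(probs), tiles)
  expect_equal(sel$worst_index, 2)   # scores 1.2, 2.9, 2.1
  expect_equal(sel$worst_score, 2.9)
  # single-tile bag
  sel1 <- rank_and_select(fixed_classifier(probs[1, , drop = FALSE]),
                          tiles[1])
  expect_equal(sel1$worst_index, 1)
  # identical probabilities: stable order, first tile wins
  same <- matrix(rep(c(1, 1, 1) / 3, 3), 3, 3, byrow = TRUE)
  expect_equal(rank_and_select(fixed_classifier(same), tiles)$worst_index, 1)
  # HSIL-probability tie-break at equal expected score
  tie <- rbind(c(0.25, 0.5, 0.25), c(0.5, 0, 0.5))   # both score 2
  expect_equal(rank_and_select(fixed_classifier(tie),
                               tiles[1:2])$worst_index, 2)
})

test_that("bag monotonicity: adding a tile never lowers the selected score", {
  tiles <- lapply(1:4, function(i) list(image = array(0, c(4, 4, 3))))
  set.seed(23)
  for (i in 1:10) {
    raw <- matrix(runif(4 * 3), 4, 3)
    probs <- raw / rowSums(raw)
    s3 <- rank_and_select(fixed_classifier(probs[1:3, ]),
                          tiles[1:3])$worst_score
    s4 <- rank_and_select(fixed_classifier(probs), tiles)$worst_score
    expect_gte(s4, s3)
  }
})

test_that("bags are built per supervision level with uncertainty exclusion", {
  mk_tile <- function(x, y, sid = "s1")
    list(image = array(0, c(4, 4, 3)), center = c(x = x, y = y),
         slide_id = sid, epithelium_id = 1L)
  manifest <- data.frame(slide_id = c("s1", "s2"),
                         label = c("HSIL", "LSIL"))
  # slide s1: 10 tiles, no annotations -> one LS bag of 10
  tiles1 <- lapply(seq(5, 95, by = 10), function(x) mk_tile(x, 10))
  ls <- build_bags(manifest, list(), tiles1, supervision = "LS")
  expect_length(ls, 1)
  expect_length(ls[[1]]$tiles, 10)
  expect_equal(ls[[1]]$label, 3L)

  # annotated epithelium with 7 tiles labelled LSIL -> AE bag of 7, label 2
  sq <- function(x0, y0, x1, y1)
    matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), 4, 2, byrow = TRUE)
  tiles2 <- lapply(seq(5, 65, by = 10), function(x) mk_tile(x, 10, "s2"))
  ann2 <- list(s2 = list(list(polygon = sq(0, 0, 70, 20), label = "LSIL",
                              role = "epithelium")))
  ae <- build_bags(manifest, ann2, tiles2, supervision = "AE")
  expect_length(ae, 1)
  expect_length(ae[[1]]$tiles, 7)
  expect_equal(ae[[1]]$label, 2L)
  expect_equal(ae[[1]]$supervision, "AE")

  # HSIL roi polygon covering 3 tile centers -> 3 single-tile AT bags
  ann3 <- list(s1 = list(list(polygon = sq(0, 0, 32, 20), label = "HSIL",
                              role = "roi")))
  at <- build_bags(manifest, ann3, tiles1, supervision = "AT")
  expect_length(at, 3)
  expect_true(all(vapply(at, function(b) length(b$tiles), integer(1)) == 1))
  expect_true(all(vapply(at, `[[`, integer(1), "label") == 3L))

  # uncertain polygon removes tiles from every bag type
  ann4 <- list(s1 = list(list(polygon = sq(0, 0, 32, 20), label = "HSIL",
                              role = "roi"),
                         list(polygon = sq(0, 0, 12, 20),
                              label = "uncertain", role = "roi")))
  at2 <- build_bags(manifest, ann4, tiles1, supervision = "AT")
  expect_length(at2, 2)
  ls2 <- build_bags(manifest, ann4, tiles1, supervision = "LS")
  expect_length(ls2[[1]]$tiles, 9)

  # error paths
  orphan <- list(mk_tile(1, 1, "nope"))
  expect_error(build_bags(manifest, list(), orphan), "missing from the manifest")
  bad <- list(s1 = list(list(polygon = sq(0, 0, 5, 5), label = "CIN9",
                             role = "roi")))
  expect_error(build_bags(manifest, bad, tiles1), "unknown label")
})
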