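test_that("confusion counts match hand-enumerated overlaps", {
  truth <- matrix(0L, 8, 8); truth[2:4, 2:4] <- 1L  # 3x3 square
  pred <- matrix(0L, 8, 8); pred[2:4, 3:5] <- 1L    # shifted one column
  cf <- confusion(pred, truth)
  expect_equal(cf, list(TP = 6L, FP = 3L, FN = 3L))

  perfect <- confusion(truth, truth)
  expect_equal(perfect, list(TP = 9L, FP = 0L, FN = 0L))
  expect_equal(confusion(matrix(0L, 8, 8), truth),
               list(TP = 0L, FP = 0L, FN = 9L))
  expect_error(confusion(matrix(0L, 4, 4), truth), "differ")
})

test_that("confusion agrees with a brute-force per-pixel loop", {
  for (seed in 1:25) {
    set.seed(seed)
    pred <- matrix(as.integer(runif(16 * 16) < 0.4), 16, 16)
    truth <- matrix(as.integer(runif(16 * 16) < 0.4), 16, 16)
    tp <- fp <- fn <- 0L
    for (i in 1:16) for (j in 1:16) {
      if (pred[i, j] == 1L && truth[i, j] == 1L) tp <- tp + 1L
      if (pred[i, j] == 1L && truth[i, j] == 0L) fp <- fp + 1L
      if (pred[i, j] == 0L && truth[i, j] == 1L) fn <- fn + 1L
    }
    expect_equal(confusion(pred, truth), list(TP = tp, FP = fp, FN = fn))
  }
})

test_that("precision/recall/F1 formulas and conventions", {
  m <- f1_score(8, 2, 8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 * 0.8 * 0.5 / 1.3, tolerance = 1e-12)
  expect_equal(round(m$f1, 4), 0.6154)

  expect_equal(f1_score(40, 0, 0)[, c("precision", "recall", "f1")],
               tibble::tibble(precision = 1, recall = 1, f1 = 1))
  expect_equal(f1_score(0, 5, 3)$f1, 0)
  # both empty: a perfect (vacuous) match
  all1 <- f1_score(0, 0, 0)
  expect_equal(c(all1$precision, all1$recall, all1$f1), c(1, 1, 1))
  # no predictions: precision 1, recall 0, F1 0
  none <- f1_score(0, 0, 10)
  expect_equal(c(none$precision, none$recall, none$f1), c(1, 0, 0))
})

test_that("F1 is symmetric in FP/FN, bounded, and 1 only at perfection", {
  for (seed in 1:50) {
    set.seed(seed)
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    a <- f1_score(tp, fp, fn)$f1
    b <- f1_score(tp, fn, fp)$f1
    expect_equal(a, b)
    expect_lte(a, 1)
    if (a == 1) expect_true(fp == 0 && fn == 0 && tp > 0 ||
                              (tp + fp + fn) == 0)
  }
})

test_that("macro and micro averaging differ as expected", {
  t1 <- matrix(0L, 4, 4); t1[1, 1] <- 1L
  p1 <- t1                                    # perfect on a tiny object
  t2 <- matrix(1L, 4, 4)
  p2 <- matrix(0L, 4, 4); p2[1:2, ] <- 1L     # half right on a big one
  macro <- set_f1(list(p1, p2), list(t1, t2), "macro")
  micro <- set_f1(list(p1, p2), list(t1, t2), "micro")
  f2 <- f1_score(confusion(p2, t2))$f1
  expect_equal(macro, (1 + f2) / 2)
  expect_equal(micro, f1_score(9, 0, 8)$f1)
})

test_that("a trained model separates foreground from background", {
  scenes <- tiny_scenes(2L)
  fit <- seg_train(build_model(tiny_config(epochs = 30L)), scenes)
  p <- seg_predict(fit$model, scenes[[1L]]$image)
  expect_gt(mean(p[scenes[[1L]]$mask == 1L]),
            mean(p[scenes[[1L]]$mask == 0L]))
})

test_that("a no-op correction loop keeps F1 constant", {
  tab <- correction_loop(
    initial_n = 1L, rounds = 2L, k_corrected_per_round = 0L,
    scene_params = desk_scene_params(image_height = 64L, image_width = 64L,
                                     n_nodules = 3L, n_roots = 1L,
                                     nodule_radius_range = c(3, 6)),
    model_config = tiny_config(epochs = 3L),
    n_new_per_round = 1L, n_heldout = 2L, seed = 3L
  )
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$heldout_f1, rep(tab$heldout_f1[1L], 3L))
  expect_equal(tab$n_pairs, rep(1L, 3L))
})
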