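test_that("contours round-trip solid shapes at high IoU", {
  sq <- matrix(0L, 24, 24)
  sq[8:17, 6:15] <- 1L
  ann <- mask_to_contours(sq)
  expect_length(ann$polygons, 1L)
  back <- contours_to_mask(ann, c(24, 24))
  expect_gte(mask_iou(back, sq), 0.95)

  expect_length(mask_to_contours(matrix(0L, 10, 10))$polygons, 0L)

  two <- pmax(disk_mask(40, 40, 12, 12, 6), disk_mask(40, 40, 30, 28, 7))
  expect_length(mask_to_contours(two)$polygons, 2L)
})

test_that("rasterization agrees with a half-plane oracle on a triangle", {
  tri <- polygon_annotation(list(rbind(c(1, 1), c(1, 21), c(21, 1))))
  m <- contours_to_mask(tri, c(30, 30))
  # oracle: pixel centres strictly inside the three half planes
  oracle <- 0L
  for (r in 1:30) for (c in 1:30) {
    if (r > 1 && c > 1 && (r - 1) + (c - 1) < 20) oracle <- oracle + 1L
  }
  expect_lte(abs(sum(m) - 200) / 200, 0.05)
  # the scanline convention includes boundary pixels; the strict-interior
  # oracle differs by at most the boundary band (3 sides of ~20 px)
  expect_lte(abs(sum(m) - oracle), 60)

  expect_equal(sum(contours_to_mask(polygon_annotation(), c(10, 10))), 0)
  expect_error(polygon_annotation(list(rbind(c(1, 1), c(2, 2)))),
               ">= 3 vertices")
})

test_that("round trip holds for every synthetic nodule of radius >= 5", {
  sc <- generate_scene(desk_scene_params(n_nodules = 6L,
                                         nodule_radius_range = c(5, 9),
                                         seed = 13L))
  for (inst in sc$instances) {
    m <- matrix(0L, nrow(sc$mask), ncol(sc$mask))
    m[inst$pixels] <- 1L
    back <- contours_to_mask(mask_to_contours(m), dim(m))
    expect_gte(mask_iou(back, m), 0.95)
  }
})

test_that("apply_corrections implements union-minus-remove with idempotence", {
  sc <- generate_scene(desk_scene_params(seed = 17L))
  pred <- sc$mask

  expect_identical(apply_corrections(pred), pred)

  whole <- polygon_annotation(list(rbind(
    c(0, 0), c(0, ncol(pred) + 1), c(nrow(pred) + 1, ncol(pred) + 1),
    c(nrow(pred) + 1, 0)
  )))
  expect_equal(sum(apply_corrections(pred, remove = whole)), 0)

  add <- mask_to_contours(disk_mask(128, 128, 20, 100, 5))
  out1 <- apply_corrections(pred, add = add)
  out2 <- apply_corrections(out1, add = add)
  expect_identical(out1, out2)
  # remove wins where add and remove overlap
  both <- apply_corrections(pred, add = add, remove = add)
  expect_equal(sum(both & contours_to_mask(add, dim(pred))), 0)
})

test_that("adding a missed nodule's true contour strictly increases F1", {
  sc <- generate_scene(desk_scene_params(n_nodules = 5L, seed = 19L))
  # prediction that missed the first instance entirely
  pred <- sc$mask
  pred[sc$instances[[1L]]$pixels] <- 0L
  before <- pixel_metrics_masks(pred, sc$mask)$f1
  add <- ground_truth_annotation(sc)
  add$polygons <- add$polygons[1L]
  add$provenance <- add$provenance[1L]
  after <- pixel_metrics_masks(apply_corrections(pred, add = add),
                               sc$mask)$f1
  expect_gt(after, before)
  expect_gte(after, 0.99)
})

test_that("LabelMe-style JSON round-trips annotations", {
  sc <- generate_scene(desk_scene_params(seed = 23L))
  ann <- mask_to_contours(sc$mask, image_id = "scene.png")
  f <- file.path(tempdir(), "ann.json")
  write_annotation_json(ann, f, dims = dim(sc$mask))
  back <- read_annotation_json(f)
  expect_equal(length(back$polygons), length(ann$polygons))
  expect_equal(back$image_id, "scene.png")
  for (i in seq_along(ann$polygons)) {
    expect_equal(unname(back$polygons[[i]]), unname(ann$polygons[[i]]),
                 tolerance = 1e-9)
  }
  # rasterization of the reloaded polygons matches the original mask
  expect_gte(mask_iou(contours_to_mask(back, dim(sc$mask)), sc$mask), 0.95)
})

test_that("corrected masks are valid training inputs", {
  sc <- tiny_scenes(1L)[[1L]]
  corrected <- apply_corrections(sc$mask,
                                 add = ground_truth_annotation(sc))
  cfg <- tiny_config(epochs = 1L)
  fit <- seg_train(build_model(cfg), list(list(image = sc$image,
                                               mask = sc$mask)))
  expect_no_error(
    seg_update(fit$model, list(list(image = sc$image, mask = corrected)),
               config = cfg)
  )
})
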