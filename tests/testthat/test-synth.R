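test_that("scene generation is deterministic and honours the empty case", {
  p <- desk_scene_params(seed = 7L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)

  empty <- generate_scene(desk_scene_params(n_nodules = 0L, seed = 2L))
  expect_equal(sum(empty$mask), 0)
  expect_equal(empty$true_count, 0L)
  expect_equal(empty$true_total_area_mm2, 0)
})

test_that("disjoint instances tile the mask exactly", {
  sc <- generate_scene(desk_scene_params(n_nodules = 5L,
                                         overlap_fraction = 0, seed = 3L))
  expect_equal(sc$true_count, 5L)
  per_instance <- vapply(sc$instances, function(i) i$pixel_count, integer(1))
  expect_equal(sum(sc$mask), sum(per_instance))
  union_pixels <- sort(unique(unlist(lapply(sc$instances, `[[`, "pixels"))))
  expect_identical(which(sc$mask == 1L), union_pixels)
  expect_equal(sc$true_total_area_mm2, sum(sc$mask) * sc$mm_per_pixel^2)
})

test_that("mask equals the union of instance pixels even with overlap", {
  sc <- generate_scene(desk_scene_params(n_nodules = 8L,
                                         overlap_fraction = 0.8, seed = 9L))
  union_pixels <- sort(unique(unlist(lapply(sc$instances, `[[`, "pixels"))))
  expect_identical(which(sc$mask == 1L), union_pixels)
  expect_equal(sc$true_count, 8L)
})

test_that("datasets are reproducible with distinct scenes across seeds", {
  p <- desk_scene_params()
  d1 <- generate_dataset(3L, p, seed = 5L)
  d2 <- generate_dataset(3L, p, seed = 5L)
  expect_identical(lapply(d1, `[[`, "image"), lapply(d2, `[[`, "image"))
  d3 <- generate_dataset(3L, p, seed = 6L)
  pool <- c(d1, d3)
  for (i in seq_along(pool)) {
    for (j in seq_len(i - 1L)) {
      expect_false(identical(pool[[i]]$image, pool[[j]]$image))
    }
  }
  expect_length(generate_dataset(1L, p), 1L)
})

test_that("placement failure raises an explicit error", {
  p <- desk_scene_params(image_height = 32L, image_width = 32L,
                         n_nodules = 200L, nodule_radius_range = c(10, 14),
                         overlap_fraction = 0)
  expect_error(generate_scene(p), "could not place")
})

test_that("increasing n_nodules never decreases the true count", {
  counts <- vapply(c(1L, 3L, 5L, 8L), function(n) {
    generate_scene(desk_scene_params(n_nodules = n, seed = 4L))$true_count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("phenotype simulator matches the stated design", {
  ph <- generate_phenotypes(design_spec(seed = 2L), trait = "size_cm2")
  expect_equal(nrow(ph), 270L)
  expect_setequal(names(ph), c("block", "treatment", "plot", "subsample",
                               "size_cm2"))
  expect_equal(nlevels(ph$plot), 9L)
  expect_true(all(ph$size_cm2 > 0))

  flat <- generate_phenotypes(design_spec(
    block_sd = 0, plot_sd = 0, subsample_sd = 0,
    treatment_effects = c(0, 0, 0), mu = 1.3
  ))
  expect_equal(flat$trait, rep(exp(1.3), 270), tolerance = 1e-12)

  expect_error(design_spec(subsample_sd = -1), "non-negative")
  expect_error(design_spec(treatment_effects = c(0, 1)),
               "treatment_effects")
})

test_that("empirical subsample SD on the log scale matches the spec", {
  spec <- design_spec(n_blocks = 1L, n_treatments = 1L,
                      n_subsamples = 10000L, block_sd = 0, plot_sd = 0,
                      treatment_effects = 0, subsample_sd = 0.46, seed = 8L)
  ph <- generate_phenotypes(spec)
  emp <- sd(log(ph$trait))
  expect_lt(abs(emp - 0.46) / 0.46, 0.05)
})

test_that("scene files round-trip through PNG + JSON sidecar", {
  sc <- generate_scene(desk_scene_params(seed = 12L))
  stem <- file.path(tempdir(), "scene_roundtrip")
  write_scene(sc, stem)
  expect_true(all(file.exists(paste0(stem, c(".png", "_mask.png", ".json")))))
  back <- read_scene(stem)
  expect_identical(back$mask, sc$mask)
  expect_lt(max(abs(back$image - sc$image)), 1 / 255)
  expect_equal(back$true_count, sc$true_count)
  expect_equal(back$mm_per_pixel, sc$mm_per_pixel)
})
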