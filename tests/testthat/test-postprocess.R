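test_that("CRF reduces to the unary-only limit when pairwise weights vanish", {
  set.seed(31)
  prob <- matrix(runif(24 * 24), 24, 24)
  img <- array(runif(24 * 24 * 3), dim = c(24, 24, 3))
  p0 <- crf_params(appearance_weight = 1e-12, smoothness_weight = 1e-12)
  out <- crf_refine(prob, img, p0)
  expect_equal(out, prob, tolerance = 1e-6)
})

test_that("CRF suppresses an isolated foreground pixel on uniform background", {
  prob <- matrix(0.1, 32, 32)
  prob[16, 16] <- 0.6
  img <- array(0.4, dim = c(32, 32, 3))
  out <- crf_refine(prob, img, crf_params(n_iterations = 5L))
  expect_lt(out[16, 16], 0.6)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("CRF is symmetric on a perfectly ambiguous input", {
  prob <- matrix(0.5, 16, 16)
  img <- array(0.5, dim = c(16, 16, 3))
  out <- crf_refine(prob, img)
  expect_equal(max(abs(out - 0.5)), 0, tolerance = 1e-6)
  expect_error(crf_refine(matrix(0.5, 8, 8), img), "differ")
})

test_that("closing fills an annulus and never shrinks foreground", {
  # ring of width 2: outer radius 10, inner radius 8, closing radius 1
  ring <- disk_mask(32, 32, 16, 16, 10) - disk_mask(32, 32, 16, 16, 8)
  filled <- close_and_fill(ring, postprocess_params(closing_radius = 1L))
  # interior flood-fill oracle: everything inside the outer circle is filled
  solid <- disk_mask(32, 32, 16, 16, 10)
  expect_true(all(filled[solid == 1L] == 1L))

  solid_disk <- disk_mask(20, 20, 10, 10, 6)
  expect_identical(close_and_fill(solid_disk, postprocess_params()),
                   solid_disk)
  empty <- matrix(0L, 10, 10)
  expect_identical(close_and_fill(empty, postprocess_params()), empty)
})

test_that("close_and_fill is monotone over random masks", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(as.integer(runif(32 * 32) < 0.3), 32, 32)
    out <- close_and_fill(m, postprocess_params(closing_radius = 2L))
    expect_true(all(out[m == 1L] == 1L))
  }
})

test_that("diagonal adjacency distinguishes 4- from 8-connectivity", {
  m <- matrix(0L, 5, 5)
  m[2, 2] <- 1L
  m[3, 3] <- 1L
  expect_equal(attr(label_components(m, 4L), "n_components"), 2L)
  expect_equal(attr(label_components(m, 8L), "n_components"), 1L)
  expect_equal(attr(label_components(matrix(0L, 4, 4), 8L), "n_components"),
               0L)
})

test_that("component labelling agrees with a flood-fill oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    density <- runif(1, 0.15, 0.6)
    m <- matrix(as.integer(runif(32 * 32) < density), 32, 32)
    conn <- if (seed %% 2 == 0) 4L else 8L
    mine <- label_components(m, conn)
    oracle <- flood_fill_oracle(m, conn)
    expect_true(same_labeling(mine, oracle))
    expect_equal(attr(mine, "n_components"), max(oracle))
  }
})

test_that("three disjoint disks are labelled with their rendered areas", {
  m <- matrix(0L, 64, 64)
  disks <- list(c(12, 12, 5), c(40, 20, 7), c(30, 50, 4))
  areas <- integer(3)
  for (i in seq_along(disks)) {
    d <- disk_mask(64, 64, disks[[i]][1], disks[[i]][2], disks[[i]][3])
    areas[i] <- sum(d)
    m <- pmax(m, d)
  }
  lab <- label_components(m, 8L)
  expect_equal(attr(lab, "n_components"), 3L)
  expect_setequal(as.integer(table(lab[lab > 0])), areas)
})

test_that("size filter keeps the documented inclusive boundary", {
  # components of 9, 10 and 11 pixels with a 10-pixel minimum: 9 drops
  m <- matrix(0L, 12, 40)
  m[2:4, 2:4] <- 1L                      # 9 px
  m[2:6, 10:11] <- 1L                    # 10 px
  m[c(2:6), 20:21] <- 1L; m[7, 20] <- 1L # 11 px
  lab <- label_components(m, 8L)
  expect_equal(attr(lab, "n_components"), 3L)
  pp <- postprocess_params(min_size_mm2 = 10, max_size_mm2 = Inf)
  kept <- filter_by_size(lab, pp, mm_per_pixel = 1)
  sizes <- as.integer(table(kept[kept > 0]))
  expect_setequal(sizes, c(10L, 11L))
  expect_equal(attr(kept, "n_components"), 2L)

  # min = 1 px is the identity; the filter is idempotent
  pp1 <- postprocess_params(min_size_mm2 = 1)
  expect_identical(filter_by_size(lab, pp1, 1)[, ], lab[, ])
  twice <- filter_by_size(kept, pp, 1)
  expect_identical(twice[, ], kept[, ])
})

test_that("size filter on {3, 50, 200} with min 10 keeps two components", {
  m <- matrix(0L, 40, 60)
  m[2, 2:4] <- 1L                        # 3 px
  m[10:19, 10:14] <- 1L                  # 50 px
  m[25:34, 30:49] <- 1L                  # 200 px
  lab <- label_components(m, 8L)
  kept <- filter_by_size(lab, postprocess_params(min_size_mm2 = 10), 1)
  expect_equal(attr(kept, "n_components"), 2L)
})
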