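#' Parameters for a synthetic root-nodule scene
#'
#' Describes a synthetic RGB photograph of a washed legume root system on a
#' dark soil-like background: thin branching root strands with small, bright,
#' roundish nodules (rotated ellipses) attached to them, often overlapping.
#' The generator exists so the whole pipeline can be exercised against known
#' per-instance ground truth; it makes no attempt at photorealism.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param n_roots Number of primary root strands.
#' @param root_width_range Length-2 vector, min/max strand width in pixels.
#' @param n_nodules Number of nodule instances to place.
#' @param nodule_radius_range Length-2 vector, min/max semi-major axis in px.
#' @param overlap_fraction Probability in `[0, 1]` that a nodule is placed
#'   touching an existing nodule (centre within one radius) rather than on a
#'   root strand.
#' @param background_noise_sd Standard deviation of the additive Gaussian
#'   pixel noise, on the `[0, 1]` intensity scale.
#' @param mm_per_pixel Physical resolution of the simulated camera.
#' @param seed Integer seed; scenes are reproducible pixel-for-pixel.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_height = 512L, image_width = 512L,
                         n_roots = 4L, root_width_range = c(3, 7),
                         n_nodules = 25L, nodule_radius_range = c(5, 12),
                         overlap_fraction = 0.3, background_noise_sd = 0.04,
                         mm_per_pixel = 0.1, seed = 1L) {
  p <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_roots = as.integer(n_roots),
    root_width_range = as.numeric(root_width_range),
    n_nodules = as.integer(n_nodules),
    nodule_radius_range = as.numeric(nodule_radius_range),
    overlap_fraction = as.numeric(overlap_fraction),
    background_noise_sd = as.numeric(background_noise_sd),
    mm_per_pixel = as.numeric(mm_per_pixel),
    seed = as.integer(seed)
  )
  stopifnot(
    p$image_height >= 16L, p$image_width >= 16L,
    p$n_roots >= 0L, p$n_nodules >= 0L,
    length(p$root_width_range) == 2L, all(p$root_width_range > 0),
    length(p$nodule_radius_range) == 2L, all(p$nodule_radius_range > 0),
    p$overlap_fraction >= 0, p$overlap_fraction <= 1,
    p$background_noise_sd >= 0, p$mm_per_pixel > 0
  )
  structure(p, class = "scene_params")
}

#' Desk-scale scene parameters
#'
#' A small 128 x 128 configuration on which the default network trains on a
#' CPU in minutes; used throughout the test harnesses.
#'
#' @param ... Overrides passed to [scene_params()].
#' @return A `scene_params` object.
#' @export
desk_scene_params <- function(...) {
  defaults <- list(
    image_height = 128L, image_width = 128L, n_roots = 2L,
    root_width_range = c(2, 4), n_nodules = 6L,
    nodule_radius_range = c(4, 8), overlap_fraction = 0,
    background_noise_sd = 0.04, mm_per_pixel = 0.1, seed = 1L
  )
  over <- list(...)
  defaults[names(over)] <- over
  do.call(scene_params, defaults)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# pixels of a rotated ellipse, clipped check done by caller; returns linear
# indices into an H x W matrix
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(W, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc2 <- c0:c1
  dr <- outer(rr - cr, rep(1, length(cc2)))
  dc <- outer(rep(1, length(rr)), cc2 - cc)
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- u * u + v * v <= 1
  idx_r <- row(inside)[inside] + r0 - 1L
  idx_c <- col(inside)[inside] + c0 - 1L
  as.integer((idx_c - 1L) * H + idx_r)
}

draw_root_strand <- function(H, W, width) {
  # random downward walk with curvature; returns matrix of (row, col) centres
  r <- runif(1, 1, H * 0.25)
  c <- runif(1, W * 0.1, W * 0.9)
  ang <- runif(1, pi / 3, 2 * pi / 3)  # pointing broadly downwards
  pts <- matrix(0, 0, 2)
  n_steps <- as.integer(H * 1.5)
  for (i in seq_len(n_steps)) {
    pts <- rbind(pts, c(r, c))
    ang <- ang + rnorm(1, 0, 0.15)
    ang <- min(max(ang, pi / 6), 5 * pi / 6)
    r <- r + sin(ang) * 1.5
    c <- c + cos(ang) * 1.5
    if (r > H || c < 1 || c > W) break
  }
  pts
}

#' Generate one synthetic root scene with ground truth
#'
#' Renders the scene described by `params`: dark noisy background with
#' low-frequency blotches, branching root strands (background in the mask),
#' and bright elliptical nodules attached to the strands. The binary mask is
#' the union of the instance pixel sets; the ground-truth count is the number
#' of instances even when their pixels merge, which deliberately makes merged
#' components a known failure mode of component-based counting.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `nodule_scene`: list with `image`
#'   (`H x W x 3` array), `mask` (0/1 integer matrix), `instances` (list of
#'   per-nodule records with `center`, `radii`, `rotation`, `pixels`,
#'   `pixel_count`), `true_count`, `true_total_area_mm2`, `mm_per_pixel`,
#'   `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    H <- params$image_height; W <- params$image_width
    # background: dark brown base + low-frequency blotches + noise
    base <- c(0.16, 0.12, 0.09)
    img <- array(rep(base, each = H * W), dim = c(H, W, 3))
    n_blotch <- max(2L, as.integer(H * W / 8000))
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    for (i in seq_len(n_blotch)) {
      br <- runif(1, 1, H); bc <- runif(1, 1, W)
      sd <- runif(1, H / 10, H / 4); amp <- runif(1, -0.04, 0.05)
      g <- amp * exp(-((rows - br)^2 + (cols - bc)^2) / (2 * sd^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + g
    }

    # roots: stamped disks along random walks; roots stay background in mask
    root_color <- c(0.42, 0.35, 0.27)
    root_pts <- matrix(0, 0, 2)
    if (params$n_roots > 0L) {
      strands <- list()
      for (i in seq_len(params$n_roots)) {
        strands[[length(strands) + 1L]] <- draw_root_strand(H, W, NA)
        if (runif(1) < 0.7 && nrow(strands[[length(strands)]]) > 10) {
          # one lateral branch per strand on average
          src <- strands[[length(strands)]]
          k <- sample(seq_len(nrow(src) - 5L), 1L) + 2L
          br <- draw_root_strand(H, W, NA)
          br[, 1] <- br[, 1] - br[1, 1] + src[k, 1]
          br[, 2] <- br[, 2] - br[1, 2] + src[k, 2]
          keep <- br[, 1] >= 1 & br[, 1] <= H & br[, 2] >= 1 & br[, 2] <= W
          strands[[length(strands) + 1L]] <- br[keep, , drop = FALSE]
        }
      }
      root_layer <- matrix(0, H, W)
      for (s in strands) {
        if (nrow(s) == 0) next
        w <- runif(1, params$root_width_range[1], params$root_width_range[2])
        rad <- max(1L, as.integer(round(w / 2)))
        for (k in seq_len(nrow(s))) {
          idx <- ellipse_pixels(s[k, 1], s[k, 2], rad, rad, 0, H, W)
          root_layer[idx] <- 1
        }
        root_pts <- rbind(root_pts, s)
      }
      shade <- root_layer * runif(1, 0.9, 1.1)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[root_layer > 0] <- root_color[ch] * shade[root_layer > 0]
        img[, , ch] <- pl
      }
    }
    if (nrow(root_pts) == 0L && params$n_nodules > 0L) {
      # no roots requested: attach nodules to a virtual midline
      root_pts <- cbind(seq(H * 0.2, H * 0.8, length.out = 50),
                        rep(W / 2, 50))
    }

    # nodules
    nodule_base <- c(0.85, 0.76, 0.58)
    instances <- list()
    mask <- matrix(0L, H, W)
    for (k in seq_len(params$n_nodules)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, params$nodule_radius_range[1],
                   params$nodule_radius_range[2])
        b <- a * runif(1, 0.65, 1)
        theta <- runif(1, 0, pi)
        if (length(instances) > 0L && runif(1) < params$overlap_fraction) {
          anchor <- instances[[sample(length(instances), 1L)]]
          ang <- runif(1, 0, 2 * pi)
          d <- runif(1, 0, anchor$radii[1])
          cr <- anchor$center[1] + d * sin(ang)
          cc <- anchor$center[2] + d * cos(ang)
        } else {
          i <- sample(nrow(root_pts), 1L)
          cr <- root_pts[i, 1]; cc <- root_pts[i, 2]
        }
        if (cr - a < 1 || cr + a > H || cc - a < 1 || cc + a > W) next
        if (params$overlap_fraction == 0 && length(instances) > 0L) {
          # enforce disjoint instances when no overlap is requested
          idx <- ellipse_pixels(cr, cc, a + 1.5, a + 1.5, 0, H, W)
          if (any(mask[idx] > 0L)) next
        }
        pix <- ellipse_pixels(cr, cc, a, b, theta, H, W)
        if (length(pix) == 0L) next
        instances[[k]] <- list(center = c(cr, cc), radii = c(a, b),
                               rotation = theta, pixels = pix,
                               pixel_count = length(pix))
        mask[pix] <- 1L
        # render: bright ellipse with radial shading and colour jitter
        jit <- runif(1, 0.9, 1.08)
        rr <- ((pix - 1L) %% H) + 1L
        cc2 <- ((pix - 1L) %/% H) + 1L
        d2 <- ((rr - cr)^2 + (cc2 - cc)^2) / (a * a)
        shade <- jit * (1 - 0.35 * pmin(d2, 1))
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[pix] <- nodule_base[ch] * shade
          img[, , ch] <- pl
        }
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("generate_scene: could not place nodule ", k,
             " after 200 attempts; image too small or too crowded",
             call. = FALSE)
      }
    }

    if (params$background_noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, params$background_noise_sd),
                         dim = dim(img))
    }
    img[img < 0] <- 0
    img[img > 1] <- 1

    structure(list(
      image = img,
      mask = mask,
      instances = instances,
      true_count = length(instances),
      true_total_area_mm2 = sum(mask) * params$mm_per_pixel^2,
      mm_per_pixel = params$mm_per_pixel,
      params = params
    ), class = "nodule_scene")
  })
}

#' @export
print.nodule_scene <- function(x, ...) {
  cat(sprintf(
    "<nodule_scene> %d x %d px, %d nodules, %.2f mm^2 total (%.3g mm/px)\n",
    nrow(x$mask), ncol(x$mask), x$true_count, x$true_total_area_mm2,
    x$mm_per_pixel
  ))
  invisible(x)
}

#' Generate a reproducible set of synthetic scenes
#'
#' @param n Number of scenes (>= 1).
#' @param params Base [scene_params()]; each scene gets a derived seed.
#' @param seed Master seed for the per-scene seed stream.
#' @return List of `nodule_scene` objects.
#' @export
generate_dataset <- function(n, params = scene_params(), seed = params$seed) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- as.integer((as.double(seed) * 10007 + i) %% 2147483647)
    generate_scene(p)
  })
}

#' Design of a simulated randomized-complete-block experiment with subsampling
#'
#' Houses the components of the model
#' `y_ijk = mu + beta_j + alpha_i + delta_ij + eps_ijk` on the log scale:
#' block effects `beta_j ~ N(0, block_sd^2)`, fixed treatment effects
#' `alpha_i`, plot (experimental) errors `delta_ij ~ N(0, plot_sd^2)` and
#' subsampling errors `eps_ijk ~ N(0, subsample_sd^2)`. Defaults are chosen
#' so that the block mean square dominates the treatment mean square, the
#' qualitative structure reported for field nodule data (3 blocks x 3
#' treatments x 30 subsampled plants, 270 observations).
#'
#' @param n_blocks,n_treatments,n_subsamples Design dimensions.
#' @param mu Overall mean on the log scale.
#' @param block_sd,plot_sd,subsample_sd Standard deviations on the log scale;
#'   must be non-negative.
#' @param treatment_effects Numeric vector of fixed effects, one per
#'   treatment, on the log scale.
#' @param seed Integer seed.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_blocks = 3L, n_treatments = 3L, n_subsamples = 30L,
                        mu = 1, block_sd = 0.42,
                        treatment_effects = c(-0.25, 0, 0.25),
                        plot_sd = 0.115, subsample_sd = 0.46, seed = 1L) {
  spec <- list(
    n_blocks = as.integer(n_blocks), n_treatments = as.integer(n_treatments),
    n_subsamples = as.integer(n_subsamples), mu = mu,
    block_sd = block_sd, treatment_effects = as.numeric(treatment_effects),
    plot_sd = plot_sd, subsample_sd = subsample_sd, seed = as.integer(seed)
  )
  if (any(c(spec$block_sd, spec$plot_sd, spec$subsample_sd) < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  stopifnot(
    spec$n_blocks >= 1L, spec$n_treatments >= 1L, spec$n_subsamples >= 1L,
    length(spec$treatment_effects) == spec$n_treatments
  )
  structure(spec, class = "design_spec")
}

#' Simulate a phenotype table from a blocked design with subsampling
#'
#' One row per (block, treatment, subsample). The trait is generated on the
#' log scale from the additive model in [design_spec()] and reported on the
#' natural scale (exponentiated), emulating traits that are analysed after a
#' logarithmic transformation.
#'
#' @param spec A [design_spec()] object.
#' @param trait Name of the generated trait column.
#' @return A tibble with columns `block`, `treatment`, `plot`, `subsample`
#'   and the trait.
#' @export
generate_phenotypes <- function(spec = design_spec(), trait = "trait") {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(spec$seed, {
    b <- spec$n_blocks; t <- spec$n_treatments; s <- spec$n_subsamples
    beta <- rnorm(b, 0, spec$block_sd)
    delta <- matrix(rnorm(b * t, 0, spec$plot_sd), b, t)
    grid <- expand.grid(subsample = seq_len(s), treatment = seq_len(t),
                        block = seq_len(b))
    logy <- spec$mu + beta[grid$block] + spec$treatment_effects[grid$treatment] +
      delta[cbind(grid$block, grid$treatment)] +
      rnorm(nrow(grid), 0, spec$subsample_sd)
    out <- tibble::tibble(
      block = factor(paste0("B", grid$block)),
      treatment = factor(paste0("T", grid$treatment)),
      plot = factor(paste0("B", grid$block, ":T", grid$treatment)),
      subsample = as.integer(grid$subsample)
    )
    out[[trait]] <- exp(logy)
    out[order(out$block, out$treatment, out$subsample), ]
  })
}

#' Write a scene to disk as paired PNGs plus a JSON sidecar
#'
#' `"<stem>.png"` (RGB image), `"<stem>_mask.png"` (0/255 mask) and
#' `"<stem>.json"` (instances, seed, resolution) are produced.
#'
#' @param scene A `nodule_scene`.
#' @param stem Path stem, without extension.
#' @return The stem, invisibly.
#' @export
write_scene <- function(scene, stem) {
  write_png(scene$image, paste0(stem, ".png"))
  write_mask_png(scene$mask, paste0(stem, "_mask.png"))
  side <- list(
    seed = scene$params$seed,
    mm_per_pixel = scene$mm_per_pixel,
    true_count = scene$true_count,
    true_total_area_mm2 = scene$true_total_area_mm2,
    instances = lapply(scene$instances, function(inst) {
      list(center = inst$center, radii = inst$radii,
           rotation = inst$rotation, pixel_count = inst$pixel_count)
    })
  )
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a scene written by [write_scene()]
#'
#' Instance pixel sets are not serialized; the returned object carries the
#' image, mask and the instance geometry from the sidecar.
#'
#' @param stem Path stem used when writing.
#' @return A `nodule_scene` (without per-instance pixel indices).
#' @export
read_scene <- function(stem) {
  img <- read_png(paste0(stem, ".png"))
  mask <- read_mask_png(paste0(stem, "_mask.png"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(
    image = img, mask = mask,
    instances = side$instances,
    true_count = side$true_count,
    true_total_area_mm2 = side$true_total_area_mm2,
    mm_per_pixel = side$mm_per_pixel,
    params = NULL
  ), class = "nodule_scene")
}
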