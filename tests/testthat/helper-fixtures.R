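# Shared fixtures, generated in code and memoized for the session.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

desk_scenes <- function(n = 4L, seed = 1L, ...) {
  memo(sprintf("scenes_%d_%d_%s", n, seed,
               paste(deparse(list(...)), collapse = "")),
       generate_dataset(n, desk_scene_params(...), seed = seed))
}

# One desk-scale model trained on 20 scenes, reused by every end-to-end test.
# Root junctions are the hard negatives; at 12 scenes the network still
# fires on some of them, at 20 it has seen enough root variety.
trained_desk_model <- function() {
  memo("trained_desk_model", {
    scenes <- generate_dataset(20L, desk_scene_params(), seed = 1L)
    fit <- seg_train(build_model(seg_model_config()), scenes)
    fit$model
  })
}

# A small, fast network for unit tests of the training mechanics.
tiny_config <- function(...) {
  defaults <- list(input_size = 64L, depth = 2L, base_channels = 8L,
                   epochs = 10L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(seg_model_config, defaults)
}

tiny_scenes <- function(n = 2L, seed = 11L) {
  memo(sprintf("tiny_scenes_%d_%d", n, seed),
       generate_dataset(n, desk_scene_params(
         image_height = 64L, image_width = 64L, n_nodules = 3L,
         nodule_radius_range = c(3, 6), n_roots = 1L
       ), seed = seed))
}

# Brute-force flood fill, the independent oracle for component labelling.
flood_fill_oracle <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] == 0L || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] == 1L && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Labelings are equal up to renaming of labels.
same_labeling <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 1]) &&
    !anyDuplicated(unique(cbind(a[fg], b[fg]))[, 2])
}

mask_iou <- function(a, b) {
  u <- sum(a > 0 | b > 0)
  if (u == 0) return(1)
  sum(a > 0 & b > 0) / u
}

disk_mask <- function(H, W, cr, cc, radius) {
  m <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if ((r - cr)^2 + (c - cc)^2 <= radius^2) m[r, c] <- 1L
  }
  m
}
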