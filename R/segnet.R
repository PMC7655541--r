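#' Configuration of the segmentation network
#'
#' A U-Net-style encoder-decoder: `depth` levels of two 3x3 conv + ReLU
#' blocks with 2x2 max-pooling, a bottleneck, a mirrored decoder with
#' nearest-neighbour upsampling and skip concatenation, and a 1x1 sigmoid
#' head giving one foreground probability per pixel. The defaults are the
#' desk-scale configuration (128 px inputs, depth 3, 16 base channels) that
#' trains on one CPU in minutes; a full-scale 1024 px network is the same
#' code with a different configuration.
#'
#' @param input_size Input side length in pixels; must be divisible by
#'   `2^depth` (and, for the scale-and-pad pipeline, a multiple of 32).
#' @param depth Number of down/upsampling levels (>= 1).
#' @param base_channels Channels of the first encoder level; doubled at each
#'   deeper level.
#' @param seed Integer seed for weight initialization and epoch shuffling.
#' @param loss `"dice_bce"` (soft-Dice plus binary cross-entropy, suited to
#'   the heavy class imbalance of small objects) or `"bce"`.
#' @param learning_rate Adam step size.
#' @param batch_size Images per gradient step.
#' @param epochs Training epochs (one epoch = one pass over the pairs).
#' @return An object of class `seg_model_config`.
#' @export
seg_model_config <- function(input_size = 128L, depth = 3L,
                             base_channels = 16L, seed = 1L,
                             loss = c("dice_bce", "bce"),
                             learning_rate = 1e-3, batch_size = 1L,
                             epochs = 30L) {
  loss <- match.arg(loss)
  cfg <- list(
    input_size = as.integer(input_size), depth = as.integer(depth),
    base_channels = as.integer(base_channels), seed = as.integer(seed),
    loss = loss, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs)
  )
  stopifnot(cfg$depth >= 1L, cfg$epochs >= 1L, cfg$batch_size >= 1L,
            cfg$learning_rate >= 0)
  if (cfg$input_size %% (2^cfg$depth) != 0) {
    stop("`input_size` must be divisible by 2^depth", call. = FALSE)
  }
  structure(cfg, class = "seg_model_config")
}

unet_channel_plan <- function(depth, base, cin = 3L) {
  enc <- lapply(seq_len(depth), function(d) {
    cd <- base * 2^(d - 1)
    prev <- if (d == 1L) cin else base * 2^(d - 2)
    list(c(prev, cd), c(cd, cd))
  })
  bott_in <- base * 2^(depth - 1)
  bott <- list(c(bott_in, 2L * bott_in), c(2L * bott_in, 2L * bott_in))
  dec <- lapply(rev(seq_len(depth)), function(d) {
    cd <- base * 2^(d - 1)
    up <- if (d == depth) 2L * bott_in else base * 2^d
    list(c(up + cd, cd), c(cd, cd))
  })
  convs <- c(do.call(c, enc), bott, do.call(c, dec))
  c(convs, list(c(base, 1L)))  # 1x1 head
}

#' Build a segmentation model
#'
#' Weights are He-initialized deterministically from `config$seed`.
#'
#' @param config A [seg_model_config()].
#' @return An object of class `nodule_unet`.
#' @export
build_model <- function(config = seg_model_config()) {
  stopifnot(inherits(config, "seg_model_config"))
  plan <- unet_channel_plan(config$depth, config$base_channels)
  n <- length(plan)
  weights <- vector("list", 2L * n)
  with_seed(config$seed, {
    for (i in seq_len(n)) {
      cin <- plan[[i]][1]; cout <- plan[[i]][2]
      k <- if (i == n) 1L else 3L  # head is 1x1
      fan_in <- k * k * cin
      weights[[2L * i - 1L]] <- array(
        rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)),
        dim = c(k, k, cin, cout)
      )
      weights[[2L * i]] <- numeric(cout)
    }
  })
  names(weights) <- paste0(rep(c("W", "b"), n),
                           rep(seq_len(n), each = 2L))
  structure(list(config = config, weights = weights, trained = FALSE,
                 pairs = NULL, opt = NULL, epochs_seen = 0L),
            class = "nodule_unet")
}

#' @export
print.nodule_unet <- function(x, ...) {
  np <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf(
    "<nodule_unet> input %d, depth %d, base %d, %s parameters (%strained)\n",
    x$config$input_size, x$config$depth, x$config$base_channels,
    format(np, big.mark = ","), if (x$trained) "" else "un"
  ))
  invisible(x)
}

flat_weights <- function(model) {
  n <- length(model$weights) / 2L
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    w <- model$weights[[2L * i - 1L]]
    d <- dim(w)
    out[[2L * i - 1L]] <- as.double(w)  # (k*k*cin) x cout column-major
    out[[2L * i]] <- as.double(model$weights[[2L * i]])
  }
  out
}

check_pair <- function(pair, size) {
  img <- pair$image
  mask <- pair$mask
  if (is.null(img) || is.null(mask)) {
    stop("training pairs must have `image` and `mask`", call. = FALSE)
  }
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L) stop("images must be H x W x 3",
                                           call. = FALSE)
  if (d[1L] != size || d[2L] != size) {
    stop(sprintf("image is %d x %d but the network input size is %d",
                 d[1L], d[2L], size), call. = FALSE)
  }
  if (!all(dim(mask) == d[1:2])) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  invisible(TRUE)
}

loss_weights <- function(loss) {
  if (loss == "bce") c(1, 0) else c(1, 1)
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) array(0, dim = dim(w) %||% length(w))),
       v = lapply(weights, function(w) array(0, dim = dim(w) %||% length(w))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_epochs <- function(model, pairs, config, epochs, val_pairs = NULL,
                       shuffle_seed_base = 0L) {
  size <- config$input_size
  lapply(pairs, check_pair, size = size)
  lw <- loss_weights(config$loss)
  if (is.null(model$opt)) model$opt <- adam_init(model$weights)
  opt <- model$opt
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_hist <- numeric(epochs)
  val_hist <- if (!is.null(val_pairs)) numeric(epochs) else NULL
  n <- length(pairs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(config$seed + 131L * (shuffle_seed_base + ep),
                     sample.int(n))
    losses <- numeric(n)
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(n, i + config$batch_size - 1L)]
      acc <- NULL
      for (j in batch) {
        p <- pairs[[j]]
        res <- .cpp_unet_grad(
          flat_weights(model), as.double(p$image), as.double(p$mask),
          size, size, 3L, config$depth, lw[1], lw[2]
        )
        losses[j] <- res$loss
        if (is.null(acc)) {
          acc <- res$grads
        } else {
          for (k in seq_along(acc)) acc[[k]] <- acc[[k]] + res$grads[[k]]
        }
      }
      if (lr > 0) {
        nb <- length(batch)
        opt$t <- opt$t + 1L
        bc1 <- 1 - b1^opt$t
        bc2 <- 1 - b2^opt$t
        for (k in seq_along(model$weights)) {
          g <- acc[[k]] / nb
          opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
          opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g * g
          step <- lr * (opt$m[[k]] / bc1) /
            (sqrt(opt$v[[k]] / bc2) + eps)
          model$weights[[k]] <- model$weights[[k]] -
            array(step, dim = dim(model$weights[[k]]) %||% length(step))
        }
      }
      i <- i + config$batch_size
    }
    loss_hist[ep] <- mean(losses)
    if (!is.null(val_pairs)) {
      f1s <- vapply(val_pairs, function(p) {
        pr <- seg_predict(model, p$image)
        pixel_metrics_masks(matrix(as.integer(pr >= 0.5), size, size),
                            p$mask)$f1
      }, numeric(1))
      val_hist[ep] <- mean(f1s)
    }
  }
  model$opt <- opt
  model$trained <- TRUE
  model$epochs_seen <- model$epochs_seen + epochs
  hist <- tibble::tibble(epoch = model$epochs_seen - epochs + seq_len(epochs),
                         loss = loss_hist)
  if (!is.null(val_hist)) hist$val_f1 <- val_hist
  attr(hist, "n_training_pairs") <- length(pairs)
  class(hist) <- c("train_history", class(hist))
  list(model = model, history = hist)
}

as_pairs <- function(x) {
  lapply(x, function(el) {
    if (inherits(el, "nodule_scene")) list(image = el$image, mask = el$mask)
    else el
  })
}

#' Train the segmentation network
#'
#' Adam optimization of the configured loss, one epoch being a full pass
#' over the training pairs. Scenes from [generate_scene()] can be passed
#' directly.
#'
#' @param model A [build_model()] handle.
#' @param pairs List of `list(image, mask)` pairs or `nodule_scene` objects,
#'   all at the network input size.
#' @param config Optional [seg_model_config()] overriding the model's.
#' @param val_pairs Optional validation pairs; per-epoch macro pixel F1 is
#'   then recorded in the history.
#' @return List with `model` (updated) and `history` (a tibble of per-epoch
#'   losses with attribute `n_training_pairs`).
#' @export
seg_train <- function(model, pairs, config = model$config, val_pairs = NULL) {
  stopifnot(inherits(model, "nodule_unet"))
  pairs <- as_pairs(pairs)
  if (length(pairs) == 0L) stop("empty training set", call. = FALSE)
  vp <- as_pairs(val_pairs %||% list())
  if (length(vp) == 0L) vp <- NULL
  res <- run_epochs(model, pairs, config, config$epochs, val_pairs = vp)
  res$model$pairs <- pairs
  res
}

#' Update a trained network with additional pairs (transfer learning)
#'
#' Continues optimization from the current parameters on the union of the
#' retained original pairs and the new ones (replay), mirroring incremental
#' retraining with corrected annotations.
#'
#' @inheritParams seg_train
#' @param additional_pairs New training pairs (e.g. oracle- or
#'   human-corrected masks with their images).
#' @return List with `model` and `history`.
#' @export
seg_update <- function(model, additional_pairs, config = model$config) {
  stopifnot(inherits(model, "nodule_unet"))
  if (!model$trained) stop("model has not been trained yet", call. = FALSE)
  additional_pairs <- as_pairs(additional_pairs)
  if (length(additional_pairs) == 0L) {
    stop("empty additional training set", call. = FALSE)
  }
  all_pairs <- c(model$pairs %||% list(), additional_pairs)
  res <- run_epochs(model, all_pairs, config, config$epochs,
                    shuffle_seed_base = model$epochs_seen)
  res$model$pairs <- all_pairs
  res
}

#' Predict per-pixel nodule probabilities
#'
#' Deterministic inference; output values lie in `[0, 1]`.
#'
#' @param model A `nodule_unet`.
#' @param image `H x W x 3` array at the network input size (a
#'   `nodule_scene` is also accepted).
#' @return `H x W` matrix of foreground probabilities.
#' @export
seg_predict <- function(model, image) {
  stopifnot(inherits(model, "nodule_unet"))
  if (inherits(image, "nodule_scene")) image <- image$image
  size <- model$config$input_size
  d <- dim(image)
  if (length(d) != 3L || d[1L] != size || d[2L] != size || d[3L] != 3L) {
    stop(sprintf("image must be %d x %d x 3", size, size), call. = FALSE)
  }
  p <- .cpp_unet_forward(flat_weights(model), as.double(image), size, size,
                         3L, model$config$depth)
  matrix(p, size, size)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding configuration, weights, optimizer
#' state and the retained training pairs.
#'
#' @param model A `nodule_unet`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nodule_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "nodule_unet"))
  model
}
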