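#' Pixelwise confusion counts between predicted and true masks
#'
#' True positives are true-foreground pixels predicted foreground; false
#' positives are true-background pixels predicted foreground; false
#' negatives are true-foreground pixels predicted background.
#'
#' @param pred,truth Binary matrices of identical dimensions.
#' @return Named list `TP`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as_binary_mask(pred, "pred")
  truth <- as_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` dimensions differ", call. = FALSE)
  }
  list(
    TP = sum(pred == 1L & truth == 1L),
    FP = sum(pred == 1L & truth == 0L),
    FN = sum(pred == 0L & truth == 1L)
  )
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Zero-denominator
#' conventions: with no predicted foreground, precision is 1 (no false
#' alarms); with no true foreground, recall is 1; F1 is 0 when `P + R = 0`;
#' when prediction and truth are both empty all three metrics are 1 (a
#' perfect match).
#'
#' @param TP,FP,FN Non-negative pixel counts, or a list as returned by
#'   [confusion()] passed as `TP`.
#' @return A one-row tibble `TP`, `FP`, `FN`, `precision`, `recall`, `f1`.
#' @export
f1_score <- function(TP, FP = NULL, FN = NULL) {
  if (is.list(TP)) {
    FP <- TP$FP; FN <- TP$FN; TP <- TP$TP
  }
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  precision <- if (TP + FP == 0) 1 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 1 else TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(TP = TP, FP = FP, FN = FN, precision = precision,
                 recall = recall, f1 = f1)
}

#' Pixel metrics of one predicted mask against its ground truth
#'
#' @param pred,truth Binary matrices.
#' @return One-row tibble as in [f1_score()].
#' @export
pixel_metrics_masks <- function(pred, truth) {
  f1_score(confusion(pred, truth))
}

#' Macro- and micro-averaged F1 over a set of image pairs
#'
#' Macro averaging (the reported default) computes F1 per image and averages
#' the scores; micro averaging pools the confusion counts first.
#'
#' @param preds,truths Lists of binary matrices, matched by position.
#' @param average `"macro"` or `"micro"`.
#' @return A single F1 value.
#' @export
set_f1 <- function(preds, truths, average = c("macro", "micro")) {
  average <- match.arg(average)
  stopifnot(length(preds) == length(truths))
  if (average == "macro") {
    mean(vapply(seq_along(preds), function(i) {
      pixel_metrics_masks(preds[[i]], truths[[i]])$f1
    }, numeric(1)))
  } else {
    cs <- lapply(seq_along(preds), function(i) confusion(preds[[i]], truths[[i]]))
    f1_score(sum(vapply(cs, `[[`, numeric(1), "TP")),
             sum(vapply(cs, `[[`, numeric(1), "FP")),
             sum(vapply(cs, `[[`, numeric(1), "FN")))$f1
  }
}

predict_masks <- function(model, scenes, threshold = 0.5) {
  lapply(scenes, function(sc) {
    p <- seg_predict(model, sc$image)
    matrix(as.integer(p >= threshold), nrow(p), ncol(p))
  })
}

#' Held-out F1 as a function of training-set size
#'
#' For each size, a fresh network is trained from scratch on that many
#' synthetic scenes and evaluated (macro pixel F1 at threshold 0.5, no CRF)
#' on a fixed held-out set; repeated over seeds. This is the desk-scale
#' analogue of tracking segmentation quality while the annotated corpus
#' grows.
#'
#' @param dataset_sizes Increasing vector of training-set sizes.
#' @param scene_params [scene_params()] for the synthetic family.
#' @param model_config [seg_model_config()] for the trained networks.
#' @param seeds Integer vector; each seed reseeds scene generation and
#'   initialization.
#' @param n_heldout Held-out scenes per seed.
#' @return A tibble `size`, `seed`, `f1` plus a summarized attribute-free
#'   long format; use [summarize_learning_curve()] for mean +/- sd.
#' @export
learning_curve <- function(dataset_sizes, scene_params = desk_scene_params(),
                           model_config = seg_model_config(), seeds = 1L,
                           n_heldout = 4L) {
  stopifnot(length(dataset_sizes) >= 1L, !is.unsorted(dataset_sizes),
            length(seeds) >= 1L)
  rows <- list()
  for (seed in seeds) {
    held <- generate_dataset(n_heldout, scene_params,
                             seed = 900000L + seed)
    train_pool <- generate_dataset(max(dataset_sizes), scene_params,
                                   seed = seed)
    for (size in dataset_sizes) {
      cfg <- model_config
      cfg$seed <- as.integer(model_config$seed + seed)
      model <- build_model(cfg)
      fit <- seg_train(model, train_pool[seq_len(size)])
      f1 <- set_f1(predict_masks(fit$model, held),
                   lapply(held, `[[`, "mask"))
      rows[[length(rows) + 1L]] <- tibble::tibble(size = size, seed = seed,
                                                  f1 = f1)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("learning_curve", class(out))
  out
}

#' Summarize a learning curve over seeds
#'
#' @param curve Tibble from [learning_curve()].
#' @return Tibble `size`, `mean_f1`, `sd_f1`, `n_seeds`.
#' @export
summarize_learning_curve <- function(curve) {
  curve |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(mean_f1 = mean(.data$f1),
                     sd_f1 = stats::sd(.data$f1),
                     n_seeds = dplyr::n(), .groups = "drop")
}

#' Semi-automatic correction / transfer-learning loop
#'
#' Each round: predict on a batch of new scenes, post-process, let a
#' scripted oracle corrector replace the predicted polygons with the
#' ground-truth polygons on the `k` worst-F1 scenes, update the network with
#' those corrected pairs (replaying the retained training set), and record
#' held-out macro F1. With `k = 0` no update happens and the recorded F1 is
#' constant: the loop is a no-op.
#'
#' @param initial_n Scenes used for the initial training.
#' @param rounds Number of correction rounds (>= 1).
#' @param k_corrected_per_round Scenes corrected and fed back per round.
#' @param scene_params,model_config Synthetic family and network
#'   configuration.
#' @param n_new_per_round New scenes predicted each round.
#' @param n_heldout Held-out scenes for the per-round F1.
#' @param seed Master seed.
#' @param update_epochs Epochs per incremental update; fewer than the
#'   from-scratch `model_config$epochs`, as the update continues from
#'   already-converged parameters.
#' @param use_crf Refine predictions with the default CRF before scoring
#'   candidates for correction.
#' @return A tibble `round`, `heldout_f1`, `n_pairs` (training pairs after
#'   the round), with round 0 the state before any correction.
#' @export
correction_loop <- function(initial_n = 4L, rounds = 3L,
                            k_corrected_per_round = 2L,
                            scene_params = desk_scene_params(),
                            model_config = seg_model_config(),
                            n_new_per_round = 4L, n_heldout = 4L,
                            seed = 1L, update_epochs = 10L,
                            use_crf = FALSE) {
  stopifnot(rounds >= 1L)
  held <- generate_dataset(n_heldout, scene_params, seed = 910000L + seed)
  truth_held <- lapply(held, `[[`, "mask")
  cfg <- model_config
  cfg$seed <- as.integer(model_config$seed + seed)
  model <- build_model(cfg)
  fit <- seg_train(model, generate_dataset(initial_n, scene_params,
                                           seed = seed))
  model <- fit$model
  rows <- list(tibble::tibble(
    round = 0L,
    heldout_f1 = set_f1(predict_masks(model, held), truth_held),
    n_pairs = length(model$pairs)
  ))
  for (r in seq_len(rounds)) {
    batch <- generate_dataset(n_new_per_round, scene_params,
                              seed = seed + 1000L * r)
    if (k_corrected_per_round > 0L) {
      scored <- vapply(batch, function(sc) {
        prob <- seg_predict(model, sc$image)
        post <- postprocess_prob(prob, sc$image,
                                 crf = if (use_crf) crf_params() else NULL,
                                 mm_per_pixel = sc$mm_per_pixel)
        pixel_metrics_masks(post$mask, sc$mask)$f1
      }, numeric(1))
      worst <- order(scored)[seq_len(min(k_corrected_per_round,
                                         length(batch)))]
      corrected <- lapply(batch[worst], function(sc) {
        ann <- ground_truth_annotation(sc)
        list(image = sc$image,
             mask = contours_to_mask(ann, dim(sc$mask)))
      })
      ucfg <- model$config
      ucfg$epochs <- as.integer(update_epochs)
      model <- seg_update(model, corrected, config = ucfg)$model
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      round = r,
      heldout_f1 = set_f1(predict_masks(model, held), truth_held),
      n_pairs = length(model$pairs)
    )
  }
  dplyr::bind_rows(rows)
}
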