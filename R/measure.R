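#' Calibrate the physical resolution from a reference object
#'
#' A reference of known physical length is measured in pixels in the image
#' frame; the ratio gives the mm-per-pixel scale used to convert pixel
#' counts to mm^2 areas.
#'
#' @param reference_pixel_length Measured length of the reference in pixels.
#' @param reference_mm_length Its physical length in millimetres.
#' @return mm per pixel.
#' @export
calibrate_scale <- function(reference_pixel_length, reference_mm_length) {
  if (reference_pixel_length <= 0 || reference_mm_length <= 0) {
    stop("reference lengths must be positive", call. = FALSE)
  }
  reference_mm_length / reference_pixel_length
}

#' Measure detected nodule components
#'
#' One record per surviving component: pixel count, physical area
#' (`pixel_count * mm_per_pixel^2`), centroid, bounding box and the outer
#' contour polygon. A merged blob of overlapping nodules is one record: the
#' connected component is the counting unit.
#'
#' @param components Labelled matrix from [label_components()] /
#'   [filter_by_size()].
#' @param mm_per_pixel Physical resolution (> 0).
#' @return A tibble with columns `label`, `pixel_count`, `area_mm2`,
#'   `centroid_row`, `centroid_col`, `bbox_top`, `bbox_left`, `bbox_height`,
#'   `bbox_width` and a list-column `contour` of `n x 2` (row, col)
#'   matrices.
#' @export
measure_components <- function(components, mm_per_pixel = 0.1) {
  if (mm_per_pixel <= 0) stop("`mm_per_pixel` must be positive", call. = FALSE)
  labs <- sort(unique(components[components > 0L]))
  if (length(labs) == 0L) {
    return(tibble::tibble(
      label = integer(0), pixel_count = integer(0), area_mm2 = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      bbox_top = integer(0), bbox_left = integer(0),
      bbox_height = integer(0), bbox_width = integer(0),
      contour = list()
    ))
  }
  H <- nrow(components)
  n_max <- max(labs)
  contours <- .cpp_trace_contours(components, n_max)
  rows <- lapply(labs, function(l) {
    idx <- which(components == l)
    r <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    tibble::tibble(
      label = l, pixel_count = length(idx),
      area_mm2 = length(idx) * mm_per_pixel^2,
      centroid_row = mean(r), centroid_col = mean(cc),
      bbox_top = min(r), bbox_left = min(cc),
      bbox_height = max(r) - min(r) + 1L,
      bbox_width = max(cc) - min(cc) + 1L,
      contour = list(contours[[l]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize the nodule phenotype of one image
#'
#' @param records Per-nodule tibble from [measure_components()].
#' @param image_id Identifier of the source image.
#' @return One-row tibble: `image_id`, `nodule_count`, `total_area_mm2`,
#'   `total_area_cm2` (`= total_area_mm2 / 100`) and `mean_area_mm2`
#'   (`NA` when the count is zero).
#' @export
summarize_image <- function(records, image_id = "image") {
  n <- nrow(records)
  total <- if (n > 0L) sum(records$area_mm2) else 0
  tibble::tibble(
    image_id = image_id,
    nodule_count = n,
    total_area_mm2 = total,
    total_area_cm2 = total / 100,
    mean_area_mm2 = if (n > 0L) total / n else NA_real_
  )
}

#' Run the full online pipeline on one image
#'
#' Scale-and-pad to the network input, predict, map the probabilities back
#' to the original frame, post-process and measure. Measurement happens on
#' the reconstructed full-size mask so areas are in the original pixel grid.
#'
#' @param model A trained `nodule_unet`.
#' @param image `H x W x 3` array (any size) or a `nodule_scene`.
#' @param mm_per_pixel Physical resolution of `image`.
#' @param image_id Identifier for the summary row.
#' @param crf,params CRF and post-processing parameters.
#' @param corrections Optional correction hook, see [postprocess_prob()].
#' @return List with `summary` (one-row tibble), `records` (per-nodule
#'   tibble), `mask` (full-size binary matrix) and `prob` (full-size
#'   probability matrix).
#' @export
measure_image <- function(model, image, mm_per_pixel = 0.1,
                          image_id = "image", crf = crf_params(),
                          params = postprocess_params(),
                          corrections = NULL) {
  if (inherits(image, "nodule_scene")) {
    mm_per_pixel <- image$mm_per_pixel
    image <- image$image
  }
  size <- model$config$input_size
  pre <- preprocess(image, size, kind = "image")
  prob_small <- seg_predict(model, pre$data)
  prob <- reconstruct(prob_small, pre$record, kind = "prob")
  post <- postprocess_prob(prob, image, crf = crf, params = params,
                           mm_per_pixel = mm_per_pixel,
                           corrections = corrections)
  records <- measure_components(post$components, mm_per_pixel)
  list(summary = summarize_image(records, image_id), records = records,
       mask = post$mask, prob = prob)
}
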