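#' Parameters of the dense-CRF refinement
#'
#' A two-label fully connected pairwise CRF over the probability map, with
#' unary potentials `-log p` and two Gaussian pairwise kernels: an appearance
#' kernel over (colour, position) and a smoothness kernel over position,
#' solved by mean-field iteration. Kernels are truncated at 2.5 sd; the
#' position scales default to values sized for desk-scale (~128 px) images,
#' with the colour scale and kernel weights kept from the reference method's
#' published defaults (colour sd 13/255 rescaled to the `[0, 1]` range).
#'
#' @param n_iterations Mean-field iterations (>= 1).
#' @param appearance_weight,appearance_color_sd,appearance_position_sd
#'   Appearance (bilateral) kernel weight and scales.
#' @param smoothness_weight,smoothness_position_sd Smoothness kernel weight
#'   and position scale.
#' @return An object of class `crf_params`.
#' @export
crf_params <- function(n_iterations = 5L, appearance_weight = 10,
                       appearance_color_sd = 0.05,
                       appearance_position_sd = 5,
                       smoothness_weight = 3, smoothness_position_sd = 3) {
  p <- list(
    n_iterations = as.integer(n_iterations),
    appearance_weight = appearance_weight,
    appearance_color_sd = appearance_color_sd,
    appearance_position_sd = appearance_position_sd,
    smoothness_weight = smoothness_weight,
    smoothness_position_sd = smoothness_position_sd
  )
  stopifnot(p$n_iterations >= 1L, p$appearance_weight >= 0,
            p$appearance_color_sd > 0, p$appearance_position_sd > 0,
            p$smoothness_weight >= 0, p$smoothness_position_sd > 0)
  structure(p, class = "crf_params")
}

#' Post-processing parameters
#'
#' @param prob_threshold Binarization threshold applied after CRF refinement.
#' @param closing_radius Disk radius (pixels) of the morphological closing.
#' @param min_size_mm2 Minimum component area kept, in mm^2; converted to a
#'   pixel bound via `mm_per_pixel` so the rule is resolution-independent.
#' @param max_size_mm2 Optional maximum component area in mm^2 (`Inf` keeps
#'   everything).
#' @param connectivity Pixel adjacency for component labelling: 8 (default;
#'   nodules are blobs, so diagonal contact should merge) or 4.
#' @return An object of class `postprocess_params`.
#' @export
postprocess_params <- function(prob_threshold = 0.5, closing_radius = 1L,
                               min_size_mm2 = 0.2, max_size_mm2 = Inf,
                               connectivity = 8L) {
  p <- list(
    prob_threshold = prob_threshold,
    closing_radius = as.integer(closing_radius),
    min_size_mm2 = min_size_mm2,
    max_size_mm2 = max_size_mm2,
    connectivity = as.integer(connectivity)
  )
  stopifnot(p$prob_threshold > 0, p$prob_threshold < 1,
            p$closing_radius >= 0L, p$min_size_mm2 >= 0,
            p$max_size_mm2 >= p$min_size_mm2,
            p$connectivity %in% c(4L, 8L))
  structure(p, class = "postprocess_params")
}

#' Refine a probability map with a dense CRF
#'
#' Mean-field inference couples each pixel's label to similar-looking and
#' nearby pixels, removing isolated false responses while respecting colour
#' edges. With both pairwise weights at zero the output equals the input
#' probabilities (unary-only limit).
#'
#' @param prob `H x W` matrix of foreground probabilities in `[0, 1]`.
#' @param image The corresponding `H x W x 3` image (or `H x W` grey matrix).
#' @param params A [crf_params()].
#' @return Refined `H x W` probability matrix.
#' @export
crf_refine <- function(prob, image, params = crf_params()) {
  stopifnot(inherits(params, "crf_params"))
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (nrow(prob) != d[1L] || ncol(prob) != d[2L]) {
    stop("`prob` and `image` dimensions differ", call. = FALSE)
  }
  .cpp_crf_meanfield(
    prob, as.double(image), d[3L], params$n_iterations,
    params$appearance_weight, params$appearance_color_sd,
    params$appearance_position_sd, params$smoothness_weight,
    params$smoothness_position_sd
  )
}

#' Morphological closing and interior hole filling
#'
#' Closing (dilation then erosion with a disk) bridges small gaps, after
#' which interior holes (background not connected to the border) are filled.
#' The output foreground always contains the input foreground.
#'
#' @param mask Binary matrix.
#' @param params A [postprocess_params()] (only `closing_radius` is used).
#' @return Binary 0/1 integer matrix.
#' @export
close_and_fill <- function(mask, params = postprocess_params()) {
  mask <- as_binary_mask(mask)
  out <- mask
  if (params$closing_radius > 0L) {
    out <- .cpp_erode(.cpp_dilate(out, params$closing_radius),
                      params$closing_radius)
  }
  out <- .cpp_fill_holes(out)
  # closing with a border-padded erosion is extensive, but guarantee it
  out[mask > 0L] <- 1L
  out
}

#' Label connected foreground components
#'
#' @param mask Binary matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (background 0) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  .cpp_label_components(as_binary_mask(mask), as.integer(connectivity))
}

#' Remove components outside the size bounds
#'
#' Components whose pixel count is below the (inclusive) minimum or above
#' the maximum are relabelled to background; survivors keep their labels.
#' Bounds given in mm^2 are converted with `mm_per_pixel`.
#'
#' @param components Labelled matrix from [label_components()].
#' @param params A [postprocess_params()].
#' @param mm_per_pixel Physical resolution used to convert the mm^2 bounds.
#' @return Labelled matrix with attribute `n_components` (count of
#'   survivors; labels are not renumbered).
#' @export
filter_by_size <- function(components, params = postprocess_params(),
                           mm_per_pixel = 0.1) {
  stopifnot(mm_per_pixel > 0)
  min_px <- params$min_size_mm2 / mm_per_pixel^2
  max_px <- params$max_size_mm2 / mm_per_pixel^2
  labs <- components[components > 0L]
  if (length(labs) == 0L) {
    attr(components, "n_components") <- 0L
    return(components)
  }
  sizes <- tabulate(labs)
  drop <- which(sizes < min_px | sizes > max_px)
  out <- components
  if (length(drop)) out[out %in% drop] <- 0L
  attr(out, "n_components") <- sum(sizes >= min_px & sizes <= max_px & sizes > 0L)
  out
}

#' Full post-processing of a probability map
#'
#' The online pipeline order: dense-CRF refinement, thresholding,
#' closing/hole filling, an optional error-correction hook (polygon
#' corrections applied to the binary mask), then component labelling and
#' size-based noise removal.
#'
#' @param prob `H x W` probability matrix.
#' @param image The corresponding image (for the CRF appearance kernel).
#' @param crf A [crf_params()] or `NULL` to skip refinement.
#' @param params A [postprocess_params()].
#' @param mm_per_pixel Physical resolution for the size filter.
#' @param corrections Optional function `mask -> mask` applied after
#'   closing (the semi-automatic error-correction hook; see
#'   [apply_corrections()]).
#' @return List with `mask` (binary), `components` (labelled matrix after
#'   size filtering) and `prob` (refined probabilities).
#' @export
postprocess_prob <- function(prob, image, crf = crf_params(),
                             params = postprocess_params(),
                             mm_per_pixel = 0.1, corrections = NULL) {
  refined <- if (is.null(crf)) prob else crf_refine(prob, image, crf)
  mask <- matrix(as.integer(refined >= params$prob_threshold),
                 nrow(refined), ncol(refined))
  mask <- close_and_fill(mask, params)
  if (!is.null(corrections)) mask <- as_binary_mask(corrections(mask))
  comp <- label_components(mask, params$connectivity)
  comp <- filter_by_size(comp, params, mm_per_pixel)
  list(mask = matrix(as.integer(comp > 0L), nrow(comp), ncol(comp)),
       components = comp, prob = refined)
}
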