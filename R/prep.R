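#' Resize an image or mask
#'
#' @param img Matrix or `H x W x C` array.
#' @param height,width Output dims.
#' @param method `"bilinear"` (RGB/probability data), `"nearest"` (labels),
#'   or `"area"` (box averaging, the right filter when shrinking).
#' @return Resized matrix/array of the same kind.
#' @export
resize_image <- function(img, height, width,
                         method = c("bilinear", "nearest", "area")) {
  method <- match.arg(method)
  was_matrix <- is.matrix(img)
  if (was_matrix) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img)
  fn <- switch(method, bilinear = .cpp_resize_bilinear,
               nearest = .cpp_resize_nearest, area = .cpp_resize_area)
  out <- fn(as.double(img), d[1L], d[2L], d[3L], as.integer(height),
            as.integer(width))
  out <- array(out, dim = c(height, width, d[3L]))
  if (was_matrix) out <- out[, , 1L]
  out
}

# binary masks: area-average when shrinking, bilinear when enlarging, then
# re-threshold at the 0.5 level so the result stays binary
resize_mask <- function(mask, height, width) {
  shrink <- height <= nrow(mask) && width <= ncol(mask)
  out <- resize_image(matrix(as.double(mask != 0), nrow(mask), ncol(mask)),
                      height, width,
                      method = if (shrink) "area" else "bilinear")
  matrix(as.integer(out >= 0.5), height, width)
}

#' Geometry of the scale-and-pad mapping to the network input size
#'
#' A single isotropic scale factor `target_size / max(height, width)` shrinks
#' the image so its longer side equals `target_size` (floor rounding on the
#' shorter side); the remainder is filled by centred constant padding. The
#' record suffices to invert the mapping exactly.
#'
#' @param height,width Original image dims in pixels.
#' @param target_size Network input size; must be a multiple of 32 (the
#'   encoder halves the grid at every level).
#' @return An object of class `transform_record`.
#' @export
transform_record <- function(height, width, target_size) {
  if (target_size %% 32 != 0) {
    stop("`target_size` must be a multiple of 32", call. = FALSE)
  }
  stopifnot(height >= 1, width >= 1)
  scale <- target_size / max(height, width)
  sh <- if (height >= width) target_size else floor(height * target_size / width)
  sw <- if (width >= height) target_size else floor(width * target_size / height)
  structure(list(
    original_height = as.integer(height),
    original_width = as.integer(width),
    scale = scale,
    scaled_height = as.integer(sh),
    scaled_width = as.integer(sw),
    pad_top = as.integer((target_size - sh) %/% 2),
    pad_left = as.integer((target_size - sw) %/% 2),
    target_size = as.integer(target_size)
  ), class = "transform_record")
}

#' Scale and pad an image to the network input size
#'
#' RGB images are resampled bilinearly and padded with their mean intensity;
#' masks are resampled with area averaging and padded with background.
#'
#' @param image Matrix (mask/grey) or `H x W x 3` array.
#' @param target_size Network input size, multiple of 32 (e.g. 1024 for
#'   full-scale camera images, 128 for the desk configuration).
#' @param kind `"image"` or `"mask"`; masks are area-average resampled and
#'   re-thresholded at 0.5 so they stay binary.
#' @return List with `data` (the `target_size` square image) and `record`
#'   (a [transform_record()]).
#' @export
preprocess <- function(image, target_size, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  d <- dim(image)
  rec <- transform_record(d[1L], d[2L], target_size)
  small <- if (kind == "mask") {
    resize_mask(image, rec$scaled_height, rec$scaled_width)
  } else {
    resize_image(image, rec$scaled_height, rec$scaled_width, "bilinear")
  }
  pad_value <- if (kind == "mask") 0 else mean(image)
  if (is.matrix(small)) {
    out <- matrix(pad_value, target_size, target_size)
    out[rec$pad_top + seq_len(rec$scaled_height),
        rec$pad_left + seq_len(rec$scaled_width)] <- small
    if (kind == "mask") storage.mode(out) <- "integer"
  } else {
    out <- array(pad_value, dim = c(target_size, target_size, d[3L]))
    out[rec$pad_top + seq_len(rec$scaled_height),
        rec$pad_left + seq_len(rec$scaled_width), ] <- small
  }
  list(data = out, record = rec)
}

#' Map a network-sized mask or probability map back to the original frame
#'
#' Strips the padding recorded in `record` and rescales the content back to
#' the original dimensions (bilinear with 0.5 re-thresholding for binary
#' masks, bilinear for probability maps).
#'
#' @param mask_small `target_size` x `target_size` matrix.
#' @param record The [transform_record()] from [preprocess()].
#' @param kind `"mask"` or `"prob"`.
#' @return Matrix at the original dimensions.
#' @export
reconstruct <- function(mask_small, record, kind = c("mask", "prob")) {
  kind <- match.arg(kind)
  stopifnot(inherits(record, "transform_record"))
  if (!is.matrix(mask_small) ||
      nrow(mask_small) != record$target_size ||
      ncol(mask_small) != record$target_size) {
    stop("`mask_small` dimensions do not match the transform record",
         call. = FALSE)
  }
  content <- mask_small[record$pad_top + seq_len(record$scaled_height),
                        record$pad_left + seq_len(record$scaled_width),
                        drop = FALSE]
  if (kind == "mask") {
    resize_mask(content, record$original_height, record$original_width)
  } else {
    resize_image(content, record$original_height, record$original_width,
                 method = "bilinear")
  }
}
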