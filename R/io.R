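#' Read a PNG image
#'
#' Minimal reader for 8-bit, non-interlaced greyscale/RGB/RGBA PNG files.
#' Values are returned in `[0, 1]`.
#'
#' @param path Path to a PNG file.
#' @return A numeric array `H x W x C`, or an `H x W` matrix for greyscale.
#' @export
read_png <- function(path) {
  res <- .cpp_read_png(path.expand(path))
  a <- array(res$pixels, dim = c(res$height, res$width, res$channels))
  if (res$channels == 1L) a <- a[, , 1L]
  a
}

#' Write a PNG image
#'
#' Values outside `[0, 1]` are clipped. A matrix is written as greyscale,
#' an `H x W x 3` array as RGB.
#'
#' @param img Numeric matrix or `H x W x C` array with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img)
  .cpp_write_png(path.expand(path), as.double(img), d[1L], d[2L], d[3L])
  invisible(path)
}

#' Write a binary nodule mask as a 0/255 PNG
#'
#' @param mask Integer or logical matrix; non-zero is foreground.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  write_png(matrix(as.double(mask != 0), nrow(mask), ncol(mask)), path)
}

#' Read a 0/255 PNG as a binary mask
#'
#' @param path Path to a PNG mask.
#' @return Integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  m <- read_png(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
}

as_binary_mask <- function(mask, arg = "mask") {
  if (is.logical(mask)) mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!is.matrix(mask) || !is.numeric(mask)) {
    stop(sprintf("`%s` must be a binary matrix", arg), call. = FALSE)
  }
  storage.mode(mask) <- "integer"
  if (any(mask != 0L & mask != 1L)) mask <- matrix(as.integer(mask != 0L), nrow(mask), ncol(mask))
  mask
}
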