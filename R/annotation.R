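#' Polygon annotations for one image
#'
#' The data layer of the semi-automatic annotation tool: a set of closed
#' polygons (vertex lists in (row, col) image coordinates, >= 3 vertices
#' each) with a provenance flag per polygon.
#'
#' @param polygons List of `n x 2` numeric matrices (columns row, col).
#' @param image_id Identifier of the annotated image.
#' @param provenance Character vector recycled over polygons: `"manual"`,
#'   `"predicted"` or `"corrected"`.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(polygons = list(), image_id = "image",
                               provenance = "manual") {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 3L) stop("every polygon needs >= 3 vertices", call. = FALSE)
    colnames(p) <- c("row", "col")
    p
  })
  provenance <- rep_len(match.arg(provenance,
                                  c("manual", "predicted", "corrected"),
                                  several.ok = TRUE),
                        length(polygons))
  structure(list(image_id = image_id, polygons = polygons,
                 provenance = provenance),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation> '%s': %d polygon(s)\n", x$image_id,
              length(x$polygons)))
  invisible(x)
}

#' Extract nodule contours from a binary mask
#'
#' One outer contour polygon per connected component, traced along the
#' pixel boundary (vertices on the half-integer pixel-corner grid), so that
#' rasterizing the contours recovers the component up to boundary pixels.
#'
#' @param mask Binary matrix.
#' @param image_id Identifier for the annotation.
#' @param connectivity Component adjacency, 8 (default) or 4.
#' @param provenance Provenance recorded for the polygons.
#' @return A [polygon_annotation()]; empty for an empty mask.
#' @export
mask_to_contours <- function(mask, image_id = "image", connectivity = 8L,
                             provenance = "predicted") {
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n_components")
  if (n == 0L) return(polygon_annotation(list(), image_id, provenance))
  polys <- .cpp_trace_contours(lab, n)
  polygon_annotation(polys, image_id, provenance)
}

#' Rasterize polygon annotations to a binary mask
#'
#' Even-odd scanline filling over pixel centres; overlapping polygons
#' union.
#'
#' @param annotation A [polygon_annotation()].
#' @param dims Length-2 integer vector `(height, width)`.
#' @return Binary 0/1 integer matrix.
#' @export
contours_to_mask <- function(annotation, dims) {
  stopifnot(inherits(annotation, "polygon_annotation"), length(dims) == 2L)
  if (length(annotation$polygons) == 0L) {
    return(matrix(0L, dims[1L], dims[2L]))
  }
  .cpp_rasterize_polygons(annotation$polygons, as.integer(dims[1L]),
                          as.integer(dims[2L]))
}

#' Apply polygon corrections to a predicted mask
#'
#' `output = (predicted UNION rasterize(add)) MINUS rasterize(remove)`;
#' removal wins where the two overlap. Idempotent for fixed corrections.
#'
#' @param predicted Binary matrix from the pipeline.
#' @param add [polygon_annotation()] of regions to add (missed nodules).
#' @param remove [polygon_annotation()] of regions to erase (false
#'   detections).
#' @return Corrected binary 0/1 integer matrix.
#' @export
apply_corrections <- function(predicted,
                              add = polygon_annotation(),
                              remove = polygon_annotation()) {
  predicted <- as_binary_mask(predicted, "predicted")
  dims <- dim(predicted)
  out <- predicted
  if (length(add$polygons) > 0L) {
    out <- pmax(out, contours_to_mask(add, dims))
  }
  if (length(remove$polygons) > 0L) {
    out[contours_to_mask(remove, dims) > 0L] <- 0L
  }
  storage.mode(out) <- "integer"
  out
}

#' Ground-truth polygon annotation of a synthetic scene
#'
#' Each instance's own pixel raster is traced separately, so overlapping
#' nodules yield one polygon each even where their mask pixels merge. This
#' is what the scripted "oracle corrector" feeds back in place of a human
#' annotator.
#'
#' @param scene A `nodule_scene`.
#' @param image_id Identifier for the annotation.
#' @return A [polygon_annotation()] with provenance `"manual"`.
#' @export
ground_truth_annotation <- function(scene, image_id = "truth") {
  stopifnot(inherits(scene, "nodule_scene"))
  H <- nrow(scene$mask); W <- ncol(scene$mask)
  polys <- lapply(scene$instances, function(inst) {
    m <- matrix(0L, H, W)
    m[inst$pixels] <- 1L
    lab <- label_components(m, 8L)
    .cpp_trace_contours(lab, attr(lab, "n_components"))[[1L]]
  })
  polygon_annotation(polys, image_id, "manual")
}

#' Write / read annotations as LabelMe-style JSON
#'
#' The interchange dialect is LabelMe-compatible: `imagePath`,
#' `imageHeight`, `imageWidth` and `shapes` entries with `label`, `points`
#' (x, y = col, row order, 0-based) and `shape_type = "polygon"`. All
#' shapes carry the single class label `"nodule"`.
#'
#' @param annotation A [polygon_annotation()].
#' @param path Output JSON path.
#' @param dims Image dims `(height, width)` recorded in the file.
#' @return `path` invisibly; `read_annotation_json()` returns a
#'   [polygon_annotation()].
#' @export
write_annotation_json <- function(annotation, path, dims = c(NA, NA)) {
  stopifnot(inherits(annotation, "polygon_annotation"))
  shapes <- mapply(function(poly, prov) {
    list(
      label = "nodule",
      points = unname(apply(poly, 1L,
                            function(v) c(v[2L] - 1, v[1L] - 1),
                            simplify = FALSE)),
      group_id = NULL,
      shape_type = "polygon",
      flags = list(provenance = prov)
    )
  }, annotation$polygons, annotation$provenance, SIMPLIFY = FALSE)
  obj <- list(
    version = "5.0.0",
    flags = list(),
    shapes = shapes,
    imagePath = annotation$image_id,
    imageHeight = dims[1L],
    imageWidth = dims[2L]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- lapply(obj$shapes, function(sh) {
    pts <- do.call(rbind, lapply(sh$points, function(p) {
      c(row = as.numeric(p[[2L]]) + 1, col = as.numeric(p[[1L]]) + 1)
    }))
    pts
  })
  prov <- vapply(obj$shapes, function(sh) {
    pr <- sh$flags$provenance
    if (is.null(pr)) "manual" else pr
  }, character(1))
  polygon_annotation(polys, obj$imagePath %||% "image",
                     if (length(prov)) prov else "manual")
}
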