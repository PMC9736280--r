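# Post-processing of probability maps: binarize, keep the largest connected
# glottis component, restrict the other classes to that ROI.

#' Binarize probability maps
#'
#' @param maps A `fees_probmaps` (H x W x C array in `[0, 1]`).
#' @param threshold Decision threshold in `(0, 1)`; pixels `>= threshold`
#'   become foreground.
#' @return Named list of binary masks, one per channel.
#' @export
binarize <- function(maps, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).", class = "feesxai_config_error")
  }
  cls <- dimnames(maps)[[3]] %||% frame_classes[seq_len(dim(maps)[3])]
  out <- lapply(seq_len(dim(maps)[3]), function(c) maps[, , c] >= threshold)
  names(out) <- cls
  out
}

#' Keep the largest connected component of a binary mask
#'
#' Components are found with the given pixel connectivity; among equal-size
#' components the one whose first pixel in row-major scan order comes first
#' (smallest `(row, col)`) is kept. An empty mask stays empty.
#'
#' @param mask Binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return Binary matrix containing exactly one component (or none).
#' @export
largest_connected_component <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(4L, 8L)) {
    abort("`connectivity` must be 4 or 8.", class = "feesxai_config_error")
  }
  if (!any(mask)) return(mask)
  lab <- cpp_label_components(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  # ties: labels are assigned in row-major discovery order, so the smallest
  # label among maxima is the component found first in scan order
  keep <- which(sizes == max(sizes))[1]
  lab == keep
}

#' Restrict a class mask to the glottis ROI
#'
#' @param roi_mask Binary glottis ROI mask.
#' @param class_mask Binary mask of the same shape.
#' @return Pixelwise AND of the two masks.
#' @export
restrict_to_roi <- function(roi_mask, class_mask) {
  roi_mask <- as_mask(roi_mask, "roi_mask")
  class_mask <- as_mask(class_mask, "class_mask")
  check_same_shape(roi_mask, class_mask, "roi_mask/class_mask")
  roi_mask & class_mask
}

#' Post-process probability maps into a final segmentation
#'
#' Binarizes all channels, keeps the largest connected component of the
#' glottis channel, and restricts the vocal-cord and aspiration masks to that
#' selected ROI component.
#'
#' @inheritParams binarize
#' @inheritParams largest_connected_component
#' @return A `fees_segmentation`: binary masks `glottis_roi`, `vocal_cords`,
#'   `aspiration` plus a `pixel_counts` vector recomputed from the final
#'   masks.
#' @export
postprocess_frame <- function(maps, threshold = 0.5, connectivity = 8L) {
  masks <- binarize(maps, threshold)
  glottis <- largest_connected_component(masks$glottis_roi, connectivity)
  cords <- restrict_to_roi(glottis, masks$vocal_cords)
  aspiration <- restrict_to_roi(glottis, masks$aspiration)
  fees_segmentation(glottis, cords, aspiration)
}

#' Construct a segmentation result
#'
#' @param glottis_roi,vocal_cords,aspiration Binary masks of one shape.
#' @return A `fees_segmentation` with per-class pixel counts.
#' @export
fees_segmentation <- function(glottis_roi, vocal_cords, aspiration) {
  glottis_roi <- as_mask(glottis_roi, "glottis_roi")
  vocal_cords <- as_mask(vocal_cords, "vocal_cords")
  aspiration <- as_mask(aspiration, "aspiration")
  check_same_shape(glottis_roi, vocal_cords)
  check_same_shape(glottis_roi, aspiration)
  structure(
    list(glottis_roi = glottis_roi, vocal_cords = vocal_cords,
         aspiration = aspiration,
         pixel_counts = c(glottis_roi = sum(glottis_roi),
                          vocal_cords = sum(vocal_cords),
                          aspiration = sum(aspiration))),
    class = "fees_segmentation")
}

#' @export
print.fees_segmentation <- function(x, ...) {
  cat(sprintf("<fees_segmentation> %dx%d  glottis:%d cords:%d aspiration:%d\n",
              nrow(x$glottis_roi), ncol(x$glottis_roi),
              x$pixel_counts[1], x$pixel_counts[2], x$pixel_counts[3]))
  invisible(x)
}

#' Serialize / read a segmentation result
#'
#' Same layout as reference annotations: one 0/255 PNG per class plus a JSON
#' file with the pixel counts.
#'
#' @param seg A `fees_segmentation`.
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return Paths written, invisibly.
#' @export
write_segmentation <- function(seg, dir, stem) {
  stopifnot(inherits(seg, "fees_segmentation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cls in frame_classes) {
    p <- file.path(dir, sprintf("%s_%s.png", stem, cls))
    png::writePNG(matrix(as.numeric(seg[[cls]]), nrow(seg[[cls]])), p)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, paste0(stem, "_counts.json"))
  jsonlite::write_json(as.list(seg$pixel_counts), jp, auto_unbox = TRUE)
  invisible(c(paths, jp))
}
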