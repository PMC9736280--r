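#' Construct a video frame
#'
#' A frame is an H x W x 3 array of 8-bit intensities (stored as numerics in
#' 0..255) tagged with its source video id and 0-based temporal index.
#'
#' @param pixels Numeric H x W x 3 array with values in 0..255 (a matrix is
#'   promoted to three identical channels).
#' @param video_id Character scalar identifying the source video.
#' @param frame_index Integer >= 0, position of the frame in the video.
#' @return An object of class `fees_frame`.
#' @export
fees_frame <- function(pixels, video_id = "video", frame_index = 0L) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array.", class = "feesxai_validation_error")
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    abort("Frame dimensions must be positive.", class = "feesxai_validation_error")
  }
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) {
    abort("`frame_index` must be a non-negative integer.",
          class = "feesxai_validation_error")
  }
  structure(
    list(pixels = clamp(pixels, 0, 255), video_id = as.character(video_id),
         frame_index = frame_index),
    class = "fees_frame"
  )
}

#' @export
print.fees_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fees_frame> %s #%d  %dx%d px\n", x$video_id, x$frame_index,
              d[1], d[2]))
  invisible(x)
}

frame_classes <- c("glottis_roi", "vocal_cords", "aspiration")
glottis_states <- c("open", "closed", "obscured", "unknown")
bolus_types <- c("slurry", "saliva", "liquid", "none")

#' Construct a reference annotation
#'
#' Holds one binary mask per structure (glottis region of interest, vocal
#' cords, aspirated bolus), the frame-level glottis-visibility label, the
#' glottis state and the bolus type. Masks may overlap: an aspirated bolus
#' lies inside the glottis ROI by definition.
#'
#' @param glottis_roi,vocal_cords,aspiration Binary matrices of one shape.
#' @param glottis_visible Logical; `FALSE` requires an empty `glottis_roi`.
#' @param glottis_state One of `"open"`, `"closed"`, `"obscured"`, `"unknown"`.
#' @param bolus_type One of `"slurry"`, `"saliva"`, `"liquid"`, `"none"`.
#' @return An object of class `fees_annotation`.
#' @export
fees_annotation <- function(glottis_roi, vocal_cords = NULL, aspiration = NULL,
                            glottis_visible = any(glottis_roi),
                            glottis_state = "unknown", bolus_type = "none") {
  glottis_roi <- as_mask(glottis_roi, "glottis_roi")
  if (is.null(vocal_cords)) vocal_cords <- matrix(FALSE, nrow(glottis_roi), ncol(glottis_roi))
  if (is.null(aspiration)) aspiration <- matrix(FALSE, nrow(glottis_roi), ncol(glottis_roi))
  vocal_cords <- as_mask(vocal_cords, "vocal_cords")
  aspiration <- as_mask(aspiration, "aspiration")
  check_same_shape(glottis_roi, vocal_cords, "glottis_roi/vocal_cords")
  check_same_shape(glottis_roi, aspiration, "glottis_roi/aspiration")
  glottis_state <- match.arg(glottis_state, glottis_states)
  bolus_type <- match.arg(bolus_type, bolus_types)
  if (!isTRUE(glottis_visible) && any(glottis_roi)) {
    abort("glottis_visible = FALSE requires an empty glottis ROI mask.",
          class = "feesxai_validation_error")
  }
  structure(
    list(glottis_roi = glottis_roi, vocal_cords = vocal_cords,
         aspiration = aspiration, glottis_visible = isTRUE(glottis_visible),
         glottis_state = glottis_state, bolus_type = bolus_type),
    class = "fees_annotation"
  )
}

#' @export
print.fees_annotation <- function(x, ...) {
  cat(sprintf(
    "<fees_annotation> %dx%d  glottis:%d cords:%d aspiration:%d visible:%s state:%s bolus:%s\n",
    nrow(x$glottis_roi), ncol(x$glottis_roi), sum(x$glottis_roi),
    sum(x$vocal_cords), sum(x$aspiration), x$glottis_visible,
    x$glottis_state, x$bolus_type))
  invisible(x)
}

# ---- video container: one PNG per frame plus a JSON index -------------------

frame_file <- function(i) sprintf("frame_%06d.png", i)

#' Write a video as a lossless frame-sequence directory
#'
#' The package's native video container is a directory holding one PNG per
#' frame (`frame_000000.png`, ...) plus `video.json` with the video id and
#' frame count; the round trip through [read_video()] is bit-exact.
#'
#' @param frames List of [fees_frame()] objects in temporal order.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_video <- function(frames, dir) {
  if (length(frames) == 0L) abort("No frames to write.", class = "feesxai_io_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]]$pixels / 255, file.path(dir, frame_file(i - 1L)))
  }
  meta <- list(video_id = frames[[1]]$video_id, n_frames = length(frames))
  jsonlite::write_json(meta, file.path(dir, "video.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a video from a frame-sequence directory
#'
#' @param path Directory written by [write_video()] (or any directory of
#'   `frame_*.png` files).
#' @return List of [fees_frame()] objects with 0-based `frame_index` in
#'   temporal order.
#' @export
read_video <- function(path) {
  if (!dir.exists(path)) {
    abort(sprintf("Video directory not found: %s", path), class = "feesxai_io_error")
  }
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("No frames found in %s", path), class = "feesxai_io_error")
  }
  video_id <- basename(path)
  meta_path <- file.path(path, "video.json")
  if (file.exists(meta_path)) {
    video_id <- jsonlite::read_json(meta_path)$video_id %||% video_id
  }
  lapply(seq_along(files), function(i) {
    px <- png::readPNG(files[[i]])
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
    px <- px[, , 1:3, drop = FALSE]
    fees_frame(round(px * 255), video_id = video_id, frame_index = i - 1L)
  })
}

# ---- annotation serialization ----------------------------------------------

#' Write a reference annotation
#'
#' Each class mask goes to `<stem>_<class>.png` (values 0/255) and the frame
#' labels to `<stem>.json`.
#'
#' @param ann A [fees_annotation()].
#' @param dir Output directory.
#' @param stem File-name stem, e.g. `"frame_000004"`.
#' @return Character vector of the paths written, invisibly.
#' @export
write_annotation <- function(ann, dir, stem) {
  stopifnot(inherits(ann, "fees_annotation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cls in frame_classes) {
    p <- file.path(dir, sprintf("%s_%s.png", stem, cls))
    png::writePNG(matrix(as.numeric(ann[[cls]]), nrow(ann[[cls]])), p)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(glottis_visible = ann$glottis_visible, glottis_state = ann$glottis_state,
         bolus_type = ann$bolus_type),
    jp, auto_unbox = TRUE)
  invisible(c(paths, jp))
}

read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  vals <- round(px * 255)
  if (!all(vals %in% c(0, 255))) {
    abort(sprintf("Mask PNG %s is not binary (0/255).", basename(path)),
          class = "feesxai_validation_error")
  }
  vals == 255
}

#' Read a reference annotation written by [write_annotation()]
#'
#' @inheritParams write_annotation
#' @return A [fees_annotation()].
#' @export
read_annotation <- function(dir, stem) {
  masks <- lapply(frame_classes, function(cls) {
    read_mask_png(file.path(dir, sprintf("%s_%s.png", stem, cls)))
  })
  names(masks) <- frame_classes
  lab <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")))
  fees_annotation(masks$glottis_roi, masks$vocal_cords, masks$aspiration,
                  glottis_visible = isTRUE(lab$glottis_visible),
                  glottis_state = lab$glottis_state %||% "unknown",
                  bolus_type = lab$bolus_type %||% "none")
}

#' Write / read a frame index as JSON lines
#'
#' One JSON object per line with the frame-level labels (video id, frame
#' index, visibility, state, bolus type and pixel counts) — the dataset's
#' lightweight manifest.
#'
#' @param index A tibble such as `tidy(<fees_dataset>)`.
#' @param path Output `.jsonl` file.
#' @return `path`, invisibly.
#' @export
write_frame_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(index))) {
    writeLines(jsonlite::toJSON(as.list(index[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_frame_index
#' @export
read_frame_index <- function(path) {
  lines <- readLines(path)
  dplyr::bind_rows(lapply(lines, function(l) {
    as_tibble(jsonlite::fromJSON(l))
  }))
}

# ---- dataset splitting ------------------------------------------------------

#' Split videos into disjoint train/validation/test sets
#'
#' Assignment is at the video level so no video contributes frames to two
#' splits. Counts are `round(fraction * n)` with any rounding remainder
#' absorbed by the training set; the permutation is deterministic per seed.
#'
#' @param video_ids Character vector of unique video identifiers.
#' @param fractions Numeric length-3 vector `(train, validation, test)`
#'   summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @return A tibble with columns `video_id`, `split` (factor
#'   train/validation/test).
#' @export
split_dataset <- function(video_ids, fractions = c(0.772, 0.065, 0.163),
                          seed = 1L) {
  video_ids <- as.character(video_ids)
  if (anyDuplicated(video_ids)) {
    abort("`video_ids` must be unique.", class = "feesxai_config_error")
  }
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three non-negative numbers summing to 1.",
          class = "feesxai_config_error")
  }
  n <- length(video_ids)
  if (n < sum(fractions > 0)) {
    abort("Fewer videos than non-empty splits.", class = "feesxai_config_error")
  }
  counts <- round(fractions * n)
  counts[1] <- counts[1] + (n - sum(counts))
  if (counts[1] < 0) abort("Rounding produced a negative training count.",
                           class = "feesxai_config_error")
  perm <- with_seed(seed, sample.int(n))
  split <- rep(c("train", "validation", "test"), times = counts)
  tibble(
    video_id = video_ids[perm],
    split = factor(split, levels = c("train", "validation", "test"))
  ) |> dplyr::arrange(.data$video_id)
}
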