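# Explainability layer: whole-video pixel-count timelines, consecutive-frame
# aspiration candidates ("meaningful frames") and contour-overlay rendering.

#' Compute a per-frame pixel-count timeline for a video
#'
#' Applies the model and post-processing to every frame and records the final
#' per-class pixel counts, giving the examiner a one-glance overview of where
#' the structures and aspiration candidates appear.
#'
#' @param video A `fees_dataset`, a list of [fees_frame()]s, or a path to a
#'   frame-sequence directory (see [read_video()]).
#' @param model A `fees_unet` or prediction function.
#' @param threshold,connectivity Post-processing parameters.
#' @param downscale Run at half resolution (the pipeline's working
#'   resolution).
#' @param keep_segmentations Also return the per-frame `fees_segmentation`s
#'   (needed for overlay rendering).
#' @return A `fees_timeline` tibble: `frame_index`, `glottis_pixels`,
#'   `vocal_cord_pixels`, `aspiration_pixels`. With
#'   `keep_segmentations = TRUE` the list of segmentations is attached as
#'   attribute `"segmentations"`.
#' @export
compute_timeline <- function(video, model, threshold = 0.5, connectivity = 8L,
                             downscale = TRUE, keep_segmentations = FALSE) {
  frames <- timeline_frames(video)
  segs <- vector("list", length(frames))
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    frame <- frames[[i]]
    if (downscale) frame <- downscale_frame(frame)
    maps <- predict_frame(model, frame)
    seg <- postprocess_frame(maps, threshold, connectivity)
    segs[[i]] <- seg
    rows[[i]] <- tibble(
      frame_index = frames[[i]]$frame_index,
      glottis_pixels = seg$pixel_counts[["glottis_roi"]],
      vocal_cord_pixels = seg$pixel_counts[["vocal_cords"]],
      aspiration_pixels = seg$pixel_counts[["aspiration"]])
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fees_timeline", class(out))
  if (keep_segmentations) attr(out, "segmentations") <- segs
  out
}

timeline_frames <- function(video) {
  if (inherits(video, "fees_dataset")) return(video$frames)
  if (is.character(video)) return(read_video(video))
  if (is.list(video) && all(vapply(video, inherits, logical(1), "fees_frame"))) {
    return(video)
  }
  abort("`video` must be a fees_dataset, a list of frames, or a directory path.",
        class = "feesxai_io_error")
}

#' Detect runs of consecutive aspiration frames
#'
#' The "meaningful frames" rule: maximal runs of consecutive frames whose
#' aspiration pixel count is at least `min_pixels`, kept when at least
#' `min_consecutive` frames long. The peak frame is the earliest frame
#' attaining the run's maximum count.
#'
#' @param timeline A `fees_timeline` (or any data frame with `frame_index`
#'   and `aspiration_pixels`).
#' @param min_consecutive Minimum run length in frames (>= 1).
#' @param min_pixels Minimum aspiration pixels for a frame to count (>= 1).
#' @return Tibble of event runs: `start_frame`, `end_frame` (inclusive),
#'   `peak_frame`, `peak_pixels`, `total_pixels`.
#' @export
detect_event_runs <- function(timeline, min_consecutive = 3L, min_pixels = 1L) {
  if (min_consecutive < 1L || min_pixels < 1L) {
    abort("`min_consecutive` and `min_pixels` must be >= 1.",
          class = "feesxai_config_error")
  }
  timeline <- dplyr::arrange(as_tibble(timeline), .data$frame_index)
  active <- timeline$aspiration_pixels >= min_pixels
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_consecutive)
  rows <- lapply(keep, function(k) {
    seg <- timeline[starts[k]:ends[k], ]
    peak <- which.max(seg$aspiration_pixels) # earliest argmax
    tibble(start_frame = seg$frame_index[1],
           end_frame = seg$frame_index[nrow(seg)],
           peak_frame = seg$frame_index[peak],
           peak_pixels = seg$aspiration_pixels[peak],
           total_pixels = sum(seg$aspiration_pixels))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(start_frame = integer(0), end_frame = integer(0),
           peak_frame = integer(0), peak_pixels = numeric(0),
           total_pixels = numeric(0))
  dplyr::arrange(out, .data$start_frame)
}

# Contour band of a mask: foreground pixels with a background 4-neighbour.
mask_contour <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  h <- nrow(mask); w <- ncol(mask)
  pad <- function(di, dj) {
    m <- matrix(FALSE, h, w)
    si <- clamp(seq_len(h) + di, 1L, h)
    sj <- clamp(seq_len(w) + dj, 1L, w)
    m <- mask[si, sj, drop = FALSE]
    m
  }
  interior <- pad(-1, 0) & pad(1, 0) & pad(0, -1) & pad(0, 1)
  mask & !interior
}

overlay_palette <- c(glottis_roi = "yellow", vocal_cords = "cyan",
                     aspiration = "magenta")

palette_rgb <- function(palette) {
  lapply(palette, function(col) as.numeric(grDevices::col2rgb(col)))
}

draw_contour <- function(px, contour, rgb, dotted = FALSE) {
  if (!any(contour)) return(px)
  if (dotted) {
    idx <- which(contour, arr.ind = TRUE)
    keep <- (idx[, 1] + idx[, 2]) %% 3L == 0L # dotted style
    contour[] <- FALSE
    contour[idx[keep, , drop = FALSE]] <- TRUE
  }
  for (ch in 1:3) {
    m <- px[, , ch]
    m[contour] <- rgb[ch]
    px[, , ch] <- m
  }
  px
}

#' Render a contour-overlay video
#'
#' Draws each class's segmentation as a solid contour line in the standard
#' palette (yellow glottis ROI, cyan vocal cords, magenta detected
#' aspiration) on every frame; reference annotations, when given, are drawn
#' as dotted contours. Pixels outside the contour bands are unmodified.
#'
#' @param video As in [compute_timeline()].
#' @param segmentations List of `fees_segmentation`s, one per frame (e.g.
#'   from [compute_timeline()] with `keep_segmentations = TRUE`).
#' @param out_dir Output frame-sequence directory.
#' @param palette Named colours for the three classes.
#' @param reference Optional list of [fees_annotation()]s drawn dotted.
#' @param downscale Whether segmentations are at half the frame resolution
#'   (frames are downscaled before drawing so shapes align).
#' @return `out_dir`, invisibly.
#' @export
render_overlay_video <- function(video, segmentations, out_dir,
                                 palette = overlay_palette, reference = NULL,
                                 downscale = TRUE) {
  frames <- timeline_frames(video)
  if (length(frames) != length(segmentations)) {
    abort("Frame count and segmentation count differ.",
          class = "feesxai_validation_error")
  }
  if (!is.null(reference) && length(reference) != length(frames)) {
    abort("Frame count and reference count differ.",
          class = "feesxai_validation_error")
  }
  cols <- palette_rgb(palette)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    frame <- frames[[i]]
    if (downscale) frame <- downscale_frame(frame)
    px <- frame$pixels
    if (!is.null(reference)) {
      ref <- if (downscale) downscale_annotation(reference[[i]]) else reference[[i]]
      for (cls in names(palette)) {
        px <- draw_contour(px, mask_contour(ref[[cls]]), cols[[cls]], dotted = TRUE)
      }
    }
    for (cls in names(palette)) {
      px <- draw_contour(px, mask_contour(segmentations[[i]][[cls]]), cols[[cls]])
    }
    out[[i]] <- fees_frame(px, frame$video_id, frame$frame_index)
  }
  write_video(out, out_dir)
}

#' Export a timeline: CSV, event JSON and plot
#'
#' Writes `timeline.csv` (one row per frame), `events.json` (runs sorted by
#' start frame) and `timeline.png` with per-class pixel-count curves, shaded
#' event spans, and a zoom panel around the highest-peak event.
#'
#' @param timeline A `fees_timeline`.
#' @param events Event runs from [detect_event_runs()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
export_timeline <- function(timeline, events, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot create output directory %s", dir),
          class = "feesxai_io_error")
  }
  cp <- file.path(dir, "timeline.csv")
  write.csv(as_tibble(timeline)[, c("frame_index", "glottis_pixels",
                                    "vocal_cord_pixels", "aspiration_pixels")],
            cp, row.names = FALSE)
  events <- dplyr::arrange(as_tibble(events), .data$start_frame)
  jp <- file.path(dir, "events.json")
  jsonlite::write_json(events, jp, digits = NA)
  pp <- file.path(dir, "timeline.png")
  p <- autoplot.fees_timeline(timeline, events = events)
  grDevices::png(pp, width = 1200, height = 800)
  print(p)
  grDevices::dev.off()
  invisible(c(cp, jp, pp))
}

#' Read back a timeline CSV
#'
#' @param path `timeline.csv` written by [export_timeline()].
#' @return A `fees_timeline` tibble.
#' @export
read_timeline <- function(path) {
  out <- as_tibble(read.csv(path))
  class(out) <- c("fees_timeline", class(out))
  out
}

#' @export
autoplot.fees_timeline <- function(object, events = NULL, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    dplyr::all_of(c("glottis_pixels", "vocal_cord_pixels", "aspiration_pixels")),
    names_to = "class", values_to = "pixels")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$frame_index,
                                          y = .data$pixels,
                                          colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(aspiration_pixels = "magenta",
                                            glottis_pixels = "goldenrod",
                                            vocal_cord_pixels = "darkcyan")) +
    ggplot2::labs(x = "frame", y = "segmented pixels",
                  title = "Pixel-count timeline") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(events),
      ggplot2::aes(xmin = .data$start_frame, xmax = .data$end_frame),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "magenta",
      inherit.aes = FALSE)
    # zoom panel around the highest-peak event
    top <- events[which.max(events$peak_pixels), ]
    span <- max(5L, top$end_frame - top$start_frame)
    zoom <- p + ggplot2::coord_cartesian(
      xlim = c(top$start_frame - span, top$end_frame + span)) +
      ggplot2::labs(title = "Timeline zoom (highest-peak event)")
    if (requireNamespace("patchwork", quietly = TRUE)) {
      p <- patchwork::wrap_plots(p, zoom, ncol = 1)
    }
  }
  p
}
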