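# Frame preprocessing, online augmentation and the stratified patch sampler.

#' Downscale a frame by a factor of two
#'
#' Interlaced-origin recordings carry comb artifacts; 2 x 2 block averaging at
#' half resolution removes them. Odd dimensions are first padded by edge
#' replication so the operation is total.
#'
#' @param frame A [fees_frame()].
#' @return A [fees_frame()] of size `ceiling(H/2) x ceiling(W/2)`.
#' @export
downscale_frame <- function(frame) {
  stopifnot(inherits(frame, "fees_frame"))
  px <- frame$pixels
  d <- dim(px)
  if (d[1] %% 2L == 1L) px <- px[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (d[2] %% 2L == 1L) px <- px[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  d <- dim(px)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  out <- (px[oi, oj, , drop = FALSE] + px[oi + 1L, oj, , drop = FALSE] +
          px[oi, oj + 1L, , drop = FALSE] + px[oi + 1L, oj + 1L, , drop = FALSE]) / 4
  fees_frame(out, frame$video_id, frame$frame_index)
}

# 2x2 max-pool for one binary mask (any annotated pixel survives).
downscale_mask <- function(mask) {
  d <- dim(mask)
  if (d[1] %% 2L == 1L) mask <- mask[c(seq_len(d[1]), d[1]), , drop = FALSE]
  if (d[2] %% 2L == 1L) mask <- mask[, c(seq_len(d[2]), d[2]), drop = FALSE]
  d <- dim(mask)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  mask[oi, oj, drop = FALSE] | mask[oi + 1L, oj, drop = FALSE] |
    mask[oi, oj + 1L, drop = FALSE] | mask[oi + 1L, oj + 1L, drop = FALSE]
}

#' Downscale a reference annotation by a factor of two
#'
#' Masks are 2 x 2 max-pooled so any annotated pixel survives; frame-level
#' labels are carried over unchanged.
#'
#' @param ann A [fees_annotation()].
#' @return A half-resolution [fees_annotation()].
#' @export
downscale_annotation <- function(ann) {
  stopifnot(inherits(ann, "fees_annotation"))
  fees_annotation(downscale_mask(ann$glottis_roi), downscale_mask(ann$vocal_cords),
                  downscale_mask(ann$aspiration), ann$glottis_visible,
                  ann$glottis_state, ann$bolus_type)
}

#' Stratified patch sampler configuration
#'
#' The sampler draws three strata: ROI patches with aspiration
#' (`p_roi * p_aspiration_given_roi`), ROI patches without aspiration
#' (`p_roi * (1 - p_aspiration_given_roi)`), and negative patches from frames
#' labeled as not containing the glottis (`1 - p_roi`). Defaults follow the
#' 80 percent ROI / 25 percent-of-those-with-aspiration design.
#'
#' @param p_roi Probability that a sampled patch contains the glottis ROI.
#' @param p_aspiration_given_roi Probability that an ROI patch shows aspiration.
#' @param batch_size Patches per training batch.
#' @param patch_size Integer `(H, W)` of the sampled patch.
#' @param seed Optional sampler seed.
#' @return A `fees_sampler_config` list.
#' @export
sampler_config <- function(p_roi = 0.8, p_aspiration_given_roi = 0.25,
                           batch_size = 16L, patch_size = c(288L, 352L),
                           seed = NULL) {
  if (p_roi < 0 || p_roi > 1 || p_aspiration_given_roi < 0 || p_aspiration_given_roi > 1) {
    abort("Sampler fractions must lie in [0, 1].", class = "feesxai_config_error")
  }
  if (batch_size < 1L) abort("`batch_size` must be >= 1.", class = "feesxai_config_error")
  structure(list(p_roi = p_roi, p_aspiration_given_roi = p_aspiration_given_roi,
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), seed = seed),
            class = "fees_sampler_config")
}

patch_strata <- c("roi_with_aspiration", "roi_without_aspiration", "negative")

# Stratum of an annotated frame.
frame_stratum <- function(ann) {
  if (!ann$glottis_visible) return("negative")
  if (any(ann$aspiration)) "roi_with_aspiration" else "roi_without_aspiration"
}

reflect_pad_to <- function(m, h, w) {
  ri <- seq_len(h); rj <- seq_len(w)
  fold <- function(idx, n) {
    # reflect indices 1..n outward: 1,2,...,n,n-1,...
    if (n == 1L) return(rep(1L, length(idx)))
    p <- (idx - 1L) %% (2L * (n - 1L))
    ifelse(p < n, p + 1L, 2L * n - 1L - p)
  }
  i <- fold(ri, nrow(m)); j <- fold(rj, ncol(m))
  m[i, j, drop = FALSE]
}

# Crop (or reflect-pad) a patch of size (ph, pw) with top-left (ti, tj),
# 1-based, from image array / mask.
crop_patch <- function(x, ti, tj, ph, pw) {
  if (is.matrix(x)) {
    m <- if (nrow(x) < ph || ncol(x) < pw) reflect_pad_to(x, max(ph, nrow(x)), max(pw, ncol(x))) else x
    m[ti:(ti + ph - 1L), tj:(tj + pw - 1L), drop = FALSE]
  } else {
    out <- array(0, c(ph, pw, dim(x)[3]))
    for (ch in seq_len(dim(x)[3])) {
      out[, , ch] <- crop_patch(x[, , ch], ti, tj, ph, pw)
    }
    out
  }
}

#' Draw one stratified training patch
#'
#' Draws a stratum with probabilities implied by the sampler configuration,
#' picks a frame of that stratum uniformly, and positions the patch to contain
#' the glottis ROI (ROI strata: centred on a uniformly chosen ROI pixel, then
#' clamped to the image bounds) or uniformly (negative stratum). Frames are
#' used at half resolution (see [downscale_frame()]) with intensities scaled
#' to `[0, 1]`; frames smaller than the patch are reflect-padded.
#'
#' @param dataset A `fees_dataset` (or list with `frames`, `annotations`).
#' @param config A [sampler_config()].
#' @param frame_ids Optional integer subset of frame positions (1-based) to
#'   sample from, e.g. the training split.
#' @param downscale Whether frames/masks are first halved in resolution.
#' @return A `fees_patch`: list with `image` (H x W x 3 in `[0, 1]`),
#'   `target` (H x W x 3 binary array, channels glottis/cords/aspiration) and
#'   `stratum`.
#' @export
sample_patch <- function(dataset, config = sampler_config(), frame_ids = NULL,
                         downscale = TRUE) {
  frame_ids <- frame_ids %||% seq_along(dataset$frames)
  strata <- vapply(dataset$annotations[frame_ids], frame_stratum, character(1))
  probs <- c(config$p_roi * config$p_aspiration_given_roi,
             config$p_roi * (1 - config$p_aspiration_given_roi),
             1 - config$p_roi)
  available <- patch_strata[probs > 0]
  missing <- setdiff(available, unique(strata))
  if (length(missing) > 0) {
    abort(sprintf("No frames available for stratum `%s`.", missing[1]),
          class = "feesxai_sampler_error")
  }
  stratum <- sample(patch_strata, 1L, prob = probs)
  pick <- sample(rep(which(strata == stratum), 2L), 1L) # rep: guard length-1 x
  fi <- frame_ids[pick]
  frame <- dataset$frames[[fi]]
  ann <- dataset$annotations[[fi]]
  if (downscale) {
    frame <- downscale_frame(frame)
    ann <- downscale_annotation(ann)
  }
  ph <- config$patch_size[1]; pw <- config$patch_size[2]
  h <- max(nrow(ann$glottis_roi), ph); w <- max(ncol(ann$glottis_roi), pw)
  if (stratum == "negative") {
    ti <- sample.int(h - ph + 1L, 1L); tj <- sample.int(w - pw + 1L, 1L)
  } else {
    roi <- which(ann$glottis_roi, arr.ind = TRUE)
    p <- roi[sample.int(nrow(roi), 1L), ]
    ti <- clamp(p[1] - ph %/% 2L, 1L, h - ph + 1L)
    tj <- clamp(p[2] - pw %/% 2L, 1L, w - pw + 1L)
  }
  img <- crop_patch(frame$pixels, ti, tj, ph, pw) / 255
  target <- array(0, c(ph, pw, 3L))
  for (k in seq_along(frame_classes)) {
    target[, , k] <- crop_patch(ann[[frame_classes[k]]], ti, tj, ph, pw)
  }
  structure(list(image = img, target = target, stratum = stratum),
            class = "fees_patch")
}

#' Randomly augment a training patch
#'
#' Applies one geometric transform (rotation, zoom in up to 1.5x, optional
#' left-right mirror) identically to the image and all target masks (bilinear
#' for the image, nearest neighbour for masks), then photometric jitter on the
#' image only: a contrast factor and a brightness shift bounded by the given
#' fraction of the patch mean. Any parameter may be fixed explicitly; `NULL`
#' draws it from its configured range.
#'
#' @param patch A `fees_patch` from [sample_patch()].
#' @param angle Rotation angle in degrees (`NULL`: uniform in
#'   `angle_range`).
#' @param zoom Zoom-in factor (`NULL`: uniform in `[1, zoom_max]`).
#' @param mirror Mirror left-right (`NULL`: fair coin).
#' @param contrast Contrast factor (`NULL`: uniform in `contrast_range`).
#' @param brightness Brightness shift as a fraction of the patch mean
#'   (`NULL`: uniform in `+/- brightness_max`).
#' @param angle_range,zoom_max,contrast_range,brightness_max Draw ranges.
#' @return The augmented `fees_patch`.
#' @export
augment_patch <- function(patch, angle = NULL, zoom = NULL, mirror = NULL,
                          contrast = NULL, brightness = NULL,
                          angle_range = c(-30, 30), zoom_max = 1.5,
                          contrast_range = c(0.75, 1.25), brightness_max = 0.25) {
  stopifnot(inherits(patch, "fees_patch"))
  angle <- angle %||% runif(1, angle_range[1], angle_range[2])
  zoom <- zoom %||% runif(1, 1, zoom_max)
  mirror <- mirror %||% (runif(1) < 0.5)
  contrast <- contrast %||% runif(1, contrast_range[1], contrast_range[2])
  brightness <- brightness %||% runif(1, -brightness_max, brightness_max)
  if (zoom < 1) zoom <- 1

  h <- dim(patch$image)[1]; w <- dim(patch$image)[2]
  identity_geom <- angle == 0 && zoom == 1 && !mirror
  if (!identity_geom) {
    # inverse mapping: output pixel -> source coordinate
    th <- angle * pi / 180
    ci <- (h + 1) / 2; cj <- (w + 1) / 2
    oi <- matrix(seq_len(h) - ci, h, w)
    oj <- matrix(seq_len(w) - cj, h, w, byrow = TRUE)
    if (mirror) oj <- -oj
    si <- ( cos(th) * oi + sin(th) * oj) / zoom + ci
    sj <- (-sin(th) * oi + cos(th) * oj) / zoom + cj

    bilinear <- function(m) {
      i0 <- clamp(floor(si), 1, h); j0 <- clamp(floor(sj), 1, w)
      i1 <- clamp(i0 + 1, 1, h); j1 <- clamp(j0 + 1, 1, w)
      fi <- clamp(si, 1, h) - i0; fj <- clamp(sj, 1, w) - j0
      g <- function(ii, jj) m[cbind(as.vector(ii), as.vector(jj))]
      v <- g(i0, j0) * (1 - fi) * (1 - fj) + g(i1, j0) * fi * (1 - fj) +
        g(i0, j1) * (1 - fi) * fj + g(i1, j1) * fi * fj
      matrix(v, h, w)
    }
    nearest <- function(m) {
      i <- clamp(round(si), 1, h); j <- clamp(round(sj), 1, w)
      inside <- si >= 0.5 & si <= h + 0.5 & sj >= 0.5 & sj <= w + 0.5
      v <- m[cbind(as.vector(i), as.vector(j))] & as.vector(inside)
      matrix(v, h, w)
    }
    outside <- si < 1 | si > h | sj < 1 | sj > w
    for (ch in 1:3) {
      m <- bilinear(patch$image[, , ch])
      m[outside] <- 0
      patch$image[, , ch] <- m
      patch$target[, , ch] <- nearest(patch$target[, , ch] > 0.5)
    }
  }
  if (contrast != 1 || brightness != 0) {
    mu <- mean(patch$image)
    patch$image <- clamp((patch$image - mu) * contrast + mu + brightness * mu, 0, 1)
  }
  patch
}
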