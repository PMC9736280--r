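# Synthetic endoscopy-like scene generator.
#
# Emulates the variability of swallowing-endoscopy footage needed to exercise
# the pipeline end to end: an elliptical glottis whose minor axis opens and
# closes, flanking bright vocal-cord bands, intermittent frames without a
# visible glottis, occasional bolus blobs of three appearance types rendered
# inside the glottis ROI, specular reflections, brightness/contrast/sharpness
# jitter, and partial visibility at the image edge. Every frame carries exact
# ground-truth masks and frame labels.

#' Scene configuration for the synthetic video generator
#'
#' @param image_size Integer `(H, W)` in pixels, both >= 64. The default
#'   matches full-resolution interlaced-origin endoscopy frames (576 x 704),
#'   which downscale by two to the network's 288 x 352 working resolution.
#' @param n_frames Number of frames to render.
#' @param glottis_size_range Range (pixels) of the glottis semi-major axis;
#'   `NULL` chooses 0.16-0.28 of the smaller image dimension.
#' @param open_close_period Period of the open/close oscillation, in frames.
#' @param visibility_prob Per-frame probability that the glottis is visible;
#'   frames inside a bolus event are always rendered visible so ground-truth
#'   aspiration runs stay temporally coherent.
#' @param partial_visibility_prob Per-frame probability that a visible glottis
#'   is shifted to clip the image edge (the hard partial-visibility case).
#' @param bolus_event_rate Expected aspiration events per 100 frames.
#' @param bolus_duration_range Event duration range in frames (inclusive).
#' @param bolus_size_range Range (pixels) of the bolus blob radius; `NULL`
#'   chooses 0.05-0.12 of the smaller image dimension.
#' @param bolus_type Bolus appearance: `"slurry"` (textured mid-intensity),
#'   `"saliva"` (small bright), or `"liquid"` (low-contrast translucent).
#' @param reflection_rate Per-frame probability of a specular highlight.
#' @param brightness_jitter Fractional per-frame brightness jitter (0.25 means
#'   the frame mean moves by at most +/- 25 percent).
#' @param blur_sigma_range Range of the per-frame Gaussian blur sigma (pixels).
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   configuration including this seed.
#' @return A validated `fees_scene_config` list.
#' @export
scene_config <- function(image_size = c(576L, 704L),
                         n_frames = 300L,
                         glottis_size_range = NULL,
                         open_close_period = 40L,
                         visibility_prob = 0.85,
                         partial_visibility_prob = 0.1,
                         bolus_event_rate = 2,
                         bolus_duration_range = c(4L, 12L),
                         bolus_size_range = NULL,
                         bolus_type = "slurry",
                         reflection_rate = 0.1,
                         brightness_jitter = 0.15,
                         blur_sigma_range = c(0, 1.5),
                         seed = 1L) {
  bad <- function(field, msg) {
    abort(sprintf("Invalid scene configuration: `%s` %s.", field, msg),
          class = "feesxai_config_error")
  }
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(is.na(image_size)) || any(image_size < 64L))
    bad("image_size", "must be two integers >= 64")
  if (!is.numeric(n_frames) || n_frames < 1L) bad("n_frames", "must be >= 1")
  mindim <- min(image_size)
  if (is.null(glottis_size_range)) {
    glottis_size_range <- c(0.16, 0.28) * mindim
  }
  if (length(glottis_size_range) != 2L || any(glottis_size_range < 0) ||
      diff(glottis_size_range) < 0)
    bad("glottis_size_range", "must be a non-negative increasing range")
  if (!is.numeric(open_close_period) || open_close_period < 2)
    bad("open_close_period", "must be >= 2 frames")
  for (pf in c("visibility_prob", "partial_visibility_prob", "reflection_rate")) {
    v <- get(pf)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      bad(pf, "must be a probability in [0, 1]")
  }
  if (!is.numeric(bolus_event_rate) || bolus_event_rate < 0)
    bad("bolus_event_rate", "must be non-negative")
  bolus_duration_range <- as.integer(bolus_duration_range)
  if (length(bolus_duration_range) != 2L || any(bolus_duration_range < 1L) ||
      diff(bolus_duration_range) < 0L)
    bad("bolus_duration_range", "must be an increasing range of frames >= 1")
  if (is.null(bolus_size_range)) bolus_size_range <- c(0.05, 0.12) * mindim
  if (length(bolus_size_range) != 2L || any(bolus_size_range < 0) ||
      diff(bolus_size_range) < 0)
    bad("bolus_size_range", "must be a non-negative increasing range")
  bolus_type <- match.arg(bolus_type, c("slurry", "saliva", "liquid"))
  if (!is.numeric(brightness_jitter) || brightness_jitter < 0 || brightness_jitter > 1)
    bad("brightness_jitter", "must be in [0, 1]")
  if (length(blur_sigma_range) != 2L || any(blur_sigma_range < 0) ||
      diff(blur_sigma_range) < 0)
    bad("blur_sigma_range", "must be a non-negative increasing range")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    bad("seed", "must be a single finite number")
  structure(
    list(image_size = image_size, n_frames = as.integer(n_frames),
         glottis_size_range = glottis_size_range,
         open_close_period = open_close_period,
         visibility_prob = visibility_prob,
         partial_visibility_prob = partial_visibility_prob,
         bolus_event_rate = bolus_event_rate,
         bolus_duration_range = bolus_duration_range,
         bolus_size_range = bolus_size_range, bolus_type = bolus_type,
         reflection_rate = reflection_rate,
         brightness_jitter = brightness_jitter,
         blur_sigma_range = blur_sigma_range, seed = seed),
    class = "fees_scene_config")
}

#' Schedule aspiration events for a scene
#'
#' The event-placement step of the generator, exposed so a schedule can be
#' reproduced independently of rendering: a Poisson number of events (rate per
#' 100 frames) with uniformly drawn start frames and durations, overlapping or
#' adjacent events merged. Deterministic given the configuration seed.
#'
#' @param config A [scene_config()].
#' @return Tibble with 0-based inclusive `start_frame`, `end_frame`.
#' @export
schedule_bolus_events <- function(config) {
  stopifnot(inherits(config, "fees_scene_config"))
  with_seed(child_seed(config$seed, 2L), {
    n <- config$n_frames
    n_events <- rpois(1L, config$bolus_event_rate * n / 100)
    if (n_events == 0L) {
      return(tibble(start_frame = integer(0), end_frame = integer(0)))
    }
    starts <- sample.int(n, n_events, replace = TRUE) - 1L
    durs <- sample(seq(config$bolus_duration_range[1],
                       config$bolus_duration_range[2]), n_events, replace = TRUE)
    ev <- tibble(start_frame = starts,
                 end_frame = pmin(starts + durs - 1L, n - 1L)) |>
      dplyr::arrange(.data$start_frame)
    # merge overlapping or adjacent intervals
    merged <- ev[1, ]
    if (nrow(ev) > 1L) {
      for (i in 2:nrow(ev)) {
        last <- nrow(merged)
        if (ev$start_frame[i] <= merged$end_frame[last] + 1L) {
          merged$end_frame[last] <- max(merged$end_frame[last], ev$end_frame[i])
        } else {
          merged <- dplyr::bind_rows(merged, ev[i, ])
        }
      }
    }
    merged
  })
}

# Per-type bolus appearance: colour, opacity, radius scale, speckle amplitude.
bolus_appearance <- function(type) {
  switch(type,
    slurry = list(col = c(175, 158, 120), alpha = 1.0, rscale = 1.0, speckle = 35),
    saliva = list(col = c(228, 226, 214), alpha = 1.0, rscale = 0.6, speckle = 8),
    liquid = list(col = c(120, 108, 96), alpha = 0.35, rscale = 1.0, speckle = 0))
}

#' Generate a synthetic endoscopy video with exact ground truth
#'
#' Renders `config$n_frames` frames of a schematic laryngeal scene and the
#' matching per-frame reference annotations, plus a log of the true aspiration
#' intervals. Bolus blobs are only drawn inside the glottis ROI, frames where
#' the glottis is not visible contain none of the three structures, and the
#' whole dataset is a pure function of the configuration (including its seed).
#'
#' @param config A [scene_config()].
#' @param video_id Identifier stored on every frame.
#' @return A `fees_dataset`: list with `frames` (list of [fees_frame()]),
#'   `annotations` (list of [fees_annotation()]), `index` (tibble of per-frame
#'   labels and pixel counts), `events` (tibble with `start_frame`,
#'   `end_frame`, `sizes` — aspiration pixels per event frame) and `config`.
#' @export
generate_fees_video <- function(config, video_id = "synthetic") {
  stopifnot(inherits(config, "fees_scene_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  n <- config$n_frames

  layout <- with_seed(child_seed(config$seed, 1L), {
    list(ci = h * runif(1, 0.42, 0.58), cj = w * runif(1, 0.42, 0.58),
         theta = runif(1, -0.4, 0.4),
         a_major = runif(1, config$glottis_size_range[1], config$glottis_size_range[2]),
         phase0 = runif(1, 0, 2 * pi),
         shading = smooth_noise(h, w, scale = max(4L, round(min(h, w) / 12))))
  })
  events <- schedule_bolus_events(config)
  in_event <- rep(FALSE, n)
  event_id <- rep(NA_integer_, n)
  if (nrow(events) > 0) {
    for (e in seq_len(nrow(events))) {
      idx <- (events$start_frame[e]:events$end_frame[e]) + 1L
      in_event[idx] <- TRUE
      event_id[idx] <- e
    }
  }
  visible <- with_seed(child_seed(config$seed, 3L),
                       runif(n) < config$visibility_prob)
  visible[in_event] <- TRUE

  base <- array(0, c(h, w, 3))
  shade <- 0.75 + 0.45 * layout$shading
  # radial vignette typical of endoscope optics
  di <- matrix(seq_len(h) - h / 2, h, w); dj <- matrix(seq_len(w) - w / 2, h, w, byrow = TRUE)
  vig <- 1 - 0.5 * (sqrt(di^2 + dj^2) / (0.75 * sqrt((h / 2)^2 + (w / 2)^2)))^2
  tissue <- c(150, 95, 85)
  for (ch in 1:3) base[, , ch] <- tissue[ch] * shade * vig

  app <- bolus_appearance(config$bolus_type)
  frames <- vector("list", n)
  annotations <- vector("list", n)
  event_sizes <- vector("list", max(1L, nrow(events)))

  with_seed(child_seed(config$seed, 4L), {
    for (t in seq_len(n)) {
      px <- base
      empty <- matrix(FALSE, h, w)
      glottis <- empty; cords <- empty; aspiration <- empty
      state <- "unknown"; btype <- "none"

      if (visible[t]) {
        s <- 0.5 * (1 + sin(2 * pi * (t - 1) / config$open_close_period + layout$phase0))
        ai <- layout$a_major
        aj <- (0.55 * ai) * (0.08 + 0.92 * s)
        ci <- layout$ci; cj <- layout$cj
        if (runif(1) < config$partial_visibility_prob) {
          # clip the structure at a random image edge
          edge <- sample(4L, 1L)
          if (edge == 1L) ci <- 0.25 * ai
          if (edge == 2L) ci <- h - 0.25 * ai
          if (edge == 3L) cj <- 0.25 * ai
          if (edge == 4L) cj <- w - 0.25 * ai
        }
        band_hw <- pmax(2, 0.18 * ai)
        # the annotated glottis ROI is the whole laryngeal-inlet region: it
        # encloses the dark opening and the flanking cord bands, so the
        # ROI-restriction step of post-processing keeps the cords
        opening <- ellipse_mask(h, w, ci, cj, ai, aj, layout$theta)
        glottis <- ellipse_mask(h, w, ci, cj, 1.12 * ai + 2,
                                aj + 2 * band_hw + 2, layout$theta)
        off <- aj + band_hw + 1
        ov <- c(-sin(layout$theta), cos(layout$theta)) # unit vector, minor axis
        b1 <- ellipse_mask(h, w, ci + off * ov[1], cj + off * ov[2],
                           0.95 * ai, band_hw, layout$theta)
        b2 <- ellipse_mask(h, w, ci - off * ov[1], cj - off * ov[2],
                           0.95 * ai, band_hw, layout$theta)
        cords <- (b1 | b2) & glottis & !opening
        state <- if (s >= 0.35) "open" else "closed"
        cord_col <- c(208, 192, 188)
        glot_col <- c(38, 26, 30)
        for (ch in 1:3) {
          m <- px[, , ch]
          m[cords] <- cord_col[ch] * (0.85 + 0.3 * layout$shading[cords])
          m[opening] <- glot_col[ch] * (0.8 + 0.4 * layout$shading[opening])
          px[, , ch] <- m
        }

        if (in_event[t] && any(opening)) {
          e <- event_id[t]
          dur <- events$end_frame[e] - events$start_frame[e] + 1L
          prog <- (t - 1 - events$start_frame[e] + 0.5) / dur
          base_r <- runif(1, config$bolus_size_range[1], config$bolus_size_range[2])
          r <- max(1.5, app$rscale * base_r * sin(pi * prog))
          # bolus centre on the glottis major axis => always inside the ROI
          u <- runif(1, -0.45, 0.45) * ai
          uv <- c(cos(layout$theta), sin(layout$theta))
          blob <- disk_mask(h, w, ci + u * uv[1], cj + u * uv[2], r)
          aspiration <- blob & opening
          if (any(aspiration)) {
            btype <- config$bolus_type
            spk <- if (app$speckle > 0)
              matrix(runif(h * w, -app$speckle, app$speckle), h, w) else 0
            for (ch in 1:3) {
              m <- px[, , ch]
              tgt <- app$col[ch] + (if (is.matrix(spk)) spk[aspiration] else 0)
              m[aspiration] <- (1 - app$alpha) * m[aspiration] + app$alpha * tgt
              px[, , ch] <- m
            }
          }
        }
      }

      blur <- runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
      fr <- corrupt_frame(
        fees_frame(clamp(px, 0, 255), video_id = video_id, frame_index = t - 1L),
        reflection_rate = config$reflection_rate, blur_sigma = blur,
        brightness_jitter = config$brightness_jitter)
      frames[[t]] <- fr
      annotations[[t]] <- fees_annotation(
        glottis, cords, aspiration, glottis_visible = visible[t],
        glottis_state = state, bolus_type = btype)
      if (in_event[t]) {
        e <- event_id[t]
        event_sizes[[e]] <- c(event_sizes[[e]], sum(aspiration))
      }
    }
  })

  if (nrow(events) > 0) events$sizes <- event_sizes[seq_len(nrow(events))]
  else events$sizes <- list()

  index <- tibble(
    video_id = video_id,
    frame_index = seq_len(n) - 1L,
    glottis_visible = visible,
    glottis_state = vapply(annotations, function(a) a$glottis_state, character(1)),
    bolus_type = vapply(annotations, function(a) a$bolus_type, character(1)),
    glottis_pixels = vapply(annotations, function(a) sum(a$glottis_roi), numeric(1)),
    aspiration_pixels = vapply(annotations, function(a) sum(a$aspiration), numeric(1))
  )

  structure(list(frames = frames, annotations = annotations, index = index,
                 events = events, config = config),
            class = "fees_dataset")
}

#' @export
print.fees_dataset <- function(x, ...) {
  cat(sprintf("<fees_dataset> %d frames %dx%d, %d aspiration event(s)\n",
              length(x$frames), x$config$image_size[1], x$config$image_size[2],
              nrow(x$events)))
  invisible(x)
}

#' @export
tidy.fees_dataset <- function(x, ...) x$index

#' Apply acquisition-style corruption to a frame
#'
#' Adds the failure sources seen in real footage: specular light reflections
#' (compact saturated patches), Gaussian blur (sharpness loss) and a global
#' brightness scaling bounded by the jitter fraction of the frame mean.
#' With all three parameters zero the frame is returned unchanged.
#'
#' @param frame A [fees_frame()].
#' @param reflection_rate Probability that a specular highlight is added.
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param brightness_jitter Maximum fractional change of the frame mean;
#'   the applied factor is drawn uniformly from `1 +/- brightness_jitter`.
#' @param seed Optional seed for a reproducible corruption; `NULL` draws from
#'   the ambient RNG stream. Out-of-range parameters are clamped with a
#'   warning rather than raising an error.
#' @return A corrupted [fees_frame()] of identical shape and intensity range.
#' @export
corrupt_frame <- function(frame, reflection_rate = 0, blur_sigma = 0,
                          brightness_jitter = 0, seed = NULL) {
  stopifnot(inherits(frame, "fees_frame"))
  cl <- function(v, lo, hi, nm) {
    if (v < lo || v > hi) {
      warn(sprintf("`%s` clamped into [%s, %s].", nm, lo, hi))
      v <- clamp(v, lo, hi)
    }
    v
  }
  reflection_rate <- cl(reflection_rate, 0, 1, "reflection_rate")
  blur_sigma <- cl(blur_sigma, 0, Inf, "blur_sigma")
  brightness_jitter <- cl(brightness_jitter, 0, 1, "brightness_jitter")
  if (reflection_rate == 0 && blur_sigma == 0 && brightness_jitter == 0) {
    return(frame)
  }
  px <- frame$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  with_seed(seed, {
    if (blur_sigma > 0) {
      for (ch in 1:3) px[, , ch] <- gaussian_blur_mat(px[, , ch], blur_sigma)
    }
    if (brightness_jitter > 0) {
      f <- runif(1, 1 - brightness_jitter, 1 + brightness_jitter)
      px <- px * f
    }
    if (reflection_rate > 0 && runif(1) < reflection_rate) {
      k <- sample(1:2, 1L)
      for (i in seq_len(k)) {
        r <- runif(1, 2, max(3, 0.04 * min(h, w)))
        spot <- disk_mask(h, w, runif(1, 1, h), runif(1, 1, w), r)
        for (ch in 1:3) {
          m <- px[, , ch]; m[spot] <- 255; px[, , ch] <- m
        }
      }
    }
  })
  fees_frame(clamp(px, 0, 255), frame$video_id, frame$frame_index)
}
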