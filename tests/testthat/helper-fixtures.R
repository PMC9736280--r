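# Shared fixtures: tiny scenes, toy masks and independent oracles.

# A small synthetic scene; defaults keep unit tests fast.
tiny_scene <- function(seed = 11, n_frames = 40, bolus_event_rate = 6,
                       bolus_type = "slurry", reflection_rate = 0.08,
                       blur_sigma_range = c(0, 1), brightness_jitter = 0.15,
                       ...) {
  scene_config(image_size = c(96, 128), n_frames = n_frames,
               bolus_event_rate = bolus_event_rate, bolus_type = bolus_type,
               reflection_rate = reflection_rate,
               blur_sigma_range = blur_sigma_range,
               brightness_jitter = brightness_jitter, seed = seed, ...)
}

# Strata present in a generated dataset.
dataset_strata <- function(ds) {
  unique(vapply(ds$annotations, function(a) {
    if (!a$glottis_visible) "negative"
    else if (any(a$aspiration)) "roi_with_aspiration" else "roi_without_aspiration"
  }, character(1)))
}

# Concatenate several generated videos into one frames+annotations container.
pool_datasets <- function(vs) {
  structure(list(frames = do.call(c, lapply(vs, `[[`, "frames")),
                 annotations = do.call(c, lapply(vs, `[[`, "annotations"))),
            class = "fees_dataset")
}

rand_mask <- function(h = 8, w = 8, p = 0.4) {
  matrix(stats::runif(h * w) < p, h, w)
}

# Exhaustive pixel-count oracles for the overlap scores.
dice_oracle <- function(x, y) {
  inter <- sum(x & y); s <- sum(x) + sum(y)
  if (s == 0) 1 else 2 * inter / s
}

jaccard_oracle <- function(x, y) {
  un <- sum(x | y)
  if (un == 0) 1 else sum(x & y) / un
}

# Plain-R flood-fill labeling, the independent oracle for the compiled
# connected-component kernel.
flood_fill_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

largest_component_oracle <- function(mask, connectivity = 8) {
  if (!any(mask)) return(mask)
  lab <- flood_fill_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  lab == which(sizes == max(sizes))[1]
}

as_probmaps_for_test <- function(maps) {
  asNamespace("feesxai")$as_probmaps(maps)
}

# Constant-map stub model useful for pipeline tests without training.
constant_model <- function(glottis = 0, cords = 0, aspiration = 0) {
  function(frame) {
    px <- if (inherits(frame, "fees_frame")) frame$pixels else frame
    h <- dim(px)[1]; w <- dim(px)[2]
    maps <- array(0, c(h, w, 3))
    maps[, , 1] <- glottis; maps[, , 2] <- cords; maps[, , 3] <- aspiration
    maps
  }
}
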