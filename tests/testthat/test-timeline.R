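test_that("timelines carry one record per frame with conserved counts", {
  ds <- generate_fees_video(tiny_scene(seed = 60, n_frames = 15))
  model <- constant_model(glottis = 0.9, cords = 0, aspiration = 0)
  tl <- compute_timeline(ds, model, keep_segmentations = TRUE)
  expect_equal(nrow(tl), 15)
  expect_equal(tl$frame_index, 0:14)
  segs <- attr(tl, "segmentations")
  for (i in seq_len(nrow(tl))) {
    expect_equal(tl$glottis_pixels[i], sum(segs[[i]]$glottis_roi))
    expect_equal(tl$vocal_cord_pixels[i], sum(segs[[i]]$vocal_cords))
    expect_equal(tl$aspiration_pixels[i], sum(segs[[i]]$aspiration))
  }
  # an all-zero model yields an all-zero timeline
  tl0 <- compute_timeline(ds, constant_model())
  expect_true(all(tl0$glottis_pixels == 0))
  expect_true(all(tl0$aspiration_pixels == 0))
})

test_that("run detection reproduces hand-traced examples", {
  tl <- tibble::tibble(frame_index = 0:7,
                       aspiration_pixels = c(0, 0, 5, 6, 7, 0, 4, 0),
                       glottis_pixels = 0, vocal_cord_pixels = 0)
  runs <- detect_event_runs(tl, min_consecutive = 2, min_pixels = 1)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start_frame, 2)
  expect_equal(runs$end_frame, 4)
  expect_equal(runs$peak_frame, 4)
  expect_equal(runs$peak_pixels, 7)
  expect_equal(runs$total_pixels, 18)
  # min_consecutive = 1 counts every maximal nonzero block
  runs1 <- detect_event_runs(tl, min_consecutive = 1, min_pixels = 1)
  blocks <- with(rle(tl$aspiration_pixels >= 1), sum(values))
  expect_equal(nrow(runs1), blocks)
  # all-zero counts produce an empty result
  tl0 <- tibble::tibble(frame_index = 0:5, aspiration_pixels = 0,
                        glottis_pixels = 0, vocal_cord_pixels = 0)
  expect_equal(nrow(detect_event_runs(tl0)), 0)
  expect_error(detect_event_runs(tl, min_consecutive = 0),
               class = "feesxai_config_error")
})

test_that("peak frame is the earliest argmax and runs are maximal", {
  tl <- tibble::tibble(frame_index = 0:9,
                       aspiration_pixels = c(0, 3, 9, 9, 2, 0, 0, 5, 5, 5),
                       glottis_pixels = 0, vocal_cord_pixels = 0)
  runs <- detect_event_runs(tl, min_consecutive = 3, min_pixels = 1)
  expect_equal(runs$peak_frame, c(2, 7))   # earliest argmax in each run
  # maximality: no two runs touch, and extending any run breaks min_pixels
  for (i in seq_len(nrow(runs))) {
    s <- runs$start_frame[i]; e <- runs$end_frame[i]
    if (s > 0) expect_lt(tl$aspiration_pixels[tl$frame_index == s - 1], 1)
    if (e < 9) expect_lt(tl$aspiration_pixels[tl$frame_index == e + 1], 1)
  }
  expect_true(all(diff(runs$start_frame) > 0))
})

test_that("run maximality holds on random count sequences", {
  set.seed(61)
  for (rep in 1:50) {
    counts <- rpois(40, 0.8)
    tl <- tibble::tibble(frame_index = 0:39, aspiration_pixels = counts,
                         glottis_pixels = 0, vocal_cord_pixels = 0)
    mc <- sample(1:4, 1); mp <- sample(1:3, 1)
    runs <- detect_event_runs(tl, min_consecutive = mc, min_pixels = mp)
    if (nrow(runs) == 0) next
    for (i in seq_len(nrow(runs))) {
      s <- runs$start_frame[i]; e <- runs$end_frame[i]
      expect_gte(e - s + 1, mc)
      expect_true(all(counts[(s + 1):(e + 1)] >= mp))
      if (s > 0) expect_lt(counts[s], mp)
      if (e < 39) expect_lt(counts[e + 2], mp)
    }
    # no overlap or adjacency between consecutive runs
    if (nrow(runs) > 1) {
      expect_true(all(runs$start_frame[-1] > runs$end_frame[-nrow(runs)] + 1))
    }
  }
})

test_that("overlay rendering only touches contour bands", {
  ds <- generate_fees_video(tiny_scene(seed = 62, n_frames = 3,
                                       reflection_rate = 0,
                                       blur_sigma_range = c(0, 0),
                                       brightness_jitter = 0))
  h <- 48; w <- 64
  blob <- matrix(FALSE, h, w); blob[20:24, 30:31] <- TRUE
  empty <- matrix(FALSE, h, w)
  segs <- list(
    fees_segmentation(empty, empty, empty),
    fees_segmentation(blob, empty, empty),
    fees_segmentation(empty, empty, empty))
  dir <- withr::local_tempdir()
  render_overlay_video(ds, segs, file.path(dir, "ov"))
  out <- read_video(file.path(dir, "ov"))
  expect_length(out, 3)
  # frames with empty masks are unchanged (up to PNG 8-bit rounding)
  for (i in c(1, 3)) {
    expect_lt(max(abs(out[[i]]$pixels -
                        round(downscale_frame(ds$frames[[i]])$pixels))), 1.01)
  }
  # the marked frame differs only within the blob's dilated neighbourhood
  diffmask <- apply(abs(out[[2]]$pixels -
                          round(downscale_frame(ds$frames[[2]])$pixels)), c(1, 2), max) > 1
  near <- matrix(FALSE, h, w); near[18:26, 28:33] <- TRUE
  expect_true(all(!diffmask | near))
  expect_error(render_overlay_video(ds, segs[1:2], file.path(dir, "bad")),
               class = "feesxai_validation_error")
})

test_that("timeline export round trips and orders events", {
  tl <- tibble::tibble(frame_index = 0:9,
                       glottis_pixels = rpois(10, 50),
                       vocal_cord_pixels = rpois(10, 20),
                       aspiration_pixels = c(0, 0, 4, 5, 6, 0, 0, 7, 8, 9))
  class(tl) <- c("fees_timeline", class(tl))
  runs <- detect_event_runs(tl, min_consecutive = 3, min_pixels = 1)
  dir <- withr::local_tempdir()
  export_timeline(tl, runs, dir)
  back <- read_timeline(file.path(dir, "timeline.csv"))
  expect_equal(as.data.frame(back), as.data.frame(tl))
  ev <- jsonlite::read_json(file.path(dir, "events.json"), simplifyVector = TRUE)
  expect_equal(ev$start_frame, sort(ev$start_frame))
  expect_equal(nrow(ev), nrow(runs))
  expect_true(file.exists(file.path(dir, "timeline.png")))
  # empty event list still exports a plot
  export_timeline(tl, runs[0, ], file.path(dir, "empty"))
  expect_true(file.exists(file.path(dir, "empty", "timeline.png")))
})
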