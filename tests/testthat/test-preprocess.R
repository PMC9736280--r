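test_that("downscaling halves frames by block averaging", {
  px <- array(0, c(6, 4, 3))
  px[, , 1] <- matrix(1:24, 6, 4)
  fr <- fees_frame(px, "v", 0)
  out <- downscale_frame(fr)
  expect_identical(dim(out$pixels), c(3L, 2L, 3L))
  expect_equal(out$pixels[1, 1, 1], mean(px[1:2, 1:2, 1]))
  expect_equal(out$pixels[3, 2, 1], mean(px[5:6, 3:4, 1]))
  # constant frames stay constant, odd sizes pad by edge replication
  con <- downscale_frame(fees_frame(array(7, c(5, 5, 3))))
  expect_true(all(con$pixels == 7))
  expect_identical(dim(con$pixels)[1:2], c(3L, 3L))
  # a 704 x 576 recording reaches the working patch resolution
  big <- downscale_frame(fees_frame(array(0, c(576, 704, 3))))
  expect_identical(dim(big$pixels)[1:2], c(288L, 352L))
})

test_that("mask downscaling max-pools: any annotated pixel survives", {
  m <- matrix(FALSE, 4, 4)
  m[3, 2] <- TRUE # single annotated pixel
  ann <- fees_annotation(m)
  out <- downscale_annotation(ann)
  # oracle: 2x2 max-pool of the 4x4 mask
  oracle <- matrix(FALSE, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    oracle[i, j] <- any(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(out$glottis_roi, oracle)
  expect_equal(sum(out$glottis_roi), 1)
})

test_that("identity augmentation parameters return the patch unchanged", {
  ds <- generate_fees_video(tiny_scene(seed = 10, n_frames = 6,
                                       bolus_event_rate = 0))
  set.seed(1)
  p <- sample_patch(ds, sampler_config(patch_size = c(48, 64), p_roi = 1,
                                       p_aspiration_given_roi = 0))
  out <- augment_patch(p, angle = 0, zoom = 1, mirror = FALSE, contrast = 1,
                       brightness = 0)
  expect_equal(out$image, p$image)
  expect_equal(out$target, p$target)
})

test_that("mirroring twice restores the patch", {
  ds <- generate_fees_video(tiny_scene(seed = 10, n_frames = 6,
                                       bolus_event_rate = 0))
  set.seed(2)
  p <- sample_patch(ds, sampler_config(patch_size = c(48, 64), p_roi = 1,
                                       p_aspiration_given_roi = 0))
  once <- augment_patch(p, angle = 0, zoom = 1, mirror = TRUE, contrast = 1,
                        brightness = 0)
  twice <- augment_patch(once, angle = 0, zoom = 1, mirror = TRUE, contrast = 1,
                         brightness = 0)
  expect_equal(twice$image, p$image, tolerance = 1e-12)
  expect_equal(twice$target, p$target)
})

test_that("rotation moves a one-pixel mask by the closed-form rotation", {
  h <- 41; w <- 41
  img <- array(0.5, c(h, w, 3))
  tgt <- array(0, c(h, w, 3))
  src <- c(12, 30)
  tgt[src[1], src[2], 1] <- 1
  patch <- structure(list(image = img, target = tgt, stratum = "roi_without_aspiration"),
                     class = "fees_patch")
  for (angle in c(15, -25, 40)) {
    out <- augment_patch(patch, angle = angle, zoom = 1, mirror = FALSE,
                         contrast = 1, brightness = 0)
    pos <- which(out$target[, , 1] > 0, arr.ind = TRUE)
    expect_gte(nrow(pos), 1)
    # forward map is the inverse of the implementation's source mapping
    th <- angle * pi / 180
    c0 <- c((h + 1) / 2, (w + 1) / 2)
    dvec <- src - c0
    # output offset o solves R(th) %*% o = dvec
    o <- solve(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2), dvec)
    expected <- c0 + o
    d <- sqrt(rowSums((pos - matrix(expected, nrow(pos), 2, byrow = TRUE))^2))
    expect_lte(min(d), 1)
  }
})

test_that("geometric transforms treat image and masks identically", {
  # transform a coordinate-grid image alongside a mask built from it
  h <- 40; w <- 40
  grid <- matrix(0, h, w); grid[seq(4, 36, by = 8), ] <- 1
  img <- array(rep(grid, 3), c(h, w, 3))
  tgt <- array(rep(grid, 3), c(h, w, 3))
  patch <- structure(list(image = img, target = tgt, stratum = "roi_without_aspiration"),
                     class = "fees_patch")
  out <- augment_patch(patch, angle = 20, zoom = 1.3, mirror = TRUE,
                       contrast = 1, brightness = 0)
  # wherever the transformed image is clearly foreground/background, the
  # nearest-neighbour mask must agree
  im <- out$image[, , 1]
  mk <- out$target[, , 1]
  expect_true(all(mk[im > 0.99] == 1))
  expect_true(all(mk[im < 0.01] == 0))
})

test_that("brightness shift is bounded by the stated fraction of the mean", {
  img <- array(runif(32 * 32 * 3, 0.2, 0.6), c(32, 32, 3))
  patch <- structure(list(image = img, target = img * 0, stratum = "negative"),
                     class = "fees_patch")
  set.seed(3)
  for (i in 1:20) {
    out <- augment_patch(patch, angle = 0, zoom = 1, mirror = FALSE)
    # contrast preserves the mean, so only the brightness term moves it
    expect_lte(abs(mean(out$image) - mean(img)), 0.2501 * mean(img))
  }
})

test_that("sampler strata obey their mask contracts", {
  ds <- generate_fees_video(tiny_scene(seed = 12, n_frames = 60,
                                       bolus_event_rate = 8))
  # force all three strata to exist
  strata <- vapply(ds$annotations, function(a) {
    if (!a$glottis_visible) "negative"
    else if (any(a$aspiration)) "roi_with_aspiration" else "roi_without_aspiration"
  }, character(1))
  expect_setequal(unique(strata),
                  c("negative", "roi_with_aspiration", "roi_without_aspiration"))
  cfg <- sampler_config(patch_size = c(48, 64))
  set.seed(4)
  for (i in 1:30) {
    p <- sample_patch(ds, cfg)
    if (p$stratum == "negative") {
      expect_equal(sum(p$target), 0)
    } else {
      expect_gt(sum(p$target[, , 1]), 0)
      if (p$stratum == "roi_with_aspiration") expect_gt(sum(p$target[, , 3]), 0)
      else expect_equal(sum(p$target[, , 3]), 0)
    }
  }
  # p_roi = 1, no aspiration: always glottis, never aspiration
  cfg2 <- sampler_config(p_roi = 1, p_aspiration_given_roi = 0,
                         patch_size = c(48, 64))
  set.seed(5)
  for (i in 1:10) {
    p <- sample_patch(ds, cfg2)
    expect_gt(sum(p$target[, , 1]), 0)
    expect_equal(sum(p$target[, , 3]), 0)
  }
})

test_that("sampling from an unavailable stratum names it", {
  ds <- generate_fees_video(tiny_scene(seed = 13, n_frames = 8,
                                       bolus_event_rate = 0))
  keep <- which(vapply(ds$annotations, function(a) a$glottis_visible, logical(1)))
  expect_error(
    sample_patch(ds, sampler_config(patch_size = c(48, 64)), frame_ids = keep),
    "roi_with_aspiration", class = "feesxai_sampler_error")
})

test_that("frames smaller than the patch are reflect-padded to size", {
  ds <- generate_fees_video(tiny_scene(seed = 14, n_frames = 4,
                                       bolus_event_rate = 0))
  set.seed(6)
  p <- sample_patch(ds, sampler_config(patch_size = c(96, 96), p_roi = 1,
                                       p_aspiration_given_roi = 0))
  # downscaled frames are 48 x 64 < 96 x 96
  expect_identical(dim(p$image), c(96L, 96L, 3L))
  expect_gt(sum(p$target[, , 1]), 0)
})
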