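test_that("dice and jaccard reproduce hand-computed toys", {
  a <- matrix(FALSE, 3, 3); a[1, 1] <- TRUE
  b <- matrix(FALSE, 3, 3); b[1, 1:2] <- TRUE
  expect_equal(dice(a, b), 2 / 3)              # |X|=1, |Y|=2, overlap 1
  expect_equal(jaccard(a, b), 0.5)             # J = D/(2-D) = 0.5
  expect_equal(dice(b, b), 1)
  expect_equal(jaccard(b, b), 1)
  disj <- matrix(FALSE, 3, 3); disj[3, 3] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_equal(jaccard(a, disj), 0)
  # both empty: the documented convention
  e <- matrix(FALSE, 2, 2)
  expect_equal(dice(e, e), 1)
  expect_equal(jaccard(e, e), 1)
  expect_error(dice(a, matrix(FALSE, 2, 3)), class = "feesxai_validation_error")
})

test_that("dice/jaccard match pixel-count oracles and the J = D/(2-D) identity", {
  set.seed(50)
  for (i in 1:1000) {
    x <- rand_mask(8, 8, runif(1, 0.1, 0.8))
    y <- rand_mask(8, 8, runif(1, 0.1, 0.8))
    d <- dice(x, y); j <- jaccard(x, y)
    expect_equal(d, dice_oracle(x, y))
    expect_equal(j, jaccard_oracle(x, y))
    expect_lt(abs(j - d / (2 - d)), 1e-12)
  }
})

test_that("frame classification follows the overlap rule case table", {
  e <- matrix(FALSE, 4, 4)
  px <- function(...) { m <- e; m[rbind(...)] <- TRUE; m }
  ref <- px(c(1, 1), c(1, 2))
  # one pixel of overlap suffices for a true positive
  expect_equal(classify_frame(px(c(1, 2), c(2, 3)), ref), "TP")
  # prediction without reference: false positive
  expect_equal(classify_frame(px(c(3, 3)), NULL), "FP")
  expect_equal(classify_frame(px(c(3, 3)), e), "FP")
  # reference without prediction: false negative
  expect_equal(classify_frame(e, ref), "FN")
  # neither: true negative
  expect_equal(classify_frame(e, NULL), "TN")
  # both present, zero overlap: mismatch (counted FP and FN downstream)
  expect_equal(classify_frame(px(c(4, 4)), ref), "mismatch")
})

test_that("confusion tallies are permutation-invariant and sum-conserving", {
  outcomes <- c("TP", "TP", "FN", "TN", "TN", "FP", "mismatch", "TN")
  cm <- confusion_matrix(outcomes)
  expect_equal(cm$tp, 2); expect_equal(cm$fp, 2)
  expect_equal(cm$fn, 2); expect_equal(cm$tn, 3)
  expect_equal(cm$mismatch, 1)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, cm$n_frames + cm$mismatch)
  set.seed(51)
  cm2 <- confusion_matrix(sample(outcomes))
  expect_equal(cm, cm2)
  cm3 <- confusion_matrix(rep("TN", 10))
  expect_equal(c(cm3$tp, cm3$fp, cm3$fn, cm3$tn), c(0, 0, 0, 10))
  expect_error(confusion_matrix(c("TP", "xx")), class = "feesxai_validation_error")
})

test_that("detection metrics reproduce the reference corpus table", {
  ref <- fees_detection_reference()
  expected <- tibble::tibble(
    split = ref$split,
    precision = c(0.955, 0.500, 0.706),
    f1 = c(0.925, 0.541, 0.632))
  for (i in 1:3) {
    dm <- detection_metrics(confusion_counts(ref$tp[i], ref$fp[i], ref$fn[i], 0))
    expect_equal(round(dm$precision, 3), expected$precision[i])
    expect_equal(round(dm$f1, 3), expected$f1[i])
    # F1 is the harmonic mean of the exact precision and recall
    expect_equal(dm$f1, 2 / (1 / dm$precision + 1 / dm$recall))
  }
})

test_that("degenerate confusion counts flag undefined metrics", {
  dm <- detection_metrics(confusion_counts(0, 0, 0, 5))
  expect_true(is.na(dm$precision) && is.na(dm$recall) && is.na(dm$f1))
  expect_false(dm$precision_defined || dm$recall_defined)
  dm2 <- detection_metrics(confusion_counts(0, 3, 0, 5))
  expect_equal(dm2$precision, 0)
  expect_false(dm2$recall_defined)
})

test_that("false-positive frame rate counts frames, not pixels", {
  seg_empty <- fees_segmentation(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4),
                                 matrix(FALSE, 4, 4))
  big <- matrix(TRUE, 4, 4)
  one <- matrix(FALSE, 4, 4); one[1, 1] <- TRUE
  seg_big <- fees_segmentation(big, big & FALSE, big & FALSE)
  seg_one <- fees_segmentation(one, one & FALSE, one & FALSE)
  expect_equal(fp_glottis_frame_rate(rep(list(seg_empty), 5)), 0)
  segs <- c(rep(list(seg_empty), 19), list(seg_one))
  expect_equal(fp_glottis_frame_rate(segs), 0.05)
  # a 16-pixel false region counts the same as a 1-pixel one
  segs2 <- c(rep(list(seg_empty), 19), list(seg_big))
  expect_equal(fp_glottis_frame_rate(segs2), 0.05)
  expect_error(fp_glottis_frame_rate(list(seg_empty), glottis_visible = TRUE),
               class = "feesxai_validation_error")
})

test_that("spearman_size_dice matches a manual rank computation with ties", {
  pairs <- tibble::tibble(
    ref_size_pixels = c(10, 20, 20, 40, 55, 70),
    dice_score = c(0.1, 0.4, 0.3, 0.5, 0.45, 0.9))
  res <- spearman_size_dice(pairs)
  # brute-force: Pearson correlation of average ranks
  r1 <- rank(pairs$ref_size_pixels); r2 <- rank(pairs$dice_score)
  manual <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(res$rho, manual, tolerance = 1e-12)
  expect_equal(res$n, 6)
  # monotone and antitone extremes
  mono <- tibble::tibble(ref_size_pixels = 1:5, dice_score = (1:5) / 10)
  expect_equal(spearman_size_dice(mono)$rho, 1)
  anti <- tibble::tibble(ref_size_pixels = 1:5, dice_score = (5:1) / 10)
  expect_equal(spearman_size_dice(anti)$rho, -1)
  expect_error(spearman_size_dice(mono[1:2, ]), class = "feesxai_validation_error")
})

test_that("evaluate_frames assembles per-frame metrics with a stub model", {
  ds <- generate_fees_video(tiny_scene(seed = 52, n_frames = 12,
                                       bolus_event_rate = 10))
  # a cheating model that returns the downscaled reference as probabilities
  oracle_model <- local({
    anns <- lapply(ds$annotations, downscale_annotation)
    i <- 0
    function(frame) {
      i <<- i + 1
      a <- anns[[i]]
      maps <- array(0, c(nrow(a$glottis_roi), ncol(a$glottis_roi), 3))
      maps[, , 1] <- a$glottis_roi; maps[, , 2] <- a$vocal_cords
      maps[, , 3] <- a$aspiration
      maps
    }
  })
  ev <- evaluate_frames(oracle_model, ds)
  expect_equal(nrow(ev), 12)
  # a perfect model scores Dice 1 wherever the class exists and never
  # produces FP/FN frames
  expect_true(all(ev$dice_glottis[!is.na(ev$dice_glottis)] == 1))
  expect_true(all(ev$outcome %in% c("TP", "TN")))
  visible_frames <- vapply(ds$annotations, function(a) a$glottis_visible, logical(1))
  expect_equal(is.na(ev$dice_glottis), !visible_frames)
})
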