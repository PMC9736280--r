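# Evaluation: overlap scores, the frame-level aspiration confusion matrix,
# precision / recall / F1, false-positive-frame rates on frames labeled as
# not showing the glottis, and the bolus-size-versus-Dice rank correlation.

#' Dice score between two binary masks
#'
#' `Dice(X, Y) = 2 * |X intersect Y| / (|X| + |Y|)`. Two empty masks score
#' 1.0 (an absent structure correctly predicted absent); frame-level absence
#' is handled separately by [classify_frame()] and
#' [fp_glottis_frame_rate()].
#'
#' @param x,y Binary matrices of one shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(x, y) {
  x <- as_mask(x, "x"); y <- as_mask(y, "y")
  check_same_shape(x, y)
  sx <- sum(x); sy <- sum(y)
  if (sx + sy == 0) return(1)
  2 * sum(x & y) / (sx + sy)
}

#' Jaccard score between two binary masks
#'
#' `J(X, Y) = |X intersect Y| / |X union Y|`; related to Dice by
#' `J = D / (2 - D)`. Two empty masks score 1.0.
#'
#' @inheritParams dice
#' @return Jaccard score in `[0, 1]`.
#' @export
jaccard <- function(x, y) {
  x <- as_mask(x, "x"); y <- as_mask(y, "y")
  check_same_shape(x, y)
  un <- sum(x | y)
  if (un == 0) return(1)
  sum(x & y) / un
}

#' Classify one frame's aspiration detection outcome
#'
#' A frame counts as a true positive whenever aspiration was segmented and
#' its Dice overlap with the reference is greater than 0. A predicted
#' aspiration with a present reference but zero overlap is a `"mismatch"`:
#' the detector both missed the true bolus and raised a spurious one, so
#' [confusion_matrix()] adds it to FP and FN (tallied separately so the
#' convention can be audited).
#'
#' @param pred_aspiration Binary predicted aspiration mask (post-processed).
#' @param ref_aspiration Binary reference mask, or `NULL` when the frame is
#'   annotated aspiration-free. An all-empty reference mask is treated as
#'   absent.
#' @return One of `"TP"`, `"FP"`, `"FN"`, `"TN"`, `"mismatch"`.
#' @export
classify_frame <- function(pred_aspiration, ref_aspiration = NULL) {
  pred_aspiration <- as_mask(pred_aspiration, "pred_aspiration")
  ref_present <- !is.null(ref_aspiration) && any(ref_aspiration)
  pred_present <- any(pred_aspiration)
  if (!ref_present) {
    return(if (pred_present) "FP" else "TN")
  }
  ref_aspiration <- as_mask(ref_aspiration, "ref_aspiration")
  if (!pred_present) return("FN")
  if (dice(pred_aspiration, ref_aspiration) > 0) "TP" else "mismatch"
}

#' Tally frame outcomes into confusion counts
#'
#' @param outcomes Character vector of [classify_frame()] results.
#' @return A `fees_confusion` tibble row with `tp`, `fp`, `fn`, `tn`,
#'   `mismatch` and `n_frames`. Mismatch frames contribute to both `fp` and
#'   `fn`, so `tp + fp + fn + tn = n_frames + mismatch`.
#' @export
confusion_matrix <- function(outcomes) {
  outcomes <- as.character(outcomes)
  bad <- setdiff(unique(outcomes), c("TP", "FP", "FN", "TN", "mismatch"))
  if (length(bad)) {
    abort(sprintf("Unknown outcome label(s): %s", paste(bad, collapse = ", ")),
          class = "feesxai_validation_error")
  }
  mm <- sum(outcomes == "mismatch")
  out <- tibble(
    tp = sum(outcomes == "TP"),
    fp = sum(outcomes == "FP") + mm,
    fn = sum(outcomes == "FN") + mm,
    tn = sum(outcomes == "TN"),
    mismatch = mm,
    n_frames = length(outcomes))
  class(out) <- c("fees_confusion", class(out))
  out
}

#' Confusion counts from explicit integers
#'
#' @param tp,fp,fn,tn Non-negative frame counts.
#' @return A `fees_confusion` tibble row.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) {
    abort("Confusion counts must be non-negative.", class = "feesxai_validation_error")
  }
  out <- tibble(tp = tp, fp = fp, fn = fn, tn = tn, mismatch = 0L,
                n_frames = tp + fp + fn + tn)
  class(out) <- c("fees_confusion", class(out))
  out
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`. A zero denominator yields `NA` with the
#' corresponding `*_defined` flag set to `FALSE` (degenerate inputs are
#' flagged, never an error).
#'
#' @param counts A `fees_confusion` (from [confusion_matrix()] or
#'   [confusion_counts()]).
#' @return Tibble with `precision`, `recall`, `f1` and their defined-flags.
#' @export
detection_metrics <- function(counts) {
  stopifnot(inherits(counts, "fees_confusion"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  tibble(precision = precision, recall = recall, f1 = f1,
         precision_defined = !is.na(precision),
         recall_defined = !is.na(recall),
         f1_defined = !is.na(f1))
}

#' False-positive glottis frame rate
#'
#' On frames labeled as not containing the glottis, the fraction whose final
#' glottis mask contains at least `min_pixels` falsely segmented pixels.
#'
#' @param segmentations List of `fees_segmentation` results, one per frame.
#' @param glottis_visible Logical vector of the frames' visibility labels;
#'   every entry must be `FALSE`.
#' @param min_pixels Pixel threshold for calling a frame false-positive
#'   (default 1: any pixel, the strictest reading).
#' @return Fraction of frames in `[0, 1]`.
#' @export
fp_glottis_frame_rate <- function(segmentations, glottis_visible = NULL,
                                  min_pixels = 1L) {
  if (!is.null(glottis_visible) && any(glottis_visible)) {
    abort("All frames must be labeled glottis_visible = FALSE.",
          class = "feesxai_validation_error")
  }
  if (length(segmentations) == 0L) return(0)
  hits <- vapply(segmentations, function(s) {
    sum(s$glottis_roi) >= min_pixels
  }, logical(1))
  mean(hits)
}

#' Spearman correlation of reference bolus size with Dice overlap
#'
#' Rank correlation (average ranks on ties, two-sided p value) between the
#' reference aspiration size in pixels and the achieved Dice score, probing
#' whether larger boluses are detected more easily.
#'
#' @param pairs Data frame with columns `ref_size_pixels` and `dice_score`
#'   (one row per frame with annotated aspiration).
#' @return Tibble with `rho`, `p_value`, `n`.
#' @export
spearman_size_dice <- function(pairs) {
  if (!all(c("ref_size_pixels", "dice_score") %in% names(pairs))) {
    abort("`pairs` needs columns ref_size_pixels and dice_score.",
          class = "feesxai_validation_error")
  }
  pairs <- pairs[stats::complete.cases(pairs[, c("ref_size_pixels", "dice_score")]), ]
  n <- nrow(pairs)
  if (n < 3L) {
    abort("At least 3 pairs are required for a Spearman correlation.",
          class = "feesxai_validation_error")
  }
  ct <- suppressWarnings(
    cor.test(pairs$ref_size_pixels, pairs$dice_score, method = "spearman",
             exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Evaluate a model over annotated frames
#'
#' Runs prediction and post-processing on each frame and assembles the
#' per-frame evaluation table feeding all reported metrics: per-class Dice on
#' frames whose reference contains the class, the aspiration detection
#' outcome, and pixel counts.
#'
#' @param model A `fees_unet` or prediction function (see [predict_frame()]).
#' @param dataset A `fees_dataset`.
#' @param frame_ids 1-based frame positions to evaluate (default all).
#' @param threshold,connectivity Post-processing parameters.
#' @param downscale Evaluate at half resolution (the pipeline's working
#'   resolution).
#' @return Tibble with one row per frame: `frame_index`, `glottis_visible`,
#'   per-class `dice_*` (NA where the reference lacks the class), `outcome`,
#'   `ref_aspiration_pixels`, `pred_*_pixels`.
#' @export
evaluate_frames <- function(model, dataset, frame_ids = NULL, threshold = 0.5,
                            connectivity = 8L, downscale = TRUE) {
  frame_ids <- frame_ids %||% seq_along(dataset$frames)
  rows <- lapply(frame_ids, function(i) {
    frame <- dataset$frames[[i]]
    ann <- dataset$annotations[[i]]
    if (downscale) {
      frame <- downscale_frame(frame)
      ann <- downscale_annotation(ann)
    }
    maps <- predict_frame(model, frame)
    seg <- postprocess_frame(maps, threshold, connectivity)
    dice_of <- function(cls) {
      if (any(ann[[cls]])) dice(seg[[cls]], ann[[cls]]) else NA_real_
    }
    tibble(
      frame_index = frame$frame_index,
      glottis_visible = ann$glottis_visible,
      bolus_type = ann$bolus_type,
      dice_glottis = dice_of("glottis_roi"),
      dice_vocal_cords = dice_of("vocal_cords"),
      dice_aspiration = dice_of("aspiration"),
      outcome = classify_frame(seg$aspiration,
                               if (any(ann$aspiration)) ann$aspiration else NULL),
      ref_aspiration_pixels = sum(ann$aspiration),
      pred_glottis_pixels = seg$pixel_counts[["glottis_roi"]],
      pred_vocal_cord_pixels = seg$pixel_counts[["vocal_cords"]],
      pred_aspiration_pixels = seg$pixel_counts[["aspiration"]])
  })
  dplyr::bind_rows(rows)
}

#' Write a metrics report
#'
#' @param frame_table Per-frame table from [evaluate_frames()].
#' @param dir Output directory.
#' @return Paths written, invisibly. The JSON carries the confusion counts,
#'   detection metrics and per-class median Dice; the CSV the per-frame
#'   table.
#' @export
write_metrics_report <- function(frame_table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- confusion_matrix(frame_table$outcome)
  dm <- detection_metrics(cm)
  summary <- list(
    confusion = as.list(cm),
    detection = as.list(dm),
    median_dice = list(
      glottis = median(frame_table$dice_glottis, na.rm = TRUE),
      vocal_cords = median(frame_table$dice_vocal_cords, na.rm = TRUE),
      aspiration = median(frame_table$dice_aspiration, na.rm = TRUE)))
  jp <- file.path(dir, "metrics.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA)
  cp <- file.path(dir, "frames.csv")
  write.csv(frame_table, cp, row.names = FALSE)
  invisible(c(jp, cp))
}

#' @export
autoplot.fees_confusion <- function(object, ...) {
  df <- tibble(
    predicted = factor(c(1, 1, 0, 0), levels = c(0, 1)),
    truth = factor(c(1, 0, 1, 0), levels = c(0, 1)),
    count = c(object$tp, object$fp, object$fn, object$tn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "true label", y = "predicted label",
                  title = "Aspiration detection confusion matrix") +
    ggplot2::theme_minimal()
}

#' Boxplot of per-class Dice scores
#'
#' @param frame_table Per-frame table from [evaluate_frames()] (optionally
#'   with an extra `split` column for faceting).
#' @return A ggplot object.
#' @export
plot_dice_boxplot <- function(frame_table) {
  long <- tidyr::pivot_longer(
    frame_table,
    dplyr::all_of(c("dice_glottis", "dice_vocal_cords", "dice_aspiration")),
    names_to = "class", values_to = "dice", names_prefix = "dice_")
  long <- dplyr::filter(long, !is.na(.data$dice))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$dice)) +
    ggplot2::geom_boxplot(outlier.shape = 18) +
    ggplot2::labs(x = NULL, y = "Dice score") +
    ggplot2::theme_minimal()
  if ("split" %in% names(frame_table)) {
    p <- p + ggplot2::facet_wrap(~split)
  }
  p
}

#' Scatterplot of reference bolus size versus Dice
#'
#' @param frame_table Per-frame table from [evaluate_frames()]; frames
#'   without annotated aspiration are dropped.
#' @return A ggplot object.
#' @export
plot_size_vs_dice <- function(frame_table) {
  df <- dplyr::filter(frame_table, .data$ref_aspiration_pixels > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_aspiration_pixels,
                                   y = .data$dice_aspiration)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "reference aspiration size (pixels)",
                  y = "aspiration Dice") +
    ggplot2::theme_minimal()
}
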