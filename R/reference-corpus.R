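# Reference statistics of the clinical FEES corpus the pipeline was designed
# around (92 patient videos, privately held). Shipped as plain tibbles so the
# worked examples and acceptance checks can reproduce the corpus arithmetic
# without access to the videos themselves.

#' Annotated-frame distribution of the reference FEES corpus
#'
#' Per-split counts of segmented frames, frames with aspiration, and frames
#' labeled as not showing the glottis, for the 92-video clinical corpus
#' (71 training / 6 validation / 15 test videos).
#'
#' @return A tibble with columns `split`, `n_videos`, `segmented_frames`,
#'   `aspiration_frames`, `no_glottis_frames`.
#' @export
fees_corpus_summary <- function() {
  tibble(
    split = factor(c("training", "validation", "test"),
                   levels = c("training", "validation", "test")),
    n_videos = c(71L, 6L, 15L),
    segmented_frames = c(1029L, 103L, 199L),
    aspiration_frames = c(424L, 17L, 63L),
    no_glottis_frames = c(2220L, 186L, 489L))
}

#' Frame-level aspiration confusion counts of the reference corpus
#'
#' Integer TP/FP/FN counts per split, reconstructed from the corpus's
#' reported precision/recall/F1 and its per-split aspiration-frame totals
#' (the published metrics are rounded to three decimals; these are the unique
#' integer counts consistent with the aspiration-frame totals, the precision
#' and the F1 of each split). Feeding them through [detection_metrics()]
#' reproduces the reported metrics.
#'
#' @return A tibble with columns `split`, `tp`, `fp`, `fn`.
#' @export
fees_detection_reference <- function() {
  tibble(
    split = factor(c("training", "validation", "test"),
                   levels = c("training", "validation", "test")),
    tp = c(380L, 10L, 36L),
    fp = c(18L, 10L, 15L),
    fn = c(44L, 7L, 27L))
}
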