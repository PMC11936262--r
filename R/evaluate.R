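#' @title Prediction evaluation and sequence prioritization
#' @name evaluation
#' @description
#' One-vs-rest confusion counts and precision/recall/F1 per residue class,
#' region-length-stratified per-residue metrics (short vs long
#' hard-missing regions, segmented independently in prediction and truth),
#' and the modeled-ratio screen for prioritizing structurally tractable
#' unsolved sequences.
NULL

#' One-vs-rest confusion counts for a residue class
#'
#' @param pred,truth Character label vectors of equal length.
#' @param target_class The class being scored.
#' @return Named integer vector `tp`, `tn`, `fp`, `fn` with attribute
#'   `target`.
#' @export
residue_confusion <- function(pred, truth, target_class) {
  if (length(pred) != length(truth)) {
    stop("prediction and truth must have equal length")
  }
  p <- pred == target_class
  t <- truth == target_class
  structure(c(tp = sum(p & t), tn = sum(!p & !t),
              fp = sum(p & !t), fn = sum(!p & t)),
            target = target_class)
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN), F1 the harmonic mean.
#' A zero denominator makes the metric (and then F1) undefined; it is
#' reported as `NA`, not 0.
#'
#' @param counts Named vector with `tp`, `fp`, `fn` (and optionally `tn`).
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Region-length-stratified confusion counts
#'
#' Hard-missing runs are segmented independently in the prediction and in
#' the truth, and each run is tagged short (<= 30 residues) or long. A
#' position is "in a short region" of a labeling iff it lies in a run that
#' labeling tags short. Per-residue TP/TN/FP/FN then score membership in
#' `length_class` regions, truth membership against predicted membership.
#'
#' @param pred,truth Character label vectors of equal length.
#' @param length_class `"short"` or `"long"`.
#' @param short_max Longest run still called short. Default 30.
#' @return Named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
region_stratified_confusion <- function(pred, truth, length_class,
                                        short_max = 30L) {
  if (length(pred) != length(truth)) {
    stop("prediction and truth must have equal length")
  }
  length_class <- match.arg(length_class, c("short", "long"))
  member <- function(labels) {
    reg <- segment_regions(labels, short_max = short_max)
    out <- rep(FALSE, length(labels))
    reg <- reg[reg$length_class == length_class, , drop = FALSE]
    for (i in seq_len(nrow(reg))) out[reg$start[i]:reg$end[i]] <- TRUE
    out
  }
  p <- member(pred)
  t <- member(truth)
  structure(c(tp = sum(p & t), tn = sum(!p & !t),
              fp = sum(p & !t), fn = sum(!p & t)),
            target = length_class)
}

#' Per-class and per-length-class metrics report
#'
#' Convenience wrapper producing the full table: one row per residue class
#' and per region length class, with confusion counts and
#' precision/recall/F1.
#'
#' @param pred,truth Character label vectors of equal length (concatenate
#'   over a corpus for corpus-level metrics).
#' @param classes Residue classes to score. Default all three.
#' @return Data frame with columns `target`, `tp`, `tn`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
metrics_report <- function(pred, truth, classes = residue_classes()) {
  rows <- lapply(classes, function(cls) {
    cc <- residue_confusion(pred, truth, cls)
    m <- precision_recall_f1(cc)
    data.frame(target = cls, t(as.matrix(cc))[1, , drop = FALSE], t(m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  region_rows <- lapply(c("short", "long"), function(lc) {
    cc <- region_stratified_confusion(pred, truth, lc)
    m <- precision_recall_f1(cc)
    data.frame(target = lc, t(as.matrix(cc))[1, , drop = FALSE], t(m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(rows, region_rows))
}

#' Screen sequences for a high predicted-modeled ratio
#'
#' A sequence is selected when the fraction of residues with pLDDT >= 70
#' and the fraction predicted modeled both reach `ratio_threshold`, and
#' the sequence is strictly longer than `min_length` residues.
#'
#' @param tracks_list List of score-track lists (each with `plddt`).
#' @param predictions_list List of predicted label vectors, aligned with
#'   `tracks_list`.
#' @param ratio_threshold Minimum for both ratios. Default 0.8.
#' @param min_length Sequences must exceed this length. Default 200.
#' @param ids Optional sequence identifiers.
#' @return Data frame with `id`, `seq_length`, `plddt_high_ratio`,
#'   `predicted_modeled_ratio` and `selected`.
#' @export
screen_sequences <- function(tracks_list, predictions_list,
                             ratio_threshold = 0.8, min_length = 200L,
                             ids = NULL) {
  stopifnot(length(tracks_list) == length(predictions_list))
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(tracks_list))
  rows <- lapply(seq_along(tracks_list), function(i) {
    plddt <- tracks_list[[i]]$plddt
    pred <- predictions_list[[i]]
    stopifnot(length(plddt) == length(pred))
    n <- length(plddt)
    hr <- mean(plddt >= 70)
    mr <- mean(pred == "modeled")
    data.frame(id = ids[i], seq_length = n, plddt_high_ratio = hr,
               predicted_modeled_ratio = mr,
               selected = hr >= ratio_threshold & mr >= ratio_threshold &
                 n > min_length,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
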