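#' @title Correlation, quadrant and composition analyses
#' @name feature_stats
#' @description
#' Descriptive statistics relating the residue taxonomy to the score
#' tracks: Pearson correlation of per-protein class counts against feature
#' counts, a quadrant partition of the joint (pLDDT, IUPred) plane at the
#' conventional thresholds 70 and 0.5, and per-class amino-acid
#' composition with enrichment relative to the modeled class.
NULL

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that reports `NA` with a warning when
#' either vector has zero variance (the correlation is then undefined).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Per-protein feature counts from score tracks and sequence
#'
#' Counts residues on each side of the conventional thresholds (pLDDT 70,
#' IUPred 0.5; a residue exactly at a threshold counts as high-confidence /
#' disordered respectively) and per amino-acid letter. Optional secondary
#' structure annotation adds per-element counts.
#'
#' @param tracks List with numeric `plddt` and `iupred` vectors.
#' @param sequence Protein sequence (same length as the tracks).
#' @param ss Optional per-position secondary-structure annotation
#'   (e.g. `"helix"`, `"sheet"`, `"turn"`, `"none"`).
#'
#' @return Named numeric vector of counts: `plddt_high`, `plddt_low`,
#'   `iupred_low`, `iupred_high`, `aa_*`, and `ss_*` when `ss` is given.
#' @export
feature_counts <- function(tracks, sequence, ss = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(tracks$plddt) == length(aa),
            length(tracks$iupred) == length(aa))
  counts <- c(plddt_high = sum(tracks$plddt >= 70),
              plddt_low = sum(tracks$plddt < 70),
              iupred_low = sum(tracks$iupred < 0.5),
              iupred_high = sum(tracks$iupred >= 0.5))
  letters20 <- names(.aa_background)
  aa_counts <- vapply(letters20, function(l) sum(aa == l), numeric(1))
  names(aa_counts) <- paste0("aa_", letters20)
  counts <- c(counts, aa_counts)
  if (!is.null(ss)) {
    stopifnot(length(ss) == length(aa))
    ss_counts <- table(ss)
    cn <- paste0("ss_", names(ss_counts))
    ssv <- as.numeric(ss_counts)
    names(ssv) <- cn
    counts <- c(counts, ssv)
  }
  counts
}

#' Correlate per-protein class counts against feature counts
#'
#' Computes one Pearson r per (class, feature) pair across proteins, on raw
#' counts (no length normalization).
#'
#' @param class_counts Matrix or data frame, one row per protein, columns
#'   the three residue classes (counts).
#' @param feature_counts Matrix or data frame, one row per protein, columns
#'   features as produced by [feature_counts()].
#'
#' @return Numeric matrix of correlations, classes x features.
#' @export
correlate_classes_vs_features <- function(class_counts, feature_counts) {
  class_counts <- as.matrix(class_counts)
  feature_counts <- as.matrix(feature_counts)
  if (nrow(class_counts) != nrow(feature_counts)) {
    stop("class and feature tables must have one row per protein")
  }
  if (nrow(class_counts) < 3L) stop("need at least 3 proteins")
  out <- matrix(NA_real_, ncol(class_counts), ncol(feature_counts),
                dimnames = list(colnames(class_counts),
                                colnames(feature_counts)))
  for (i in seq_len(ncol(class_counts))) {
    for (j in seq_len(ncol(feature_counts))) {
      out[i, j] <- tryCatch(
        pearson_r(class_counts[, i], feature_counts[, j]),
        warning = function(w) NA_real_)
    }
  }
  out
}

#' Assign residues to score quadrants
#'
#' Partition of the joint score plane at pLDDT 70 and IUPred 0.5:
#' Q1 = high confidence & ordered, Q2 = high confidence & disordered,
#' Q3 = low confidence & ordered, Q4 = low confidence & disordered.
#' A residue exactly at a threshold counts as high confidence (pLDDT) and
#' disordered (IUPred).
#'
#' @param plddt Numeric vector in \[0, 100\].
#' @param iupred Numeric vector in \[0, 1\], same length.
#' @return Character vector of `"Q1"`..`"Q4"`.
#' @export
assign_quadrant <- function(plddt, iupred) {
  if (length(plddt) != length(iupred)) stop("tracks must have equal length")
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT must lie in [0, 100]")
  if (any(iupred < 0 | iupred > 1)) stop("IUPred must lie in [0, 1]")
  high <- plddt >= 70
  dis <- iupred >= 0.5
  out <- character(length(plddt))
  out[high & !dis] <- "Q1"
  out[high & dis] <- "Q2"
  out[!high & !dis] <- "Q3"
  out[!high & dis] <- "Q4"
  out
}

#' Per-class quadrant occupancy
#'
#' For each residue class, the fraction of its residues falling in each
#' quadrant. Fractions per class sum to 1; a class with no residues is
#' reported as `NA`.
#'
#' @param labels Character vector of residue classes.
#' @param tracks List with aligned `plddt` and `iupred` vectors.
#' @return Numeric matrix, classes x quadrants (Q1..Q4).
#' @export
quadrant_occupancy <- function(labels, tracks) {
  stopifnot(length(labels) == length(tracks$plddt),
            length(labels) == length(tracks$iupred))
  q <- assign_quadrant(tracks$plddt, tracks$iupred)
  classes <- residue_classes()
  out <- matrix(NA_real_, length(classes), 4L,
                dimnames = list(classes, paste0("Q", 1:4)))
  for (cls in classes) {
    sel <- labels == cls
    if (!any(sel)) next
    out[cls, ] <- vapply(paste0("Q", 1:4),
                         function(qq) mean(q[sel] == qq), numeric(1))
  }
  out
}

#' Per-class amino-acid composition and enrichment
#'
#' Frequencies per class sum to 1; enrichment is each class's frequency
#' divided by the modeled class's frequency, letter by letter.
#'
#' @param labels Character vector of residue classes.
#' @param sequence Protein sequence (or concatenation over a corpus), same
#'   length as `labels`.
#' @return List with `frequencies` (classes x letters) and `enrichment`
#'   (classes x letters, relative to modeled).
#' @export
composition_profile <- function(labels, sequence) {
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == length(labels))
  letters_all <- sort(unique(c(names(.aa_background), unique(aa))))
  classes <- residue_classes()
  freq <- matrix(NA_real_, length(classes), length(letters_all),
                 dimnames = list(classes, letters_all))
  for (cls in classes) {
    sel <- labels == cls
    if (!any(sel)) next
    freq[cls, ] <- vapply(letters_all,
                          function(l) mean(aa[sel] == l), numeric(1))
  }
  enrich <- sweep(freq, 2L, freq["modeled", ], "/")
  list(frequencies = freq, enrichment = enrich)
}
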