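#' @title Residue taxonomy from multi-entry C-alpha presence
#' @name classification
#' @description
#' A protein deposited several times in the PDB gives one C-alpha presence
#' mask per structure entry, all aligned to the same full-length sequence.
#' Comparing the masks position by position yields a three-way taxonomy:
#' positions resolved in every entry are `modeled`, positions resolved in no
#' entry are `hard_missing` (the operational proxy for structural disorder),
#' and positions resolved in some entries but not others are `soft_missing`
#' (boundary or dynamic behaviour).
NULL

#' Residue class labels used throughout the package
#'
#' @return Character vector of the three residue classes, in canonical order.
#' @export
residue_classes <- function() c("modeled", "hard_missing", "soft_missing")

#' Classify residues from C-alpha presence masks
#'
#' Applies the per-position rule over a set of structure entries for one
#' protein: present in all entries -> `modeled`; absent in all ->
#' `hard_missing`; otherwise -> `soft_missing`.
#'
#' @param observations A list of logical presence vectors (one per structure
#'   entry, `TRUE` where the residue's C-alpha is present), or a logical
#'   matrix with one row per entry. All masks must have equal length.
#' @param warn_single Warn when only one entry is supplied (soft_missing is
#'   then unobservable). Default `TRUE`.
#'
#' @return A character vector of per-position labels with attribute
#'   `n_entries_used`.
#' @export
#'
#' @examples
#' classify_residues(list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE)))
classify_residues <- function(observations, warn_single = TRUE) {
  if (is.matrix(observations)) {
    mask <- observations
  } else if (is.list(observations) && length(observations) > 0L) {
    lens <- lengths(observations)
    if (length(unique(lens)) != 1L) {
      stop("all presence masks must have equal length; got lengths ",
           paste(unique(lens), collapse = ", "))
    }
    mask <- do.call(rbind, lapply(observations, as.logical))
  } else {
    stop("'observations' must be a non-empty list of masks or a logical matrix")
  }
  if (nrow(mask) == 0L) stop("at least one structure observation is required")
  if (anyNA(mask)) stop("presence masks must not contain NA")
  if (nrow(mask) == 1L && warn_single) {
    warning("single structure entry: soft_missing cannot be observed")
  }
  n_present <- colSums(mask)
  labels <- rep("soft_missing", ncol(mask))
  labels[n_present == nrow(mask)] <- "modeled"
  labels[n_present == 0L] <- "hard_missing"
  structure(labels, n_entries_used = nrow(mask))
}

#' Segment hard-missing runs into short and long disordered regions
#'
#' Finds every maximal run of consecutive `hard_missing` positions and tags
#' it `short` when it spans 30 or fewer residues, `long` otherwise.
#'
#' @param labels Character vector of residue labels (any vector; positions
#'   equal to `"hard_missing"` define the runs).
#' @param short_max Longest run still called `short`, in residues.
#'   Default 30.
#'
#' @return A data frame with columns `start`, `end` (1-based inclusive),
#'   `length` and `length_class` (`"short"`/`"long"`), sorted by `start`.
#'   Zero rows when no position is hard missing.
#' @export
#'
#' @examples
#' segment_regions(c("modeled", "hard_missing", "hard_missing", "modeled"))
segment_regions <- function(labels, short_max = 30L) {
  hard <- labels == "hard_missing"
  if (!any(hard)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), length_class = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(hard)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  len <- r$lengths[keep]
  data.frame(start = starts[keep], end = ends[keep], length = len,
             length_class = ifelse(len <= short_max, "short", "long"),
             stringsAsFactors = FALSE)
}

#' Label positions as solved or unsolved from structure-coverage annotation
#'
#' Positions inside any annotated solved range are `solved`; all others are
#' `unsolved`. Overlapping ranges are merged. A protein with no ranges (an
#' "undetermined sequence") is unsolved along its whole length.
#'
#' @param annotation A coverage annotation as returned by
#'   [read_coverage_annotations()]: a list with `accession`, `seq_length`
#'   and `solved_ranges` (a two-column matrix of 1-based inclusive
#'   start/end pairs, possibly zero rows).
#'
#' @return Character vector of length `seq_length` with values `"solved"` /
#'   `"unsolved"`.
#' @export
label_solved_unsolved <- function(annotation) {
  n <- annotation$seq_length
  stopifnot(is.numeric(n), n >= 1)
  out <- rep("unsolved", n)
  rng <- annotation$solved_ranges
  if (!is.null(rng) && nrow(rng) > 0L) {
    for (i in seq_len(nrow(rng))) {
      out[rng[i, 1L]:rng[i, 2L]] <- "solved"
    }
  }
  out
}
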