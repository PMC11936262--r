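#' @title Synthetic proteins with planted missing-residue structure
#' @name synthetic_data
#' @description
#' The generator plants a ground-truth residue taxonomy (modeled /
#' hard_missing / soft_missing), emits multi-entry C-alpha presence masks
#' consistent with that truth, and draws pLDDT / IUPred score tracks from
#' class-conditional distributions centred on the medians reported for
#' X-ray structures (pLDDT 97.1 / 84.4 / 55.5 and IUPred 0.2 / 0.29 / 0.38
#' for modeled / soft / hard). Every stage is seeded, so fixture sets are
#' byte-identical across runs.
NULL

# background amino-acid frequencies (approximate Swiss-Prot composition)
.aa_background <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686
)

.default_enrichment <- function() {
  bg <- .aa_background
  hard <- bg
  hard[c("K", "E", "S", "P")] <- hard[c("K", "E", "S", "P")] * 2.5
  hard[c("W", "Y", "F", "L", "I", "V")] <-
    hard[c("W", "Y", "F", "L", "I", "V")] * 0.35
  hard <- hard / sum(hard)
  soft <- sqrt(bg * hard)
  soft <- soft / sum(soft)
  list(modeled = bg, hard_missing = hard, soft_missing = soft)
}

.default_score_params <- function() {
  list(
    plddt = list(
      location = c(modeled = 97.1, hard_missing = 55.5, soft_missing = 84.4),
      scale    = c(modeled = 3,    hard_missing = 12,   soft_missing = 8)),
    iupred = list(
      location = c(modeled = 0.20, hard_missing = 0.38, soft_missing = 0.29),
      scale    = c(modeled = 0.08, hard_missing = 0.15, soft_missing = 0.12))
  )
}

#' Configuration for the synthetic protein generator
#'
#' Defaults describe a corpus that mirrors the reported X-ray statistics:
#' score locations at the per-class medians, hard-missing regions split
#' evenly between short (<= 30 residues) and long runs, and hard-missing
#' sequence composition enriched in K, E, S and P while depleted in
#' W, Y, F, L, I and V.
#'
#' @param n_proteins Number of proteins to generate.
#' @param length_range Two integers, min and max sequence length.
#' @param class_weights Probabilities of drawing a (modeled, hard_missing,
#'   soft_missing) segment when laying out the region budget; must sum to 1.
#' @param short_long_mix Probability that a hard-missing region is drawn
#'   short (<= 30 residues) rather than long.
#' @param n_entries_range Two integers, min and max structure entries per
#'   protein.
#' @param soft_visibility Probability that a soft-missing residue is present
#'   in any one entry; must lie strictly inside (0, 1).
#' @param score_params Per-class location/scale for the pLDDT (0-100) and
#'   IUPred (0-1) tracks; see the default for the expected shape.
#' @param smoothing_window Moving-average window (residues) applied to both
#'   score tracks to mimic along-sequence autocorrelation.
#' @param enrichment Per-class amino-acid weight tables (named numeric
#'   vectors over the 20 standard residues).
#' @param x_rate Rate at which residues are replaced by the unknown letter
#'   `X` (exercises the unknown token in the encoder). Default 0.
#' @param seed Integer seed; every derived stage is seeded from it.
#'
#' @return A validated list of class `misscan_generator_config`.
#' @export
generator_config <- function(n_proteins = 100L,
                             length_range = c(300L, 800L),
                             class_weights = c(modeled = 0.60,
                                               hard_missing = 0.25,
                                               soft_missing = 0.15),
                             short_long_mix = 0.5,
                             n_entries_range = c(2L, 5L),
                             soft_visibility = 0.5,
                             score_params = .default_score_params(),
                             smoothing_window = 5L,
                             enrichment = .default_enrichment(),
                             x_rate = 0,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              class_weights = class_weights,
              short_long_mix = short_long_mix,
              n_entries_range = as.integer(n_entries_range),
              soft_visibility = soft_visibility,
              score_params = score_params,
              smoothing_window = as.integer(smoothing_window),
              enrichment = enrichment,
              x_rate = x_rate,
              seed = as.integer(seed))
  class(cfg) <- "misscan_generator_config"
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param config A `misscan_generator_config` object.
#' @export
validate_generator_config <- function(config) {
  w <- config$class_weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("class_weights must be 3 non-negative probabilities summing to 1")
  }
  if (config$soft_visibility <= 0 || config$soft_visibility >= 1) {
    stop("soft_visibility must lie strictly inside (0, 1)")
  }
  lr <- config$length_range
  if (length(lr) != 2L || lr[1] < 1L || lr[2] < lr[1]) {
    stop("length_range must be (min, max) with min >= 1 and max >= min")
  }
  if (config$smoothing_window < 1L) stop("smoothing_window must be >= 1")
  if (config$short_long_mix < 0 || config$short_long_mix > 1) {
    stop("short_long_mix must be a probability")
  }
  if (config$n_entries_range[1] < 1L) stop("n_entries_range min must be >= 1")
  for (trk in c("plddt", "iupred")) {
    p <- config$score_params[[trk]]
    if (is.null(p) ||
        !all(residue_classes() %in% names(p$location)) ||
        !all(residue_classes() %in% names(p$scale))) {
      stop("score_params$", trk, " needs location and scale for all classes")
    }
  }
  invisible(config)
}

# sample() that treats a length-1 x as a single value, not as 1:x
.sample_from <- function(x, size, replace = FALSE) {
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size, replace = replace)
}

# lay out one protein's labels as alternating class segments; hard segments
# are separated by at least one modeled residue so run segmentation of the
# realized labels reproduces the drawn regions
.plant_labels <- function(len, class_weights, short_long_mix) {
  labels <- character(0)
  prev <- ""
  classes <- residue_classes()
  while (length(labels) < len) {
    cls <- sample(classes, 1L, prob = class_weights)
    if (cls == "hard_missing" && prev == "hard_missing") {
      labels <- c(labels, rep("modeled", sample(1:5, 1L)))
      prev <- "modeled"
      next
    }
    seg_len <- switch(cls,
      modeled = sample(20:150, 1L),
      soft_missing = sample(2:20, 1L),
      hard_missing = if (stats::runif(1) < short_long_mix) {
        sample(1:30, 1L)
      } else {
        sample(31:150, 1L)
      })
    labels <- c(labels, rep(cls, seg_len))
    prev <- cls
  }
  labels[seq_len(len)]
}

.draw_sequence <- function(labels, enrichment, x_rate) {
  seq <- vapply(labels, function(cls) {
    w <- enrichment[[cls]]
    sample(names(w), 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  if (x_rate > 0) {
    flip <- stats::runif(length(seq)) < x_rate
    seq[flip] <- "X"
  }
  paste(seq, collapse = "")
}

#' Generate ground-truth labelled proteins
#'
#' Draws, for each protein, a sequence length, a per-position class vector
#' laid out as contiguous regions (hard-missing runs separated by at least
#' one modeled residue), and an amino-acid sequence whose letters are drawn
#' from the per-class enrichment tables.
#'
#' @param config A [generator_config()].
#' @return A list of proteins, each a list with `id`, `sequence`, `labels`
#'   and `regions` (the hard-missing region table from [segment_regions()]).
#' @export
generate_truth <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  lapply(seq_len(config$n_proteins), function(i) {
    len <- .sample_from(config$length_range[1]:config$length_range[2], 1L)
    labels <- .plant_labels(len, config$class_weights, config$short_long_mix)
    list(id = sprintf("SYN%04d", i),
         sequence = .draw_sequence(labels, config$enrichment, config$x_rate),
         labels = labels,
         regions = segment_regions(labels))
  })
}

#' Simulate per-entry C-alpha presence masks from planted truth
#'
#' Modeled positions are present in every entry and hard-missing positions
#' absent in every entry. Soft-missing positions are present in each entry
#' independently with probability `soft_visibility`; with
#' `enforce_recoverable = TRUE` (the default) each soft column is re-drawn
#' until it is neither all-present nor all-absent, so classifying the masks
#' recovers the planted truth exactly.
#'
#' @param truth Character vector of planted residue labels.
#' @param n_entries Number of structure entries to simulate (>= 1).
#' @param soft_visibility Per-entry presence probability for soft residues.
#' @param seed Integer seed.
#' @param enforce_recoverable Re-sample degenerate soft columns. Disable to
#'   study unrecoverable soft residues, as real data can contain.
#'
#' @return List of logical presence masks, one per entry, each with an
#'   `entry_id` attribute.
#' @export
simulate_observations <- function(truth, n_entries, soft_visibility = 0.5,
                                  seed = 1L, enforce_recoverable = TRUE) {
  n_entries <- as.integer(n_entries)
  if (n_entries < 1L) stop("n_entries must be >= 1")
  soft <- which(truth == "soft_missing")
  if (n_entries == 1L && length(soft) > 0L) {
    stop("soft_missing truth cannot be represented with a single entry")
  }
  set.seed(seed)
  len <- length(truth)
  base <- truth == "modeled"
  masks <- matrix(rep(base, n_entries), nrow = n_entries, byrow = TRUE)
  if (length(soft) > 0L) {
    draw <- matrix(stats::runif(n_entries * length(soft)) < soft_visibility,
                   nrow = n_entries)
    if (enforce_recoverable && n_entries >= 2L) {
      repeat {
        bad <- which(colSums(draw) %in% c(0L, n_entries))
        if (length(bad) == 0L) break
        draw[, bad] <- stats::runif(n_entries * length(bad)) < soft_visibility
      }
    }
    masks[, soft] <- draw
  }
  lapply(seq_len(n_entries), function(e) {
    structure(masks[e, ], entry_id = sprintf("entry%02d", e))
  })
}

# centred moving average with truncated windows at the ends
.moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + (window - 1L - h), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulate pLDDT and IUPred score tracks for planted truth
#'
#' Scores are drawn per position from class-conditional normal
#' distributions, clipped to the track's range, then moving-average
#' smoothed to mimic along-sequence autocorrelation. Values are quantized
#' to the precision of the on-disk formats (pLDDT: 2 decimals, the PDB
#' temperature-factor column; IUPred: 4 decimals) so fixtures round-trip
#' bit-exactly.
#'
#' @param truth Character vector of planted residue labels.
#' @param score_params Per-class location/scale lists; see
#'   [generator_config()].
#' @param smoothing_window Moving-average window in residues (>= 1).
#' @param seed Integer seed.
#'
#' @return A list with numeric vectors `plddt` (in \[0, 100\]) and `iupred`
#'   (in \[0, 1\]).
#' @export
simulate_scores <- function(truth, score_params = .default_score_params(),
                            smoothing_window = 5L, seed = 1L) {
  if (smoothing_window < 1L) stop("smoothing_window must be >= 1")
  for (trk in c("plddt", "iupred")) {
    p <- score_params[[trk]]
    if (is.null(p) || !all(unique(truth) %in% names(p$location))) {
      stop("score_params must define location/scale for every class present")
    }
  }
  set.seed(seed)
  n <- length(truth)
  draw_track <- function(params, lo, hi, digits) {
    x <- stats::rnorm(n, mean = params$location[truth],
                      sd = params$scale[truth])
    x <- pmin(pmax(x, lo), hi)
    x <- .moving_average(x, smoothing_window)
    round(pmin(pmax(x, lo), hi), digits)
  }
  list(plddt = draw_track(score_params$plddt, 0, 100, 2L),
       iupred = draw_track(score_params$iupred, 0, 1, 4L))
}

#' Generate a complete synthetic corpus
#'
#' Convenience orchestration: planted truth, per-protein presence masks and
#' score tracks, all seeded from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List of protein records, each with `id`, `sequence`, `labels`,
#'   `regions`, `observations`, `tracks` and `n_entries`.
#' @export
generate_corpus <- function(config) {
  proteins <- generate_truth(config)
  set.seed(config$seed %% 100000000L + 7L)
  n <- length(proteins)
  n_entries <- .sample_from(
    config$n_entries_range[1]:config$n_entries_range[2], n, replace = TRUE)
  stage_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2L)
  for (i in seq_len(n)) {
    proteins[[i]]$n_entries <- n_entries[i]
    proteins[[i]]$observations <- simulate_observations(
      proteins[[i]]$labels, n_entries[i], config$soft_visibility,
      seed = stage_seeds[i, 1L])
    proteins[[i]]$tracks <- simulate_scores(
      proteins[[i]]$labels, config$score_params, config$smoothing_window,
      seed = stage_seeds[i, 2L])
  }
  proteins
}

#' Write a synthetic corpus to disk as plain-text fixtures
#'
#' Emits, per protein, a FASTA file, one minimal PDB file per structure
#' entry (C-alpha atoms only, at positions where the residue is present),
#' an AlphaFold-style model PDB carrying pLDDT in the temperature-factor
#' column, and an IUPred3-style three-column score table; plus a JSON
#' manifest listing every file together with the truth labels (encoded
#' M/H/S per position).
#'
#' @param proteins Corpus from [generate_corpus()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly; also written to `manifest.json`.
#' @export
write_fixture_set <- function(proteins, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  code <- c(modeled = "M", hard_missing = "H", soft_missing = "S")
  entries <- lapply(proteins, function(p) {
    fasta <- paste0(p$id, ".fasta")
    seqs <- Biostrings::AAStringSet(p$sequence)
    names(seqs) <- p$id
    Biostrings::writeXStringSet(seqs, file.path(out_dir, fasta))

    entry_files <- vapply(seq_along(p$observations), function(e) {
      f <- sprintf("%s_entry%02d.pdb", p$id, e)
      .write_ca_pdb(file.path(out_dir, f), p$sequence,
                    present = p$observations[[e]])
      f
    }, character(1))

    model <- paste0(p$id, "_model.pdb")
    .write_ca_pdb(file.path(out_dir, model), p$sequence,
                  present = rep(TRUE, nchar(p$sequence)),
                  bfactor = p$tracks$plddt, backbone = TRUE)

    iupred <- paste0(p$id, "_iupred.tsv")
    .write_iupred_table(file.path(out_dir, iupred), p$sequence,
                        p$tracks$iupred)

    list(id = p$id, length = nchar(p$sequence), fasta = fasta,
         entries = as.list(entry_files), model = model, iupred = iupred,
         labels = paste(code[p$labels], collapse = ""))
  })
  manifest <- list(n_proteins = length(proteins), proteins = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# minimal PDB writer for fixtures: fixed-format ATOM records, chain A,
# residues numbered on the full-length sequence
.write_ca_pdb <- function(path, sequence, present, bfactor = NULL,
                          backbone = FALSE) {
  aa <- strsplit(sequence, "")[[1]]
  res3 <- bio3d::aa123(aa)
  res3[aa == "X"] <- "UNK"
  idx <- which(present)
  if (is.null(bfactor)) bfactor <- rep(0, length(aa))
  names_per_res <- if (backbone) c("N", "CA", "C") else "CA"
  lines <- character(0)
  serial <- 0L
  for (i in idx) {
    for (an in names_per_res) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, an, res3[i], i,
        i * 1.0, match(an, names_per_res) * 1.0, 0.0, 1.00, bfactor[i],
        substr(an, 1L, 1L)))
    }
  }
  writeLines(c(lines, "END"), path)
}

.write_iupred_table <- function(path, sequence, iupred) {
  aa <- strsplit(sequence, "")[[1]]
  rows <- sprintf("%d\t%s\t%.4f", seq_along(aa), aa, iupred)
  writeLines(c("# POS\tRES\tIUPRED", rows), path)
}
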