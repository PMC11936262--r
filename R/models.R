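#' @title Residue-class predictors: threshold baselines and LSTM labeler
#' @name models
#' @description
#' Three predictors of residue class from the score tracks: a pLDDT
#' threshold baseline (below 70 is called hard missing), an IUPred
#' threshold baseline (at or above 0.5 is called hard missing), and a
#' single-layer LSTM sequence labeler over a 23-dimensional encoding
#' (21 token dimensions — 20 amino acids plus unknown — and the two score
#' tracks) emitting three-class probabilities per position. The baselines
#' never predict soft_missing.
NULL

.token_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' pLDDT threshold baseline
#'
#' Residues scoring under 70 are called `hard_missing`, the rest `modeled`.
#'
#' @param track Numeric pLDDT vector in \[0, 100\].
#' @return Character vector of `modeled` / `hard_missing`.
#' @export
plddt_baseline <- function(track) {
  if (any(track < 0 | track > 100)) stop("pLDDT must lie in [0, 100]")
  ifelse(track < 70, "hard_missing", "modeled")
}

#' IUPred threshold baseline
#'
#' Residues scoring at or above 0.5 are called `hard_missing`, the rest
#' `modeled` (a residue exactly at 0.5 counts as disordered, matching the
#' quadrant convention).
#'
#' @param track Numeric IUPred vector in \[0, 1\].
#' @return Character vector of `modeled` / `hard_missing`.
#' @export
iupred_baseline <- function(track) {
  if (any(track < 0 | track > 1)) stop("IUPred must lie in [0, 1]")
  ifelse(track >= 0.5, "hard_missing", "modeled")
}

#' Training configuration for the LSTM labeler
#'
#' The published presets standardize sequence length to 1,500 with 256
#' hidden units for the X-ray group and 2,500 with 300 hidden units for
#' the SPA group; both are available here, plus free choice for smaller
#' experiments.
#'
#' @param preset `"xray"`, `"spa"`, or `NULL` for manual settings.
#' @param standardized_length Sequences are zero-padded (mask off) to this
#'   length; longer sequences are truncated with a warning.
#' @param hidden_units LSTM hidden state size.
#' @param epochs,batch_size,learning_rate Adam optimization settings.
#' @param validation_fraction Fraction of proteins held out for the
#'   training log's validation split.
#' @param min_hard_missing Proteins with fewer hard-missing residues than
#'   this are discarded before training to avoid bias towards the modeled
#'   class. Default 5.
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling.
#'
#' @return A list of class `misscan_train_config`.
#' @export
train_config <- function(preset = NULL,
                         standardized_length = 1500L,
                         hidden_units = 256L,
                         epochs = 30L, batch_size = 32L,
                         learning_rate = 1e-3,
                         validation_fraction = 0.1,
                         min_hard_missing = 5L,
                         seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("xray", "spa"))
    if (preset == "xray") {
      standardized_length <- 1500L; hidden_units <- 256L
    } else {
      standardized_length <- 2500L; hidden_units <- 300L
    }
  }
  stopifnot(standardized_length >= 1L, hidden_units >= 1L,
            min_hard_missing >= 0L, epochs >= 1L, batch_size >= 1L)
  structure(list(standardized_length = as.integer(standardized_length),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 min_hard_missing = as.integer(min_hard_missing),
                 seed = as.integer(seed)),
            class = "misscan_train_config")
}

#' Encode a protein for the LSTM labeler
#'
#' Each position becomes a 23-dimensional row: a one-active token over the
#' 20 standard amino acids plus an unknown token (dimension 21) for any
#' other letter, then pLDDT rescaled to \[0, 1\] and the IUPred score.
#' Rows beyond the sequence are zero with the mask off; sequences longer
#' than the standardized length are truncated with a warning.
#'
#' @param sequence Protein sequence.
#' @param tracks List with aligned `plddt` and `iupred` vectors.
#' @param labels Optional character vector of residue classes (targets).
#' @param config A [train_config()].
#'
#' @return List with `input` (standardized_length x 23 matrix), `mask`
#'   (logical), `targets` (integer, 1 = modeled, 2 = hard_missing,
#'   3 = soft_missing, 0 = padding; all 0 when `labels` is `NULL`) and
#'   `length` (number of real positions encoded).
#' @export
encode_protein <- function(sequence, tracks, labels = NULL, config) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  stopifnot(length(tracks$plddt) == n, length(tracks$iupred) == n)
  L <- config$standardized_length
  if (n > L) {
    warning("sequence of length ", n, " truncated to standardized length ",
            L, "; the tail is excluded")
    aa <- aa[seq_len(L)]
    n <- L
  }
  input <- matrix(0, nrow = L, ncol = 23L)
  tok <- match(aa, .token_alphabet)
  tok[is.na(tok)] <- 21L
  input[cbind(seq_len(n), tok)] <- 1
  input[seq_len(n), 22L] <- tracks$plddt[seq_len(n)] / 100
  input[seq_len(n), 23L] <- tracks$iupred[seq_len(n)]
  mask <- c(rep(TRUE, n), rep(FALSE, L - n))
  targets <- integer(L)
  if (!is.null(labels)) {
    targets[seq_len(n)] <- match(labels[seq_len(n)], residue_classes())
  }
  list(input = input, mask = mask, targets = targets, length = n)
}

#' Filter out proteins with too few hard-missing residues
#'
#' Proteins whose hard-missing count is below `min_hard_missing` are
#' discarded before training to prevent bias towards the modeled class.
#'
#' @param dataset List of protein records, each with a `labels` element.
#' @param min_hard_missing Minimum hard-missing count to retain. Default 5.
#' @return The filtered list.
#' @export
filter_training_entries <- function(dataset, min_hard_missing = 5L) {
  keep <- vapply(dataset, function(p) {
    sum(p$labels == "hard_missing") >= min_hard_missing
  }, logical(1))
  out <- dataset[keep]
  if (length(out) == 0L) {
    stop("no proteins left after the hard-missing filter; ",
         "a larger or more disordered corpus is required")
  }
  out
}

#' Train the LSTM residue labeler
#'
#' A single-direction LSTM layer followed by a dense softmax over the
#' three residue classes, optimized with Adam under masked categorical
#' cross-entropy (padded positions carry no loss). Training is
#' deterministic given `config$seed`.
#'
#' @param dataset List of protein records with `sequence`, `tracks` and
#'   `labels`.
#' @param config A [train_config()].
#' @param filter Apply [filter_training_entries()] first. Default `TRUE`.
#'
#' @return Object of class `misscan_lstm`: weights, the config, the
#'   per-epoch training loss, and the held-out protein ids.
#' @export
train_recurrent <- function(dataset, config, filter = TRUE) {
  if (filter) dataset <- filter_training_entries(dataset,
                                                 config$min_hard_missing)
  if (length(dataset) < 2L) stop("need at least 2 proteins to train")
  set.seed(config$seed)

  n_val <- floor(length(dataset) * config$validation_fraction)
  val_idx <- if (n_val > 0) sample.int(length(dataset), n_val) else integer(0)
  train_set <- if (n_val > 0) dataset[-val_idx] else dataset
  val_ids <- vapply(dataset[val_idx], function(p) p$id %||% NA_character_,
                    character(1))

  enc <- lapply(train_set, function(p) {
    encode_protein(p$sequence, p$tracks, p$labels, config)
  })
  inputs <- lapply(enc, `[[`, "input")
  targets <- do.call(rbind, lapply(enc, `[[`, "targets"))

  H <- config$hidden_units
  D <- 23L
  K <- 3L
  init <- list(
    Wx = matrix(stats::rnorm(4L * H * D, sd = 1 / sqrt(D)), 4L * H, D),
    Wh = matrix(stats::rnorm(4L * H * H, sd = 1 / sqrt(H)), 4L * H, H),
    b = c(rep(0, H), rep(1, H), rep(0, 2L * H)),  # forget-gate bias 1
    Wy = matrix(stats::rnorm(K * H, sd = 1 / sqrt(H)), K, H),
    by = rep(0, K))
  perms <- t(vapply(seq_len(config$epochs),
                    function(e) sample.int(length(train_set)),
                    integer(length(train_set))))

  fit <- lstm_train_cpp(inputs, targets, perms, init,
                        config$batch_size, config$learning_rate, 5.0)

  structure(list(weights = fit[c("Wx", "Wh", "b", "Wy", "by")],
                 config = config,
                 epoch_loss = fit$epoch_loss,
                 validation_ids = val_ids),
            class = "misscan_lstm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict residue classes with a trained LSTM labeler
#'
#' @param object A `misscan_lstm` model.
#' @param sequence Protein sequence.
#' @param tracks List with aligned `plddt` and `iupred` vectors.
#' @param ... Unused.
#'
#' @return List with `labels` (character, one per real position) and
#'   `probabilities` (positions x 3 matrix, columns the residue classes).
#' @export
predict.misscan_lstm <- function(object, sequence, tracks, ...) {
  enc <- encode_protein(sequence, tracks, labels = NULL, object$config)
  if (nrow(enc$input) != object$config$standardized_length) {
    stop("encoded length does not match the model's standardized length")
  }
  probs <- lstm_forward_cpp(enc$input, object$weights)
  real <- which(enc$mask)
  probs <- probs[real, , drop = FALSE]
  colnames(probs) <- residue_classes()
  labels <- residue_classes()[max.col(probs, ties.method = "first")]
  list(labels = labels, probabilities = probs)
}

#' @export
print.misscan_lstm <- function(x, ...) {
  cat("LSTM residue labeler:", x$config$hidden_units, "hidden units,",
      "standardized length", x$config$standardized_length, "\n")
  cat("trained", length(x$epoch_loss), "epochs; final loss",
      format(utils::tail(x$epoch_loss, 1), digits = 4), "\n")
  invisible(x)
}
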