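#' @title Readers and writers for structure and score-track files
#' @name structure_io
#' @description
#' Small-file readers for every external format the pipeline consumes:
#' PDB/mmCIF structure files (C-alpha presence), AlphaFold model files
#' (pLDDT in the temperature-factor column), IUPred3 long-mode output
#' tables, FASTA, and coverage annotation tables. Input structures must be
#' numbered on the full-length sequence (1-based); renumbering arbitrary
#' author numbering is out of scope.
NULL

.read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "cif") {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
}

#' Read per-position C-alpha presence from a structure file
#'
#' `presence[i]` is `TRUE` iff an atom named `CA` exists for residue number
#' `i` in the chosen chain. Alternate locations count once. Residue numbers
#' outside `1..seq_length` are ignored with a warning; insertion codes and
#' non-positive residue numbers are rejected.
#'
#' @param structure_file Path to a PDB or mmCIF file.
#' @param chain_id Chain identifier to read.
#' @param seq_length Length of the full-length sequence the file is
#'   numbered on.
#'
#' @return Logical vector of length `seq_length` with attributes
#'   `entry_id` (file stem) and `chain_id`.
#' @export
read_calpha_presence <- function(structure_file, chain_id = "A", seq_length) {
  pdb <- tryCatch(.read_structure(structure_file),
                  error = function(e) stop("cannot parse structure file '",
                                           structure_file, "': ",
                                           conditionMessage(e)))
  atoms <- pdb$atom
  chains <- unique(atoms$chain)
  if (!chain_id %in% chains) {
    stop("chain '", chain_id, "' not found in ", structure_file,
         "; available chains: ", paste(chains, collapse = ", "))
  }
  ca <- atoms[atoms$chain == chain_id & atoms$elety == "CA", , drop = FALSE]
  if (any(!is.na(ca$insert) & ca$insert != "")) {
    stop("insertion codes are not supported: ", structure_file)
  }
  if (any(ca$resno < 1L)) {
    stop("non-positive residue numbers are not supported: ", structure_file)
  }
  resno <- unique(ca$resno)
  out_of_range <- resno[resno > seq_length]
  if (length(out_of_range) > 0L) {
    warning("ignoring ", length(out_of_range),
            " residue number(s) beyond seq_length in ", structure_file)
    resno <- resno[resno <= seq_length]
  }
  presence <- rep(FALSE, seq_length)
  presence[resno] <- TRUE
  structure(presence,
            entry_id = tools::file_path_sans_ext(basename(structure_file)),
            chain_id = chain_id)
}

#' Read a pLDDT track from an AlphaFold model file
#'
#' AlphaFold deposits the per-residue confidence (pLDDT, 0-100) in the
#' temperature-factor field of every atom of the residue. The reader takes
#' one value per residue and asserts that all atoms of a residue agree to
#' within 1e-6. Files on a 0-1 scale (all values <= 1) are rejected rather
#' than rescaled.
#'
#' @param model_file Path to the model PDB/mmCIF file.
#' @param seq_length Expected number of residues.
#'
#' @return Numeric vector of length `seq_length`, values in \[0, 100\].
#' @export
read_plddt_track <- function(model_file, seq_length) {
  pdb <- .read_structure(model_file)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  resno <- sort(unique(atoms$resno))
  if (length(resno) != seq_length) {
    stop("model has ", length(resno), " residues but seq_length is ",
         seq_length)
  }
  spread <- tapply(atoms$b, atoms$resno, function(b) diff(range(b)))
  if (any(spread > 1e-6)) {
    bad <- names(spread)[which(spread > 1e-6)[1]]
    stop("atoms of residue ", bad, " disagree on the temperature factor")
  }
  vals <- tapply(atoms$b, atoms$resno, function(b) b[1])
  track <- as.numeric(vals[order(as.numeric(names(vals)))])
  if (any(track < 0 | track > 100)) {
    stop("pLDDT values must lie in [0, 100]")
  }
  if (max(track) <= 1) {
    stop("pLDDT track appears to be on a 0-1 scale; expected 0-100")
  }
  track
}

#' Read an IUPred3 long-mode output table
#'
#' Expects the three-column dialect: comment lines starting with `#`, then
#' tab-separated position, residue letter and score rows. Positions must be
#' strictly increasing and residue letters must match the supplied
#' sequence.
#'
#' @param table_file Path to the score table.
#' @param sequence The protein sequence the table was computed on.
#'
#' @return Numeric vector of per-position scores in \[0, 1\].
#' @export
read_iupred_output <- function(table_file, sequence) {
  tab <- utils::read.table(table_file, sep = "\t", comment.char = "#",
                           col.names = c("pos", "res", "score"),
                           colClasses = c("integer", "character", "numeric"))
  if (any(diff(tab$pos) <= 0L)) {
    stop("positions in ", table_file, " are not strictly increasing")
  }
  aa <- strsplit(sequence, "")[[1]]
  if (nrow(tab) != length(aa)) {
    stop("table has ", nrow(tab), " rows but sequence has ", length(aa),
         " residues")
  }
  mism <- which(tab$res != aa)
  if (length(mism) > 0L) {
    stop("residue letter mismatch at position ", tab$pos[mism[1]],
         ": table has '", tab$res[mism[1]], "', sequence has '",
         aa[mism[1]], "'")
  }
  if (any(tab$score < 0 | tab$score > 1)) {
    stop("IUPred scores must lie in [0, 1]")
  }
  tab$score
}

#' Zero-score track for sequences too short for IUPred3
#'
#' IUPred3 cannot process sequences shorter than 16 residues; these are
#' assigned an arbitrary score of 0 throughout, reflecting their negligible
#' disorder content. Longer sequences return `NULL` as the pass-through
#' signal that a real score table is required.
#'
#' @param sequence Protein sequence.
#' @return Numeric vector of zeros when `nchar(sequence) < 16`, else `NULL`.
#' @export
default_short_sequence_scores <- function(sequence) {
  n <- nchar(sequence)
  if (n < 16L) rep(0, n) else NULL
}

#' Read FASTA sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read a coverage annotation table
#'
#' One row per protein: `accession`, `seq_length`, and a semicolon-separated
#' list of 1-based inclusive `start-end` solved ranges (may be empty for
#' proteins with no structural coverage).
#'
#' @param table_file Path to a CSV file with those three columns.
#' @return List of annotations, each a list with `accession`, `seq_length`
#'   and `solved_ranges` (two-column integer matrix, possibly zero rows).
#' @export
read_coverage_annotations <- function(table_file) {
  tab <- utils::read.csv(table_file, header = TRUE,
                         colClasses = c("character", "integer", "character"),
                         strip.white = TRUE)
  lapply(seq_len(nrow(tab)), function(i) {
    field <- trimws(tab[i, 3L])
    if (is.na(field) || field == "") {
      rng <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    } else {
      parts <- strsplit(field, ";")[[1]]
      parsed <- lapply(trimws(parts), function(p) {
        m <- regmatches(p, regexec("^([0-9]+)-([0-9]+)$", p))[[1]]
        if (length(m) != 3L) {
          stop("malformed range '", p, "' on line ", i + 1L, " of ",
               table_file)
        }
        as.integer(m[2:3])
      })
      rng <- do.call(rbind, parsed)
      colnames(rng) <- c("start", "end")
      bad <- rng[, 1L] < 1L | rng[, 2L] < rng[, 1L] |
        rng[, 2L] > tab$seq_length[i]
      if (any(bad)) {
        stop("invalid range on line ", i + 1L, " of ", table_file,
             " (need 1 <= start <= end <= seq_length)")
      }
    }
    list(accession = tab[i, 1L], seq_length = tab$seq_length[i],
         solved_ranges = rng)
  })
}

#' Write a report table with a JSON summary
#'
#' @param report A data frame; written tab-separated.
#' @param path Output path for the TSV.
#' @param summary Optional named list; written as JSON next to `path` with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, summary = NULL) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary)) {
    jsonlite::write_json(summary,
                         paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
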