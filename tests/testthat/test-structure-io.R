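# hand-formatted ATOM records, independent of the package's fixture writer
pdb_line <- function(serial, name, resname, chain, resno, b = 0) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, name, resname, chain, resno, 1.0, 2.0, 3.0, 1.00, b,
          substr(name, 1, 1))
}

write_test_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

test_that("C-alpha presence reflects exactly the residues in the file", {
  f <- write_test_pdb(c(pdb_line(1, "CA", "ALA", "A", 1),
                        pdb_line(2, "CA", "GLY", "A", 2),
                        pdb_line(3, "CA", "LYS", "A", 4)))
  pres <- read_calpha_presence(f, "A", seq_length = 4)
  expect_equal(as.logical(pres), c(TRUE, TRUE, FALSE, TRUE))

  expect_error(read_calpha_presence(f, "B", seq_length = 4),
               "available chains")

  expect_warning(
    short <- read_calpha_presence(f, "A", seq_length = 3),
    "beyond seq_length")
  expect_equal(as.logical(short), c(TRUE, TRUE, FALSE))

  # non-CA atoms do not create presence
  f2 <- write_test_pdb(c(pdb_line(1, "N", "ALA", "A", 1),
                         pdb_line(2, "CA", "GLY", "A", 2)))
  expect_equal(as.logical(read_calpha_presence(f2, "A", 2)), c(FALSE, TRUE))
})

test_that("pLDDT tracks come from the temperature-factor column", {
  f <- write_test_pdb(c(pdb_line(1, "N", "ALA", "A", 1, 97.1),
                        pdb_line(2, "CA", "ALA", "A", 1, 97.1),
                        pdb_line(3, "CA", "GLY", "A", 2, 84.4),
                        pdb_line(4, "CA", "LYS", "A", 3, 55.5)))
  expect_equal(read_plddt_track(f, 3), c(97.1, 84.4, 55.5))

  expect_error(read_plddt_track(f, 5), "seq_length")

  disagree <- write_test_pdb(c(pdb_line(1, "N", "ALA", "A", 1, 50),
                               pdb_line(2, "CA", "ALA", "A", 1, 60)))
  expect_error(read_plddt_track(disagree, 1), "disagree")

  zero_one <- write_test_pdb(c(pdb_line(1, "CA", "ALA", "A", 1, 0.9),
                               pdb_line(2, "CA", "GLY", "A", 2, 0.5)))
  expect_error(read_plddt_track(zero_one, 2), "0-1 scale")
})

test_that("IUPred tables validate positions and residue letters", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# POS\tRES\tIUPRED", "1\tM\t0.2000", "2\tK\t0.3800",
               "3\tP\t0.5100"), f)
  expect_equal(read_iupred_output(f, "MKP"), c(0.20, 0.38, 0.51))
  expect_error(read_iupred_output(f, "MAP"), "position 2")
  expect_error(read_iupred_output(f, "MKPA"), "residues")

  bad_order <- tempfile(fileext = ".tsv")
  writeLines(c("2\tK\t0.1", "1\tM\t0.1"), bad_order)
  expect_error(read_iupred_output(bad_order, "MK"), "increasing")
})

test_that("sequences too short for IUPred3 get an all-zero track", {
  expect_equal(default_short_sequence_scores(strrep("A", 15)), rep(0, 15))
  expect_null(default_short_sequence_scores(strrep("A", 16)))
  expect_equal(default_short_sequence_scores(""), numeric(0))
})

test_that("coverage annotation tables parse and validate ranges", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("accession,seq_length,ranges",
               "A6NED2, 376, 139-143",
               "NOPDB, 50, ",
               "MULTI, 100, 5-10;20-30"), f)
  ann <- read_coverage_annotations(f)
  expect_length(ann, 3)
  expect_equal(ann[[1]]$solved_ranges[1, ], c(start = 139, end = 143))
  expect_equal(nrow(ann[[2]]$solved_ranges), 0)
  expect_equal(nrow(ann[[3]]$solved_ranges), 2)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("accession,seq_length,ranges", "X, 10, 5-12"), bad)
  expect_error(read_coverage_annotations(bad), "line 2")

  malformed <- tempfile(fileext = ".csv")
  writeLines(c("accession,seq_length,ranges", "X, 10, 5to8"), malformed)
  expect_error(read_coverage_annotations(malformed), "malformed")
})

test_that("synthetic fixtures round-trip through the readers bit-exactly", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_proteins = 2, length_range = c(40, 80), seed = 17)
  corpus <- generate_corpus(cfg)
  write_fixture_set(corpus, dir)
  for (p in corpus) {
    n <- nchar(p$sequence)
    seqs <- read_fasta_sequences(file.path(dir, paste0(p$id, ".fasta")))
    expect_identical(unname(seqs[p$id]), p$sequence)
    for (e in seq_along(p$observations)) {
      m <- read_calpha_presence(
        file.path(dir, sprintf("%s_entry%02d.pdb", p$id, e)), "A", n)
      expect_identical(as.logical(m), as.logical(p$observations[[e]]))
    }
    expect_identical(
      read_plddt_track(file.path(dir, paste0(p$id, "_model.pdb")), n),
      p$tracks$plddt)
    expect_identical(
      read_iupred_output(file.path(dir, paste0(p$id, "_iupred.tsv")),
                         p$sequence),
      p$tracks$iupred)
  }
})

test_that("report tables carry a JSON summary sidecar", {
  dir <- withr::local_tempdir()
  rep <- data.frame(target = c("modeled", "hard_missing"), f1 = c(0.97, 0.58))
  path <- file.path(dir, "report.tsv")
  write_report(rep, path, summary = list(n = 2))
  back <- utils::read.delim(path)
  expect_equal(back$f1, rep$f1)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$n, 2)
})
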