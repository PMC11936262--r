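# explicit four-way loop, independent of residue_confusion
brute_confusion <- function(pred, truth, target) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == target
    t <- truth[i] == target
    if (p && t) tp <- tp + 1L
    else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# per-position membership in length-class regions of one labeling
brute_membership <- function(labels, length_class) {
  out <- rep(FALSE, length(labels))
  i <- 1
  while (i <= length(labels)) {
    if (labels[i] == "hard_missing") {
      j <- i
      while (j < length(labels) && labels[j + 1] == "hard_missing") j <- j + 1
      cls <- if (j - i + 1 <= 30) "short" else "long"
      if (cls == length_class) out[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

test_that("one-vs-rest confusion counts match their definitions", {
  truth <- c("modeled", "hard_missing")
  expect_equal(as.vector(residue_confusion(truth, truth, "modeled")[c("fp", "fn")]),
               c(0L, 0L))
  cc <- residue_confusion(c("modeled", "modeled"), truth, "modeled")
  expect_equal(as.vector(cc), c(1L, 0L, 1L, 0L))
  expect_error(residue_confusion("modeled", truth, "modeled"),
               "equal length")
})

test_that("precision, recall and F1 follow the printed formulas", {
  m <- precision_recall_f1(c(tp = 1, fp = 1, fn = 1))
  expect_equal(unname(m), c(0.5, 0.5, 0.5))

  m2 <- precision_recall_f1(c(tp = 0, fp = 0, fn = 5))
  expect_true(is.na(m2[["precision"]]))
  expect_equal(m2[["recall"]], 0)
  expect_true(is.na(m2[["f1"]]))

  m3 <- precision_recall_f1(c(tp = 3, fp = 1, fn = 2))
  expect_equal(unname(m3), c(0.75, 0.6, 2 * 0.75 * 0.6 / 1.35))
})

test_that("F1 lies between precision and recall whenever defined", {
  set.seed(12)
  for (i in 1:200) {
    counts <- c(tp = rpois(1, 5), tn = rpois(1, 5),
                fp = rpois(1, 3), fn = rpois(1, 3))
    m <- precision_recall_f1(counts)
    if (!anyNA(m)) {
      expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-12)
      expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
    }
  }
})

test_that("region-stratified counts use each labeling's own segmentation", {
  truth <- c(rep("modeled", 3), rep("hard_missing", 8), rep("modeled", 3))
  cc <- region_stratified_confusion(truth, truth, "short")
  expect_equal(as.vector(cc), c(8L, 6L, 0L, 0L))

  # a truth run of 31 split by one predicted modeled residue becomes two
  # predicted-short runs: every truth-long position is missed for "long"
  truth2 <- c("modeled", rep("hard_missing", 31), "modeled")
  pred2 <- truth2
  pred2[17] <- "modeled"
  long <- region_stratified_confusion(pred2, truth2, "long")
  expect_equal(as.vector(long), c(0L, 2L, 0L, 31L))
  short <- region_stratified_confusion(pred2, truth2, "short")
  expect_equal(as.vector(short["fp"]), 30L)

  none <- rep("modeled", 12)
  expect_equal(as.vector(region_stratified_confusion(none, none, "short")),
               c(0L, 12L, 0L, 0L))
})

test_that("confusion counts agree with brute-force oracles at random", {
  set.seed(13)
  classes <- residue_classes()
  for (i in 1:60) {
    len <- sample(20:200, 1)
    truth <- random_labels(len, seed = 1000 + i)
    pred <- random_labels(len, seed = 2000 + i)
    for (cls in classes) {
      expect_identical(as.vector(residue_confusion(pred, truth, cls)),
                       as.vector(brute_confusion(pred, truth, cls)))
    }
    for (lc in c("short", "long")) {
      pm <- brute_membership(pred, lc)
      tm <- brute_membership(truth, lc)
      expected <- c(tp = sum(pm & tm), tn = sum(!pm & !tm),
                    fp = sum(pm & !tm), fn = sum(!pm & tm))
      expect_identical(as.vector(region_stratified_confusion(pred, truth, lc)),
                       as.vector(expected))
    }
  }
})

test_that("metrics report covers classes and region length classes", {
  truth <- random_labels(300, 77)
  pred <- random_labels(300, 78)
  rep <- metrics_report(pred, truth)
  expect_equal(rep$target,
               c(residue_classes(), "short", "long"))
  expect_true(all(rep$tp + rep$tn + rep$fp + rep$fn == 300))
})

test_that("the screen selects on both ratios and strict length", {
  mk <- function(n, high_frac, mod_frac) {
    plddt <- c(rep(90, round(n * high_frac)),
               rep(50, n - round(n * high_frac)))
    pred <- c(rep("modeled", round(n * mod_frac)),
              rep("hard_missing", n - round(n * mod_frac)))
    list(tracks = list(plddt = plddt), pred = pred)
  }
  cases <- list(mk(250, 0.85, 0.82),   # selected
                mk(250, 0.85, 0.79),   # modeled ratio below threshold
                mk(250, 0.79, 0.9),    # pLDDT ratio below threshold
                mk(200, 0.9, 0.9),     # exactly 200 residues: excluded
                mk(201, 0.9, 0.9),     # just over 200: selected
                mk(250, 0.8, 0.8))     # ratios exactly at threshold: selected
  res <- screen_sequences(lapply(cases, `[[`, "tracks"),
                          lapply(cases, `[[`, "pred"))
  expect_equal(res$selected, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))

  # monotone in the ratio threshold
  strict <- screen_sequences(lapply(cases, `[[`, "tracks"),
                             lapply(cases, `[[`, "pred"),
                             ratio_threshold = 0.9)
  expect_true(all(res$selected | !strict$selected))
})
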