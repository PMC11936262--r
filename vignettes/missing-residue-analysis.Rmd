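---
title: "Classifying missing residues and relating them to disorder scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying missing residues and relating them to disorder scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misscan)
```

## The problem

Experimentally determined protein structures routinely lack coordinates for
part of the chain. These "missing" residues are not noise: regions that
X-ray crystallography or cryo-EM cannot resolve are strongly enriched in
intrinsically disordered regions (IDRs). When the same protein has been
deposited several times, the pattern of absence across entries carries
information. `misscan` operationalizes this with a three-way residue
taxonomy over a group of structure entries that share one full-length
sequence:

* **modeled** — the C&alpha; atom is present in *every* entry;
* **hard missing** — the C&alpha; is absent in *every* entry: the
  operational proxy for structural disorder;
* **soft missing** — present in some entries, absent in others: boundary
  or dynamic behaviour.

Maximal runs of hard-missing residues are segmented into **short**
(&le; 30 residues) and **long** (&gt; 30) disordered regions; the
30-residue cut follows established length-dependent disorder analyses,
and short and long regions behave differently for every predictor we
evaluate.

Two per-residue score tracks are consumed as inputs, never recomputed:
AlphaFold's pLDDT confidence (0–100, stored in the temperature-factor
column of model files; &ge; 70 is conventionally "confident") and the
IUPred3 long-mode disorder score (0–1; &ge; 0.5 conventionally
disordered). Sequences shorter than 16 residues, which IUPred3 cannot
process, receive an all-zero track (`default_short_sequence_scores()`).

## The synthetic corpus

The package is exercised end-to-end on synthetic proteins
(`generator_config()`, `generate_corpus()`). The generator plants a
ground-truth label per position and then emits everything downstream
consistently, so recovery can be checked exactly. Its defaults are the
study conditions for all tests:

* **Score distributions.** Class-conditional truncated normals centred on
  the X-ray medians reported for the three classes: pLDDT 97.1 / 84.4 /
  55.5 and IUPred 0.20 / 0.29 / 0.38 for modeled / soft / hard. Only
  medians are reported for the real data, so the scales — (3, 8, 12) for
  pLDDT and (0.08, 0.12, 0.15) for IUPred — were chosen once to keep the
  classes separable but overlapping, roughly matching the violin spreads
  of per-class score distributions seen in such data.
* **Autocorrelation.** Real score tracks vary smoothly along the chain.
  After drawing i.i.d. per-position scores, a centred moving average
  (default window 5 residues) is applied. The window is a modelling
  choice, not a reported value. Scores are then quantized to the on-disk
  precision (2 decimals for pLDDT, the PDB B-factor format; 4 for IUPred)
  so that written fixtures read back bit-exactly.
* **Region architecture.** Labels are laid out as alternating segments:
  modeled stretches of 20–150 residues, soft stretches of 2–20, and
  hard-missing regions drawn short (1–30) or long (31–150) with equal
  probability by default. Consecutive hard regions are separated by at
  least one modeled residue so run segmentation is unambiguous.
* **Observations.** Each protein gets 2–5 structure entries. Modeled
  positions are present in all, hard-missing in none; soft-missing
  positions are present per entry with probability 0.5 and re-drawn until
  the column is neither all-present nor all-absent, making the planted
  truth exactly recoverable. Real data can contain unrecoverable soft
  residues; `enforce_recoverable = FALSE` disables the constraint for
  robustness experiments. A single-entry protein cannot represent soft
  truth at all and is rejected.
* **Composition.** Sequence letters are drawn per class. Hard-missing
  positions up-weight K, E, S and P (×2.5) and down-weight W, Y, F, L, I
  and V (×0.35) against a Swiss-Prot-like background; soft-missing uses
  the geometric mean of the two tables, mirroring the intermediate
  composition of dynamically disordered residues.
* **Sizes.** 100 proteins of 300–800 residues for descriptive statistics;
  200 training plus 50 held-out proteins for the learning experiments.
  These sizes give stable medians and correlations while keeping the full
  suite fast.

What the generator does *not* emulate: 3D coordinates (only presence
matters), resolution differences between experiment groups, author
renumbering of deposited chains, and score miscalibration (synthetic
pLDDT is, by construction, honestly informative about the planted
classes). Passing tests therefore demonstrate correctness of the
machinery and faithful behaviour *under the planted statistics*, not
predictor performance on real proteins.

```{r corpus}
cfg <- generator_config(n_proteins = 20, seed = 1)
corpus <- generate_corpus(cfg)
p <- corpus[[1]]
table(p$labels)
head(p$regions)
```

## Classification and its contracts

`classify_residues()` applies the per-position rule; it is total on any
non-empty set of equal-length masks and always partitions the sequence.
Positions never covered by any entry's construct are indistinguishable
from hard missing under the C&alpha; rule and are labelled hard missing.
A single-entry protein yields only modeled/hard labels and triggers a
warning rather than an error.

```{r classify}
labs <- classify_residues(p$observations)
identical(as.character(labs), p$labels)
```

`segment_regions()` returns maximal hard-missing runs; a run of exactly
30 residues is short, 31 is long. `label_solved_unsolved()` implements
the coverage-annotation view used for human-proteome screening: positions
inside any annotated PDB-covered range are solved, everything else —
including the whole sequence of proteins with no structural record — is
unsolved.

## Descriptive statistics

Correlations are computed **across proteins on raw counts** (the count of
residues in a class against the count of residues passing a feature
threshold), not across residues and not length-normalized; this matches
how class/feature agreement is usually summarized for such corpora and
keeps the statistic interpretable for proteins of very different lengths.
Quadrants partition the joint score plane at pLDDT 70 and IUPred 0.5; a
residue exactly at a threshold counts as high-confidence and as
disordered respectively. The same boundary conventions are used by the
threshold baselines, so a residue at IUPred exactly 0.5 is always
disordered everywhere in the package.

```{r quadrants}
all_labs <- unlist(lapply(corpus, `[[`, "labels"))
tracks <- list(plddt = unlist(lapply(corpus, function(p) p$tracks$plddt)),
               iupred = unlist(lapply(corpus, function(p) p$tracks$iupred)))
round(quadrant_occupancy(all_labs, tracks), 3)
```

## Predictors

Two pointwise baselines: pLDDT under 70 &rarr; hard missing; IUPred at or
above 0.5 &rarr; hard missing. Neither ever predicts soft missing.

The sequence labeler is a compact single-direction LSTM followed by a
dense softmax over the three classes, written against RcppArmadillo and
trained with Adam under masked categorical cross-entropy. Inputs are
encoded per position as 23 dimensions: a one-active token over the 20
standard amino acids plus an unknown token (dimension 21), then pLDDT
rescaled to [0, 1] — so both score dimensions share a scale — and the
IUPred score. Sequences are zero-padded to a standardized length with the
padding masked out of the loss, or truncated with a warning when longer;
the truncated tail is excluded from evaluation. Published presets are
available (`train_config(preset = "xray")`: length 1,500, 256 units;
`"spa"`: 2,500, 300 units); tests and the acceptance script use a reduced
setting (length 800, 64 units, 40 epochs at learning rate 3e-3) that
trains in about a minute on one CPU while reaching the same qualitative
result — the LSTM tracks the pLDDT baseline closely.

Numerical choices: forget-gate bias initialized to 1 (standard for LSTM
stability), Gaussian weight init scaled by fan-in, global gradient-norm
clipping at 5, and all randomness (init, shuffling, splits) drawn from
the R RNG so training is exactly reproducible given the seed. Training
aborts with diagnostics on a non-finite loss. Proteins with fewer than 5
hard-missing residues are discarded before training to avoid bias toward
the modeled class. The recurrent layer is single-direction only; class
weighting is deliberately not applied.

Design notes on open points: the 21st token dimension is read as
"unknown residue" (any letter outside the 20 standard amino acids,
including X) rather than a gap token; and the validation split is a
generic seeded held-out fraction, standing in for the
deposition-date-based (pre/post-2022) split used with real corpora,
which has no synthetic analogue.

## Evaluation

Per-class metrics are one-vs-rest per-residue confusion counts with
precision, recall and F1 exactly as defined by TP/(TP+FP), TP/(TP+FN)
and their harmonic mean. A zero denominator leaves the metric (and F1)
`NA` rather than 0, preserving a distinction that summary tables often
blur. Region-stratified metrics segment hard-missing runs independently
in the prediction and in the truth and score per-residue membership in
short (or long) regions of each labeling; this reading — where a
predicted run's own length determines its tag — explains why region-level
F1 drops relative to plain hard-missing F1 through extra false positives
(a long truth region fragmented by one wrong call becomes two short
predicted regions, every position of which is a short false positive).
Soft-missing truth counts as a negative for both baseline targets, since
the baselines cannot emit it.

`screen_sequences()` implements the prioritization rule for unsolved
proteins: selected iff the fraction of residues with pLDDT &ge; 70 and
the fraction predicted modeled are both at least 0.8 *and* the sequence
is strictly longer than 200 residues.

```{r metrics}
pred <- plddt_baseline(tracks$plddt)
metrics_report(pred, all_labs)[, c("target", "precision", "recall", "f1")]
```

## Limitations

* The classification rule inherits the blind spots of the C&alpha;
  criterion: construct boundaries, proteolysed termini and crystal
  contacts all masquerade as disorder in real data.
* The synthetic scores are drawn from the *reported medians* of one
  experiment group (X-ray); other modalities have different score
  geometry and the package's defaults do not emulate them.
* IUPred's threshold baseline performs poorly under these defaults
  because the planted hard-missing IUPred median (0.38) lies below the
  0.5 cut — the same qualitative weakness reported for real corpora,
  though more pronounced here.
* Corpus curation (selecting the longest complete chains, mapping author
  numbering to full-length sequences, bulk retrieval) is out of scope;
  readers require inputs numbered on the full-length sequence.
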