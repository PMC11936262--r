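# shared synthetic corpora, built once per test run
.corpus_cache <- new.env(parent = emptyenv())

shared_corpus <- function(n = 100L, seed = 1L) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.corpus_cache[[key]])) {
    .corpus_cache[[key]] <- generate_corpus(
      generator_config(n_proteins = n, seed = seed))
  }
  .corpus_cache[[key]]
}

corpus_labels <- function(corpus) unlist(lapply(corpus, `[[`, "labels"))
corpus_plddt <- function(corpus) {
  unlist(lapply(corpus, function(p) p$tracks$plddt))
}
corpus_iupred <- function(corpus) {
  unlist(lapply(corpus, function(p) p$tracks$iupred))
}

# independent restatement of the three-way residue rule, position by position
brute_force_classify <- function(mask_matrix) {
  vapply(seq_len(ncol(mask_matrix)), function(j) {
    col <- mask_matrix[, j]
    if (all(col)) "modeled" else if (!any(col)) "hard_missing"
    else "soft_missing"
  }, character(1))
}

# random label vector with contiguous structure for region tests
random_labels <- function(len, seed) {
  set.seed(seed)
  labs <- character(0)
  while (length(labs) < len) {
    cls <- sample(c("modeled", "hard_missing", "soft_missing"), 1,
                  prob = c(0.5, 0.35, 0.15))
    labs <- c(labs, rep(cls, sample(1:40, 1)))
  }
  labs[seq_len(len)]
}
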