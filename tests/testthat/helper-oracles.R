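# Independent brute-force oracles used to cross-check the optimized paths.

CANONICAL20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# naive per-window dictionary count: loop + substr, no shared code with
# corpus_windows()/build_scs_table()
naive_scs_counts <- function(sequences, n) {
  counts <- new.env(parent = emptyenv())
  total <- 0L
  for (s in sequences) {
    L <- nchar(s)
    if (L < n) next
    for (i in seq_len(L - n + 1)) {
      w <- substr(s, i, i + n - 1)
      if (all(strsplit(w, "")[[1]] %in% CANONICAL20)) {
        total <- total + 1L
        counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
      }
    }
  }
  list(R = unlist(as.list(counts)), Q = total)
}

# brute-force double loop over all window pairs under the "gap" relation
# convention (sub_start = core_start + 2 + r for r > 0, core_start - |r| - 2
# for r < 0)
naive_idiom_counts <- function(sequences, max_relation = 10) {
  rel_counts <- list()
  denoms <- list()
  for (s in sequences) {
    L <- nchar(s)
    if (L < 3) next
    is_can <- function(w) all(strsplit(w, "")[[1]] %in% CANONICAL20)
    for (i in seq_len(L - 2)) {
      core <- substr(s, i, i + 2)
      if (!is_can(core)) next
      for (r in c(-(max_relation:1), 1:max_relation)) {
        j <- if (r > 0) i + 2 + r else i - abs(r) - 2
        if (j < 1 || j > L - 2) next
        sub <- substr(s, j, j + 2)
        if (!is_can(sub)) next
        key <- paste(core, sub, r, sep = "|")
        dkey <- paste(core, r, sep = "|")
        rel_counts[[key]] <- (rel_counts[[key]] %||% 0L) + 1L
        denoms[[dkey]] <- (denoms[[dkey]] %||% 0L) + 1L
      }
    }
  }
  list(relation = rel_counts, denominator = denoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small reproducible random corpus over the full alphabet
random_corpus <- function(nseq, len_range = c(10, 40), seed = 42,
                          alphabet = CANONICAL20) {
  set.seed(seed)
  seqs <- vapply(seq_len(nseq), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    paste0(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  as_scs_corpus(seqs, label = paste0("rand", seed))
}

passage_path <- function() {
  system.file("extdata", "english_passage.txt", package = "scskit")
}
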