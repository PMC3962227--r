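test_that("the single-sequence toy table is fully hand-checkable", {
  tab <- build_idiom_table(as_scs_corpus("MKVLAG"), max_relation = 10)
  fwd <- tab[tab$core == "MKV" & tab$sub == "LAG" & tab$relation == 1, ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$relation_count, 1L)
  expect_equal(fwd$denominator, 1L)
  expect_equal(fwd$Y, 1.0)
  expect_equal(fwd$sub_count, 1L)
  expect_equal(attr(tab, "total_triplets"), 4L)
  expect_equal(fwd$X, 0.25)
  expect_equal(fwd$score, 3.0)
  # mirror record
  rev <- tab[tab$core == "LAG" & tab$sub == "MKV" & tab$relation == -1, ]
  expect_equal(rev$relation_count, 1L)
  # sequences of length 3 admit no pair
  expect_equal(nrow(build_idiom_table(as_scs_corpus(c("MKV", "LAG")))), 0)
})

test_that("evaluation score is (Y - X)/X", {
  expect_equal(evaluation_score(0.2, 0.2), 0)
  expect_equal(evaluation_score(0.1, 0.2), 1)
  expect_equal(evaluation_score(0.1, 0), -1)
  expect_true(is.na(evaluation_score(0, 0.5)))
  expect_true(all(evaluation_score(runif(20, 0.01, 1), runif(20)) >= -1))
})

test_that("idiom table equals the brute-force double loop on small corpora", {
  for (seed in c(31, 32)) {
    corpus <- random_corpus(40, c(6, 30), seed = seed,
                            alphabet = c(CANONICAL20, "X"))
    tab <- build_idiom_table(corpus, max_relation = 4)
    oracle <- naive_idiom_counts(corpus$sequence, max_relation = 4)
    expect_equal(nrow(tab), length(oracle$relation))
    for (key in names(oracle$relation)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      row <- tab[tab$core == parts[1] & tab$sub == parts[2] &
                   tab$relation == as.integer(parts[3]), ]
      expect_equal(row$relation_count, oracle$relation[[key]])
      dkey <- paste(parts[1], parts[3], sep = "|")
      expect_equal(row$denominator, oracle$denominator[[dkey]])
    }
  }
})

test_that("mirror symmetry and Y-normalization hold exhaustively", {
  corpus <- random_corpus(30, c(8, 25), seed = 44)
  tab <- build_idiom_table(corpus, max_relation = 5)
  # relation_count(c, s, +r) == relation_count(s, c, -r)
  key <- paste(tab$core, tab$sub, tab$relation)
  mirror <- paste(tab$sub, tab$core, -tab$relation)
  idx <- match(mirror, key)
  expect_false(anyNA(idx))
  expect_equal(tab$relation_count, tab$relation_count[idx])
  # sum of Y over subs at fixed (core, relation) is 1
  sums <- aggregate(Y ~ core + relation, data = as.data.frame(tab), sum)
  expect_true(all(abs(sums$Y - 1) < 1e-12))
  # and relation counts at fixed (core, relation) sum to the denominator
  cs <- aggregate(relation_count ~ core + relation,
                  data = as.data.frame(tab), sum)
  dn <- unique(as.data.frame(tab)[, c("core", "relation", "denominator")])
  m <- merge(cs, dn, by = c("core", "relation"))
  expect_equal(m$relation_count, m$denominator)
})

test_that("idiom queries filter by rank, count, and role", {
  corpus <- random_corpus(50, c(15, 40), seed = 55)
  tab <- build_idiom_table(corpus, max_relation = 3)
  top100 <- query_idioms(tab, max_rank = 100)
  expect_equal(nrow(top100), min(100, nrow(tab)))
  expect_equal(top100$rank, seq_len(nrow(top100)))
  expect_equal(top100$score, sort(tab$score, decreasing = TRUE)[1:nrow(top100)])

  trip <- tab$core[1]
  both <- query_idioms(tab, trip, role = "either", max_rank = 500)
  core_only <- query_idioms(tab, trip, role = "core", max_rank = 500)
  sub_only <- query_idioms(tab, trip, role = "sub", max_rank = 500)
  expect_setequal(both$rank, union(core_only$rank, sub_only$rank))
  expect_equal(nrow(query_idioms(tab, "WWW", max_rank = 1e6)) > 0,
               "WWW" %in% c(tab$core, tab$sub))
  expect_error(query_idioms(tab, "notatriplet"),
               class = "scskit_data_error")
})

test_that("annotation finds table idioms at their positions", {
  tab <- build_idiom_table(as_scs_corpus("MKVLAG"), max_relation = 10)
  hits <- annotate_sequence("MKVLAG", tab, rank_border = 10)
  fwd <- hits[hits$core == "MKV" & hits$relation == 1, ]
  expect_equal(fwd$core_position, 1L)
  expect_equal(fwd$sub_position, 4L)
  expect_equal(fwd$sub, "LAG")
  # ordered N-terminal first
  expect_true(!is.unsorted(hits$core_position))
  # nothing under an impossible border
  expect_equal(nrow(annotate_sequence("MKVLAG", tab, rank_border = 0)), 0)
  # default border is 1000: idioms at rank <= 1000 all annotate
  expect_equal(annotate_sequence("MKVLAG", tab),
               annotate_sequence("MKVLAG", tab, rank_border = 1000))
  expect_equal(nrow(annotate_sequence("ACDEF", tab)), 0)
})

test_that("greedy design chains adjacency idioms from a seed", {
  tab <- build_idiom_table(as_scs_corpus("MKVLAG"))
  d1 <- design_sequence("MKV", tab, steps = 1)
  expect_equal(d1$sequence, "MKVLAG")
  expect_equal(nrow(d1$steps), 1)
  d0 <- design_sequence("MKV", tab, steps = 0)
  expect_equal(d0$sequence, "MKV")
  # each completed step lengthens the sequence by exactly 3
  corpus <- random_corpus(60, c(20, 50), seed = 66)
  big <- build_idiom_table(corpus, max_relation = 2)
  d <- design_sequence(big$core[1], big, steps = 4)
  expect_equal(nchar(d$sequence), 3 + 3 * nrow(d$steps))
  expect_equal(tidy(d), d$steps)
  expect_equal(glance(d)$length, nchar(d$sequence))
  # left extension prepends
  dl <- design_sequence("LAG", tab, steps = 1, direction = "left")
  expect_equal(dl$sequence, "MKVLAG")
  # a seed with no idioms yields a zero-step trace
  dn <- design_sequence("WWW", tab, steps = 3)
  expect_equal(dn$sequence, "WWW")
  expect_equal(nrow(dn$steps), 0)
  expect_error(design_sequence("WW", tab, steps = 1),
               class = "scskit_data_error")
})

test_that("planted idiom attains evaluation-score rank 1", {
  spec <- corpus_spec(
    300, c(80, 120), residue_probs = nr_aa_like_probs(),
    planted_idioms = data.frame(core = "ALA", sub = "WCW", relation = 2,
                                rate = 1.0),
    seed = 91, label = "idiom")
  corpus <- generate_corpus(spec)
  tab <- build_idiom_table(corpus, max_relation = 10, min_count = 50)
  expect_equal(tab$core[1], "ALA")
  expect_equal(tab$sub[1], "WCW")
  expect_equal(tab$relation[1], 2L)
  expect_equal(tab$rank[tab$core == "ALA" & tab$sub == "WCW" &
                          tab$relation == 2], 1L)
})

test_that("idiom tables round-trip through TSV", {
  corpus <- random_corpus(20, c(10, 30), seed = 77)
  tab <- build_idiom_table(corpus, max_relation = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_idiom_table(tab, f)
  back <- read_idiom_table(f)
  expect_equal(attr(back, "total_triplets"), attr(tab, "total_triplets"))
  expect_equal(attr(back, "max_relation"), 3L)
  expect_equal(back$core, tab$core)
  expect_equal(back$score, tab$score, tolerance = 1e-12)
  expect_equal(back$rank, tab$rank)
})
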