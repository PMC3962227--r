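toy <- as_scs_corpus(c("ACDEF", "ACD"), label = "toy")

test_that("residue frequencies are pooled counts over canonical residues", {
  f <- residue_frequencies(as_scs_corpus(c("ACAC", "A")))
  expect_equal(attr(f, "total"), 5)
  expect_equal(f$count[f$residue == "A"], 3L)
  expect_equal(f$count[f$residue == "C"], 2L)
  expect_equal(f$prob[f$residue == "A"], 0.6)
  expect_equal(sum(f$prob), 1, tolerance = 1e-12)

  f1 <- residue_frequencies(as_scs_corpus("AAAA"))
  expect_equal(f1$prob[f1$residue == "A"], 1.0)
  expect_error(residue_frequencies(as_scs_corpus("XXXX")),
               class = "scskit_data_error")
})

test_that("expected count is the product formula E = Q * P1...Pn", {
  uniform <- residue_frequencies(
    as_scs_corpus(paste0(CANONICAL20, collapse = "")))
  expect_equal(expected_count(uniform, 8000, "MKV"), 8000 * 0.05^3)
  expect_equal(expected_count(uniform, 8000, "WWW"), 1.0)

  f <- residue_frequencies(toy)
  expect_equal(expected_count(f, 4, "ACD"), 4 * 0.25^3)
  # residue absent from the corpus has P = 0, hence E = 0
  expect_equal(expected_count(f, 4, "WWW"), 0)
  expect_error(expected_count(f, 4, "AXD"), class = "scskit_data_error")
})

test_that("availability follows A = R/E - 1 with the -1 floor", {
  expect_equal(availability(5, 5), 0)
  expect_equal(availability(0, 2), -1)
  expect_equal(availability(2, 0.0625), 31.0)
  expect_true(is.na(availability(0, 0)))
  expect_error(availability(-1, 1), class = "scskit_data_error")
})

test_that("the toy two-sequence corpus reproduces all hand-derived values", {
  t3 <- build_scs_table(toy, 3)
  expect_equal(scs_Q(t3), 4)
  expect_equal(sum(t3$R), 4)
  look <- scs_lookup(t3, c("ACD", "CDE", "DEF", "AAA"))
  expect_equal(look$R, c(2L, 1L, 1L, 0L))
  expect_equal(look$E[look$scs == "ACD"], 0.0625)
  expect_equal(look$A[look$scs == "ACD"], 31.0)
  expect_equal(look$A[look$scs == "AAA"], -1)
  expect_equal(look$E[look$scs == "AAA"], 4 * 0.25^3)
})

test_that("repertoire size is 20^n and matches exhaustive enumeration", {
  expect_equal(repertoire_size(3), 8000)
  expect_equal(repertoire_size(4), 160000)
  expect_equal(repertoire_size(5), 3200000)
  expect_equal(repertoire_size(6), 6.4e7)
  for (n in 1:4) {
    keys <- enumerate_repertoire(n)
    expect_equal(length(keys), repertoire_size(n))
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_error(repertoire_size(0), class = "scskit_data_error")
})

test_that("counting conserves windows and matches the naive oracle", {
  for (seed in c(11, 12)) {
    corpus <- random_corpus(60, c(5, 35), seed = seed,
                            alphabet = c(CANONICAL20, "X", "*"))
    for (n in c(3, 4)) {
      tab <- build_scs_table(corpus, n)
      oracle <- naive_scs_counts(corpus$sequence, n)
      expect_equal(scs_Q(tab), oracle$Q)
      expect_equal(sum(tab$R), scs_Q(tab))
      o <- sort(oracle$R)
      got <- setNames(tab$R, tab$scs)[names(o)]
      expect_equal(unname(got), unname(o))
      expect_equal(length(tab$R), length(o))
    }
  }
})

test_that("normalization: full-repertoire E sums to Q and E*A sums to 0", {
  corpus <- random_corpus(40, c(20, 60), seed = 5)
  t3 <- build_scs_table(corpus, 3, repertoire = "full")
  Q <- scs_Q(t3)
  expect_equal(nrow(t3), 8000)
  expect_equal(sum(t3$E), Q, tolerance = 1e-6)
  expect_equal(sum(t3$E * t3$A) / Q, 0, tolerance = 1e-6)
})

test_that("adding a record never decreases a real count", {
  base <- random_corpus(20, c(10, 30), seed = 3)
  t0 <- build_scs_table(base, 3)
  extra <- as_scs_corpus(
    rbind(as.data.frame(base[, c("identifier", "sequence")]),
          data.frame(identifier = "extra", sequence = "MKVMKVMKV")))
  t1 <- build_scs_table(extra, 3)
  merged <- merge(as.data.frame(t0[, c("scs", "R")]),
                  as.data.frame(t1[, c("scs", "R")]),
                  by = "scs", all.x = TRUE)
  expect_true(all(merged$R.y >= merged$R.x))
  expect_gt(scs_lookup(t1, "MKV")$R, scs_lookup(t0, "MKV")$R)
})

test_that("rank-frequency ranks ties per policy", {
  rf <- rank_frequency(c(x = 5, y = 3, z = 3, w = 1))
  expect_equal(rf$rank, c(1L, 2L, 2L, 4L))
  expect_equal(rf$item, c("x", "y", "z", "w"))
  ord <- rank_frequency(c(x = 5, y = 3, z = 3, w = 1), "ordinal")
  expect_equal(ord$rank, 1:4)
  all1 <- rank_frequency(c(a = 1, b = 1, c = 1))
  expect_true(all(all1$rank == 1))
  expect_error(rank_frequency(numeric()), class = "scskit_data_error")
})

test_that("worked word-count example reproduces the printed frequencies", {
  tokens <- read_text_tokens(passage_path())
  rf <- rank_frequency(count_items(tokens))
  freq_of <- function(w) rf$frequency[rf$item == w]
  expect_equal(freq_of("of"), 7)
  expect_equal(rf$rank[rf$item == "of"], 1L)
  expect_equal(freq_of("amino"), 4)
  expect_equal(freq_of("acid"), 4)
  expect_equal(freq_of("a"), 4)
  expect_equal(freq_of("the"), 3)
  expect_equal(freq_of("proteins"), 3)
  expect_equal(freq_of("that"), 3)
  expect_equal(freq_of("english"), 2)
  expect_equal(freq_of("words"), 2)
  # singular and plural are counted as distinct tokens
  expect_equal(freq_of("sequences"), 4)
  expect_equal(freq_of("sequence"), 2)
})

test_that("power-law fit recovers known slopes", {
  exact <- rank_frequency(
    tibble::tibble(item = paste0("w", 1:100), frequency = 1000 / (1:100)),
    tie_policy = "ordinal")
  fit <- power_law_fit(exact)
  expect_equal(fit$slope, -1.0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)

  const <- rank_frequency(
    tibble::tibble(item = letters[1:10], frequency = rep(5, 10)), "ordinal")
  expect_equal(power_law_fit(const)$slope, 0, tolerance = 1e-12)

  rounded <- rank_frequency(
    tibble::tibble(item = paste0("w", 1:50),
                   frequency = round(500 * (1:50)^-0.8)), "ordinal")
  expect_equal(power_law_fit(rounded)$slope, -0.8, tolerance = 0.05)
  expect_error(power_law_fit(exact, rank_range = c(1, 1)),
               class = "scskit_data_error")

  td <- suppressWarnings(tidy(fit))  # summary.lm warns on an exact fit
  expect_equal(td$estimate[2], fit$slope)
  expect_equal(glance(fit)$slope, fit$slope)
})

test_that("SCS tables round-trip through TSV", {
  t3 <- build_scs_table(toy, 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scs_table(t3, f)
  back <- read_scs_table(f)
  expect_equal(scs_n(back), 3L)
  expect_equal(scs_Q(back), 4L)
  expect_equal(scs_label(back), "toy")
  expect_equal(back$scs, t3$scs)
  expect_equal(back$R, t3$R)
  expect_equal(back$A, t3$A, tolerance = 1e-12)
})
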