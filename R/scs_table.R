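#' Pooled residue frequencies of a corpus
#'
#' Counts each of the 20 canonical residues over all sequences of the corpus
#' (non-canonical letters are ignored) and derives the per-position
#' probabilities P_a = count_a / total used in the expected-count model.
#'
#' @param corpus An `scs_corpus`.
#' @return A tibble of class `scs_residue_freqs` with columns `residue`,
#'   `count`, `prob` (one row per canonical residue, zero rows never dropped)
#'   and attribute `total`.
#' @examples
#' residue_frequencies(as_scs_corpus(c("ACAC", "A")))
#' @export
residue_frequencies <- function(corpus) {
  counts <- vapply(.AA, function(a) {
    sum(stringi::stri_count_fixed(corpus$sequence, a))
  }, numeric(1))
  total <- sum(counts)
  if (total == 0) .stop_data("corpus contains no canonical residues")
  out <- tibble(residue = .AA, count = as.integer(unname(counts)),
                prob = unname(counts) / total)
  structure(out, total = total,
            class = c("scs_residue_freqs", class(out)))
}

#' Expected SCS count under positional independence
#'
#' E = Q * P1 * P2 * ... * Pn, the count predicted from database-wide residue
#' frequencies assuming each position is drawn independently. This is a pure
#' product: no positional or dipeptide correction is applied.
#'
#' @param freqs An [residue_frequencies()] result.
#' @param Q Total number of length-n windows in the database.
#' @param scs Character vector of canonical SCS strings (equal lengths not
#'   required).
#' @return Numeric vector of expected counts.
#' @examples
#' f <- residue_frequencies(as_scs_corpus(c("ACDEF", "ACD")))
#' expected_count(f, 4, "ACD")
#' @export
expected_count <- function(freqs, Q, scs) {
  stopifnot(Q >= 0)
  if (length(scs) == 0) return(numeric())
  if (any(!.is_canonical(scs))) {
    .stop_data("non-canonical character in SCS: %s",
               scs[which(!.is_canonical(scs))[1]])
  }
  p <- setNames(freqs$prob, freqs$residue)
  out <- rep(as.numeric(Q), length(scs))
  maxlen <- max(stringi::stri_length(scs))
  for (j in seq_len(maxlen)) {
    cj <- stringi::stri_sub(scs, j, j)
    has <- nzchar(cj)
    out[has] <- out[has] * p[cj[has]]
  }
  unname(out)
}

#' Availability score
#'
#' A = (R - E)/E = R/E - 1: the relative excess of an SCS's real count over
#' its expected count. A is 0 when usage matches expectation, positive for
#' over-used SCSs, and exactly -1 for SCSs that do not occur at all
#' (non-existent). Undefined (NA) when E = 0, which only arises in corpora
#' missing a residue entirely.
#'
#' @param R Real count(s), non-negative.
#' @param E Expected count(s), non-negative.
#' @return Numeric vector; `NA` where `E == 0`.
#' @export
availability <- function(R, E) {
  if (any(R < 0, na.rm = TRUE) || any(E < 0, na.rm = TRUE)) {
    .stop_data("negative count passed to availability()")
  }
  ifelse(E > 0, R / E - 1, NA_real_)
}

#' Size of the SCS repertoire
#'
#' The number of distinct length-n words over the 20-letter amino-acid
#' alphabet: 20^n. 8,000 triplets, 160,000 quartets, 3,200,000 pentats.
#'
#' @param n SCS length, a positive integer (vectorized).
#' @return 20^n as a double (exact for all practical n).
#' @export
repertoire_size <- function(n) {
  if (any(n < 1) || any(n != trunc(n))) .stop_data("n must be a positive integer")
  20^n
}

#' Enumerate the full SCS repertoire
#'
#' All 20^n canonical SCS strings, in lexicographic order. Intended for
#' n <= 5; memory grows as 20^n.
#'
#' @param n SCS length.
#' @return Character vector of length `repertoire_size(n)`.
#' @export
enumerate_repertoire <- function(n) {
  stopifnot(length(n) == 1, n >= 1)
  if (n > 5) .stop_data("full repertoire enumeration is limited to n <= 5")
  grid <- expand.grid(rep(list(.AA), n), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

#' Build the SCS availability table of a corpus
#'
#' The central statistic: for a fixed SCS length n, counts every canonical
#' sliding window over all records (real counts R, total Q), computes
#' expected counts E = Q * P1...Pn from the same corpus's pooled residue
#' frequencies (self-referential background), and assigns availability
#' A = R/E - 1 to every SCS.
#'
#' @param corpus An `scs_corpus`.
#' @param n SCS length in 3..8.
#' @param repertoire `"observed"` (default) tabulates SCSs that occur at
#'   least once; `"full"` additionally materializes every unobserved SCS of
#'   the 20^n repertoire with R = 0, A = -1 (n <= 5 only).
#' @return A tibble of class `scs_table` with columns `scs`, `R`, `E`, `A`,
#'   sorted by `scs`, and attributes `n`, `Q`, `scs_label`, `residue_freqs`.
#' @examples
#' build_scs_table(as_scs_corpus(c("ACDEF", "ACD")), n = 3)
#' @export
build_scs_table <- function(corpus, n, repertoire = c("observed", "full")) {
  repertoire <- match.arg(repertoire)
  if (!(n %in% 3:8)) .stop_data("SCS length n must be in 3..8")
  win <- corpus_windows(corpus, n)
  if (nrow(win) == 0) {
    .stop_data("corpus yields no canonical windows at n = %d", n)
  }
  Q <- nrow(win)
  freqs <- residue_frequencies(corpus)
  tab <- win |> count(.data$scs, name = "R") |> arrange(.data$scs)
  if (repertoire == "full") {
    all_scs <- enumerate_repertoire(n)
    tab <- tibble(scs = all_scs) |>
      left_join(tab, by = "scs") |>
      mutate(R = ifelse(is.na(.data$R), 0L, .data$R))
  }
  tab$E <- expected_count(freqs, Q, tab$scs)
  tab$A <- availability(tab$R, tab$E)
  structure(tab, n = as.integer(n), Q = Q,
            scs_label = corpus_label(corpus), residue_freqs = freqs,
            class = c("scs_table", class(as_tibble(tab))))
}

#' SCS table metadata accessors
#' @param table An `scs_table`.
#' @return `scs_n()` the SCS length; `scs_Q()` the total window count;
#'   `scs_label()` the corpus label.
#' @export
scs_n <- function(table) attr(table, "n")

#' @rdname scs_n
#' @export
scs_Q <- function(table) attr(table, "Q")

#' @rdname scs_n
#' @export
scs_label <- function(table) attr(table, "scs_label") %||% "corpus"

#' Look up availability of arbitrary SCSs in a table
#'
#' SCSs absent from the table are treated as unobserved: R = 0 and A = -1
#' (or NA when the expected count is itself 0).
#'
#' @param table An `scs_table`.
#' @param scs Character vector of canonical SCSs of the table's length.
#' @return A tibble with columns `scs`, `R`, `E`, `A` in the order queried.
#' @export
scs_lookup <- function(table, scs) {
  n <- scs_n(table)
  if (any(stringi::stri_length(scs) != n)) {
    .stop_data("query SCS length differs from table n = %d", n)
  }
  out <- tibble(scs = scs) |>
    left_join(as_tibble(table)[, c("scs", "R", "E", "A")], by = "scs")
  miss <- is.na(out$R)
  if (any(miss)) {
    out$R[miss] <- 0L
    out$E[miss] <- expected_count(attr(table, "residue_freqs"),
                                  scs_Q(table), out$scs[miss])
    out$A[miss] <- availability(0, out$E[miss])
  }
  out
}

#' @export
print.scs_table <- function(x, ...) {
  cat(sprintf("# SCS table (n = %d) over '%s': Q = %s windows, %d distinct SCS\n",
              scs_n(x), scs_label(x), format(scs_Q(x), big.mark = ","),
              sum(x$R > 0)))
  NextMethod()
}

#' Write / read an SCS table as TSV
#'
#' Columns `scs`, `R`, `E`, `A` with a header line; undefined availability is
#' rendered as `.`. Table metadata (n, Q, corpus label) is carried in
#' `#`-prefixed comment lines so the table round-trips.
#'
#' @param table An `scs_table`.
#' @param path Output path.
#' @return `path` (write) or an `scs_table` (read).
#' @export
write_scs_table <- function(table, path) {
  writeLines(sprintf("# scs_table n=%d Q=%d label=%s",
                     scs_n(table), scs_Q(table), scs_label(table)), path)
  out <- as_tibble(table)[, c("scs", "R", "E", "A")]
  out$A <- ifelse(is.na(out$A), ".", format(out$A, digits = 15, trim = TRUE,
                                            scientific = FALSE))
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_scs_table
#' @export
read_scs_table <- function(path) {
  if (!file.exists(path)) .stop_data("SCS table file not found: %s", path)
  meta_line <- readLines(path, n = 1)
  meta <- stringi::stri_match_first_regex(
    meta_line, "^# scs_table n=(\\d+) Q=(\\d+) label=(.*)$")
  if (is.na(meta[1, 1])) .stop_data("'%s' is not an scs_table TSV", path)
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(
                           scs = "c", R = "i", E = "d", A = "c"))
  tab$A <- suppressWarnings(as.numeric(ifelse(tab$A == ".", NA, tab$A)))
  structure(as_tibble(tab), n = as.integer(meta[1, 2]),
            Q = as.integer(meta[1, 3]), scs_label = meta[1, 4],
            class = c("scs_table", class(as_tibble(tab))))
}

#' Availability rank-frequency view of an SCS table
#'
#' @param table An `scs_table`.
#' @param tie_policy Passed to [rank_frequency()].
#' @return A rank-frequency table of the real counts of observed SCSs.
#' @export
scs_rank_frequency <- function(table, tie_policy = c("competition", "ordinal")) {
  obs <- as_tibble(table) |> filter(.data$R > 0)
  rank_frequency(setNames(obs$R, obs$scs), tie_policy = tie_policy)
}

#' @export
autoplot.scs_table <- function(object, ...) {
  obs <- as_tibble(object) |> filter(!is.na(.data$A))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$A)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::labs(
      x = "availability A = R/E - 1", y = "SCS species",
      title = sprintf("Availability distribution (n = %d, %s)",
                      scs_n(object), scs_label(object)))
}
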