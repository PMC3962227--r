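#' Build the triplet idiom table of a corpus
#'
#' An idiom is a (core triplet, sub triplet, relation) pattern: a positional
#' association between two triplets within a +/-`max_relation` window.
#' Relation +1 means the sub triplet sits just next to the core triplet on
#' the right (C-terminal side). In the default non-overlapping `"gap"`
#' convention, |r| counts adjacent triplet slots: the sub window starts at
#' `core_start + 2 + r` for r > 0 and at `core_start - |r| - 2` for r < 0
#' (gap of |r| - 1 residues). The alternative `"offset"` convention reads r
#' as a plain residue offset (`core_start + r`), allowing overlapping
#' windows.
#'
#' For every idiom the table carries:
#' \describe{
#'   \item{relation_count}{occurrences of the idiom.}
#'   \item{denominator}{core occurrences with a fully valid (in-sequence,
#'     canonical) sub window at that relation — so Y <= 1 exactly.}
#'   \item{sub_count, X}{global count of the sub triplet and its frequency
#'     X = sub_count / Q among all Q triplet windows.}
#'   \item{Y}{relation frequency, relation_count / denominator.}
#'   \item{score}{evaluation score (Y - X)/X: how much more often the sub
#'     triplet occurs at that position than its unrestricted frequency
#'     predicts.}
#'   \item{rank}{1..N by score descending; ties broken by relation_count
#'     descending, then core, sub, relation.}
#' }
#'
#' @param corpus An `scs_corpus`.
#' @param max_relation Largest |relation| considered (default 10).
#' @param min_count Minimum relation_count for a record to be kept
#'   (default 1; guards rank inflation by singletons when raised).
#' @param mode Relation convention, `"gap"` (default) or `"offset"`.
#' @return A tibble of class `scs_idiom_table` with columns `core`, `sub`,
#'   `relation`, `relation_count`, `denominator`, `Y`, `sub_count`, `X`,
#'   `score`, `rank`, and attributes `total_triplets`, `scs_label`,
#'   `max_relation`, `mode`, `min_count`.
#' @examples
#' build_idiom_table(as_scs_corpus("MKVLAG"), max_relation = 2)
#' @export
build_idiom_table <- function(corpus, max_relation = 10, min_count = 1,
                              mode = c("gap", "offset")) {
  mode <- match.arg(mode)
  stopifnot(max_relation >= 1, min_count >= 0)
  win <- corpus_windows(corpus, 3)
  if (nrow(win) == 0) .stop_data("corpus yields no canonical triplet windows")
  Q <- nrow(win)
  sub_counts <- win |> count(.data$scs, name = "sub_count")

  relations <- c(seq_len(max_relation), -seq_len(max_relation))
  seq_lens <- setNames(stringi::stri_length(corpus$sequence),
                       corpus$identifier)
  # per-record lookup: window string by start position (NA if non-canonical)
  pairs <- vector("list", length(relations))
  names(pairs) <- as.character(relations)
  win_by_rec <- split(win[, c("start", "scs")], win$identifier)
  for (k in seq_along(relations)) {
    r <- relations[k]
    acc <- vector("list", length(win_by_rec))
    for (i in seq_along(win_by_rec)) {
      w <- win_by_rec[[i]]
      id <- names(win_by_rec)[i]
      L <- seq_lens[[id]]
      sub_start <- if (mode == "gap") {
        if (r > 0) w$start + 2L + r else w$start - abs(r) - 2L
      } else {
        w$start + r
      }
      inside <- sub_start >= 1L & sub_start <= L - 2L
      idx <- match(sub_start[inside], w$start)   # canonical sub windows only
      ok <- !is.na(idx)
      if (any(ok)) {
        acc[[i]] <- tibble(core = w$scs[inside][ok],
                           sub = w$scs[idx[ok]],
                           relation = r)
      }
    }
    pairs[[k]] <- bind_rows(acc)
  }
  pairs <- bind_rows(pairs)
  if (nrow(pairs) == 0) {
    tab <- tibble(core = character(), sub = character(),
                  relation = integer(), relation_count = integer(),
                  denominator = integer(), Y = numeric(),
                  sub_count = integer(), X = numeric(), score = numeric(),
                  rank = integer())
    return(structure(tab, total_triplets = Q,
                     scs_label = corpus_label(corpus),
                     max_relation = max_relation, mode = mode,
                     min_count = min_count,
                     class = c("scs_idiom_table", class(tab))))
  }
  tab <- pairs |>
    count(.data$core, .data$sub, .data$relation, name = "relation_count")
  denoms <- pairs |>
    count(.data$core, .data$relation, name = "denominator")
  tab <- tab |>
    left_join(denoms, by = c("core", "relation")) |>
    left_join(sub_counts, by = c(sub = "scs")) |>
    mutate(Y = .data$relation_count / .data$denominator,
           X = .data$sub_count / Q,
           # (Y - X)/X computed as rc*Q/(denom*sub_count) - 1: algebraically
           # identical, and bit-identical for mirror-image idioms, so exact
           # score ties resolve through the deterministic tie-break
           score = as.numeric(.data$relation_count) * Q /
             (as.numeric(.data$denominator) * .data$sub_count) - 1) |>
    filter(.data$relation_count >= min_count) |>
    arrange(desc(.data$score), desc(.data$relation_count),
            .data$core, .data$sub, .data$relation) |>
    mutate(rank = row_number()) |>
    select("core", "sub", "relation", "relation_count", "denominator",
           "Y", "sub_count", "X", "score", "rank")
  structure(tab, total_triplets = Q, scs_label = corpus_label(corpus),
            max_relation = max_relation, mode = mode, min_count = min_count,
            class = c("scs_idiom_table", class(as_tibble(tab))))
}

#' Idiom evaluation score
#'
#' (Y - X)/X: the excess of the relation frequency Y over the sub triplet's
#' unrestricted frequency X. 0 when the positional association is exactly
#' what the sub triplet's abundance predicts, -1 when the idiom never
#' occurs, large when the connection is idiomatic.
#'
#' @param X Sub triplet frequency (probability), > 0 for a defined score.
#' @param Y Relation frequency (probability).
#' @return `(Y - X)/X`; `NA` where `X == 0`.
#' @export
evaluation_score <- function(X, Y) {
  ifelse(X > 0, (Y - X) / X, NA_real_)
}

#' Query ranked idioms
#'
#' Without a triplet, returns the global top-`max_rank` idioms by evaluation
#' score. With a triplet, returns the idioms of rank <= `max_rank` that
#' contain it in the requested role.
#'
#' @param table An [build_idiom_table()] result.
#' @param triplet Optional canonical triplet to search for.
#' @param role Where the triplet may appear: `"either"` (default), `"core"`,
#'   or `"sub"`.
#' @param max_rank Rank cut-off (default 1000).
#' @param min_count Minimum relation_count (default 1).
#' @return The matching rows, rank ascending.
#' @export
query_idioms <- function(table, triplet = NULL,
                         role = c("either", "core", "sub"),
                         max_rank = 1000, min_count = 1) {
  role <- match.arg(role)
  out <- as_tibble(table) |>
    filter(.data$rank <= max_rank, .data$relation_count >= min_count)
  if (!is.null(triplet)) {
    if (stringi::stri_length(triplet) != 3 || !.is_canonical(triplet)) {
      .stop_data("'%s' is not a canonical triplet", triplet)
    }
    out <- switch(role,
      core = filter(out, .data$core == triplet),
      sub = filter(out, .data$sub == triplet),
      either = filter(out, .data$core == triplet | .data$sub == triplet))
  }
  arrange(out, .data$rank)
}

#' Annotate a sequence with idiomatic connections
#'
#' For every core triplet window of the query and every relation of the
#' table's convention, emits a hit when the (core, sub, relation) triple
#' exists in the table with rank at or under `rank_border`. Hits are ordered
#' by core position (N-terminal first).
#'
#' @param sequence Query residue string (length >= 6 for any possible hit).
#' @param table An `scs_idiom_table`.
#' @param rank_border Rank threshold; a list of 100 usually suffices, the
#'   default is 1000.
#' @return A tibble with columns `core_position`, `core`, `relation`,
#'   `sub_position`, `sub`, `rank`.
#' @export
annotate_sequence <- function(sequence, table, rank_border = 1000) {
  mode <- attr(table, "mode") %||% "gap"
  max_relation <- attr(table, "max_relation") %||% 10
  w <- sequence_windows(sequence, 3)
  empty <- tibble(core_position = integer(), core = character(),
                  relation = integer(), sub_position = integer(),
                  sub = character(), rank = integer())
  if (nrow(w) == 0) return(empty)
  L <- stringi::stri_length(sequence)
  cand <- tidyr::expand_grid(
    i = seq_len(nrow(w)),
    relation = c(seq_len(max_relation), -seq_len(max_relation)))
  cand$core_position <- w$start[cand$i]
  cand$core <- w$scs[cand$i]
  cand$sub_position <- ifelse(
    cand$relation > 0,
    if (mode == "gap") cand$core_position + 2L + cand$relation
    else cand$core_position + cand$relation,
    if (mode == "gap") cand$core_position - abs(cand$relation) - 2L
    else cand$core_position + cand$relation)
  cand <- cand[cand$sub_position >= 1 & cand$sub_position <= L - 2, ]
  idx <- match(cand$sub_position, w$start)
  cand <- cand[!is.na(idx), ]
  cand$sub <- w$scs[idx[!is.na(idx)]]
  hits <- cand |>
    left_join(as_tibble(table)[, c("core", "sub", "relation", "rank")],
              by = c("core", "sub", "relation")) |>
    filter(!is.na(.data$rank), .data$rank <= rank_border) |>
    select("core_position", "core", "relation", "sub_position", "sub",
           "rank") |>
    arrange(.data$core_position, .data$sub_position)
  if (nrow(hits) == 0) empty else hits
}

#' Design a sequence by greedy idiom chaining
#'
#' Grows a sequence from a seed triplet, one triplet per step, always
#' applying the highest-scoring eligible idiom at relation +1 (for rightward
#' steps the terminal triplet is the core and the chosen sub triplet is
#' appended; a leftward step mirrors this through relation -1, prepending
#' the chosen sub). Only adjacency (|relation| = 1) is used for chaining —
#' idioms at larger relations inform annotation but give no residue-by-
#' residue construction. Stops early when no eligible idiom remains.
#'
#' @param seed A canonical triplet.
#' @param table An `scs_idiom_table`.
#' @param steps Number of extension steps; each completed step lengthens the
#'   sequence by exactly 3 residues.
#' @param direction `"right"` (default), `"left"`, or `"both"` (alternating,
#'   starting rightward).
#' @param min_score Optional minimum evaluation score for an idiom to be
#'   eligible.
#' @return An object of class `scs_design`: list with `seed`, `sequence`,
#'   and a `steps` tibble (one row per completed step); supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' tab <- build_idiom_table(as_scs_corpus("MKVLAG"))
#' design_sequence("MKV", tab, steps = 1)
#' @export
design_sequence <- function(seed, table, steps,
                            direction = c("right", "left", "both"),
                            min_score = NULL) {
  direction <- match.arg(direction)
  if (stringi::stri_length(seed) != 3 || !.is_canonical(seed)) {
    .stop_data("seed must be a canonical triplet")
  }
  stopifnot(steps >= 0)
  tab <- as_tibble(table)
  sequence <- seed
  trace <- list()
  dirs <- if (direction == "both") {
    rep_len(c("right", "left"), steps)
  } else {
    rep(direction, length.out = steps)
  }
  for (s in seq_len(steps)) {
    d <- dirs[s]
    if (d == "right") {
      core <- stringi::stri_sub(sequence, -3)
      cand <- tab |> filter(.data$core == !!core, .data$relation == 1L)
    } else {
      core <- stringi::stri_sub(sequence, 1, 3)
      cand <- tab |> filter(.data$core == !!core, .data$relation == -1L)
    }
    if (!is.null(min_score)) cand <- filter(cand, .data$score >= min_score)
    if (nrow(cand) == 0) break
    pick <- cand |> arrange(.data$rank) |> head(1)
    sequence <- if (d == "right") paste0(sequence, pick$sub)
                else paste0(pick$sub, sequence)
    trace[[length(trace) + 1]] <- mutate(pick, step = s, direction = d)
  }
  steps_tbl <- if (length(trace) > 0) {
    bind_rows(trace) |>
      select("step", "direction", "core", "sub", "relation", "score", "rank")
  } else {
    tibble(step = integer(), direction = character(), core = character(),
           sub = character(), relation = integer(), score = numeric(),
           rank = integer())
  }
  structure(list(seed = seed, sequence = sequence, steps = steps_tbl,
                 table_label = attr(table, "scs_label") %||% "corpus"),
            class = "scs_design")
}

#' @export
print.scs_design <- function(x, ...) {
  cat(sprintf("Designed sequence from seed %s (%d step(s), table '%s'):\n  %s\n",
              x$seed, nrow(x$steps), x$table_label, x$sequence))
  invisible(x)
}

#' @export
tidy.scs_design <- function(x, ...) x$steps

#' @export
glance.scs_design <- function(x, ...) {
  tibble(seed = x$seed, steps = nrow(x$steps),
         length = stringi::stri_length(x$sequence),
         mean_score = if (nrow(x$steps) > 0) mean(x$steps$score) else NA_real_)
}

#' Write / read an idiom table as TSV
#'
#' Columns core, sub, relation, relation_count, denominator, Y, sub_count,
#' X, score, rank; metadata carried in a `#` comment line for round-trips.
#'
#' @param table An `scs_idiom_table`.
#' @param path Output path.
#' @return `path` (write) or an `scs_idiom_table` (read).
#' @export
write_idiom_table <- function(table, path) {
  writeLines(sprintf(
    "# scs_idiom_table Q=%d max_relation=%d mode=%s min_count=%d label=%s",
    attr(table, "total_triplets"), attr(table, "max_relation"),
    attr(table, "mode"), attr(table, "min_count"),
    attr(table, "scs_label") %||% "corpus"), path)
  readr::write_tsv(as_tibble(table), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_idiom_table
#' @export
read_idiom_table <- function(path) {
  if (!file.exists(path)) .stop_data("idiom table file not found: %s", path)
  meta <- stringi::stri_match_first_regex(
    readLines(path, n = 1),
    "^# scs_idiom_table Q=(\\d+) max_relation=(\\d+) mode=(\\S+) min_count=(\\d+) label=(.*)$")
  if (is.na(meta[1, 1])) .stop_data("'%s' is not an scs_idiom_table TSV", path)
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(
                           core = "c", sub = "c", relation = "i",
                           relation_count = "i", denominator = "i",
                           Y = "d", sub_count = "i", X = "d", score = "d",
                           rank = "i"))
  structure(as_tibble(tab),
            total_triplets = as.integer(meta[1, 2]),
            max_relation = as.integer(meta[1, 3]),
            mode = meta[1, 4], min_count = as.integer(meta[1, 5]),
            scs_label = meta[1, 6],
            class = c("scs_idiom_table", class(as_tibble(tab))))
}

#' @export
print.scs_idiom_table <- function(x, ...) {
  cat(sprintf(
    "# Idiom table over '%s': %d idiom(s), Q = %s triplets, relations +/-%d (%s mode)\n",
    attr(x, "scs_label") %||% "corpus", nrow(x),
    format(attr(x, "total_triplets"), big.mark = ","),
    attr(x, "max_relation"), attr(x, "mode")))
  NextMethod()
}
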