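#' Specify a synthetic protein corpus
#'
#' Describes a seeded random corpus with controlled statistical structure:
#' an i.i.d. residue background, planted enriched SCSs (overwritten at
#' Poisson-distributed positions, so the enrichment rate has a tractable
#' expectation), forbidden SCSs (guaranteed absent from every generated
#' sequence), and planted idioms (core and sub triplets placed at a fixed
#' relation). Plants overwrite residues rather than inserting, keeping
#' sequence lengths exact.
#'
#' @param num_sequences Number of sequences.
#' @param length_range `c(min, max)` uniform integer bounds, min >= 6.
#' @param residue_probs Named probability vector over the 20 canonical
#'   residues (default uniform 0.05 each); must sum to 1 within 1e-9. See
#'   [nr_aa_like_probs()] for a realistic unequal preset.
#' @param enriched Data frame with columns `scs`, `rate` (expected
#'   insertions per sequence), or NULL.
#' @param forbidden Character vector of SCSs that must not appear.
#' @param planted_idioms Data frame with columns `core`, `sub`, `relation`,
#'   `rate`, or NULL. Relations follow the `"gap"` convention of
#'   [build_idiom_table()].
#' @param seed Integer RNG seed; generation is fully deterministic given the
#'   spec.
#' @param label Corpus label.
#' @return A list of class `scs_corpus_spec`.
#' @export
corpus_spec <- function(num_sequences, length_range = c(80, 200),
                        residue_probs = NULL, enriched = NULL,
                        forbidden = character(), planted_idioms = NULL,
                        seed = 1L, label = "synthetic") {
  stopifnot(num_sequences >= 1, length(length_range) == 2,
            length_range[1] >= 6, length_range[1] <= length_range[2])
  if (is.null(residue_probs)) {
    residue_probs <- setNames(rep(1 / 20, 20), .AA)
  }
  if (!setequal(names(residue_probs), .AA)) {
    .stop_data("residue_probs must be named by the 20 canonical residues")
  }
  residue_probs <- residue_probs[.AA]
  if (abs(sum(residue_probs) - 1) > 1e-9) {
    .stop_data("residue_probs must sum to 1 (got %.12f)", sum(residue_probs))
  }
  enriched <- .check_plant(enriched, c("scs", "rate"))
  planted_idioms <- .check_plant(planted_idioms,
                                 c("core", "sub", "relation", "rate"))
  if (length(forbidden) > 0 && any(!.is_canonical(forbidden))) {
    .stop_data("forbidden SCSs must be canonical")
  }
  structure(list(num_sequences = as.integer(num_sequences),
                 length_range = as.integer(length_range),
                 residue_probs = residue_probs, enriched = enriched,
                 forbidden = forbidden, planted_idioms = planted_idioms,
                 seed = as.integer(seed), label = label),
            class = "scs_corpus_spec")
}

.check_plant <- function(x, cols) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(NULL)
  x <- as_tibble(x)
  if (!all(cols %in% names(x))) {
    .stop_data("plant specification needs columns: %s",
               paste(cols, collapse = ", "))
  }
  if (any(x$rate < 0)) .stop_data("plant rates must be non-negative")
  seqs <- unlist(x[intersect(c("scs", "core", "sub"), names(x))])
  if (any(!.is_canonical(seqs))) .stop_data("planted SCSs must be canonical")
  x[, cols]
}

#' Unequal residue background preset
#'
#' Residue probabilities shaped like a large protein database (common
#' residues such as L, A, S, G near or above 7%; rare ones such as W and C
#' near 1-2%), for generating more realistic synthetic corpora than the
#' uniform default.
#'
#' @return Named probability vector over the 20 canonical residues.
#' @export
nr_aa_like_probs <- function() {
  p <- c(A = 7.9, C = 1.9, D = 5.4, E = 6.1, F = 4.0, G = 7.3, H = 2.2,
         I = 5.5, K = 5.8, L = 9.1, M = 2.3, N = 4.3, P = 5.0, Q = 4.0,
         R = 5.1, S = 6.8, T = 5.6, V = 6.9, W = 1.3, Y = 3.5)
  p / sum(p)
}

#' Generate a synthetic corpus
#'
#' Draws sequences i.i.d. from the background, overwrites planted enriched
#' SCSs and idiom pairs at Poisson-placed, non-overlapping positions, then
#' rewrites any window matching a forbidden SCS until none remains
#' (post-generation assertion; errors if resampling exceeds the retry cap).
#' Byte-identical output for identical specs.
#'
#' @param spec An [corpus_spec()].
#' @param retry_cap Maximum forbidden-removal passes per sequence.
#' @return An `scs_corpus`.
#' @examples
#' generate_corpus(corpus_spec(3, c(10, 20), seed = 7))
#' @export
generate_corpus <- function(spec, retry_cap = 100) {
  stopifnot(inherits(spec, "scs_corpus_spec"))
  seqs <- withr::with_seed(spec$seed, .generate_sequences(spec, retry_cap))
  as_scs_corpus(
    tibble(identifier = sprintf("syn%05d", seq_len(spec$num_sequences)),
           description = "synthetic record", species = spec$label,
           sequence = seqs),
    label = spec$label)
}

.generate_sequences <- function(spec, retry_cap) {
  seqs <- character(spec$num_sequences)
  for (i in seq_len(spec$num_sequences)) {
    L <- spec$length_range[1] +
      sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1L) - 1L
    chars <- sample(.AA, L, replace = TRUE, prob = spec$residue_probs)
    occupied <- rep(FALSE, L)
    place <- function(word, start) {
      idx <- start:(start + stringi::stri_length(word) - 1)
      chars[idx] <<- stringi::stri_sub(word, seq_along(idx), length = 1)
      occupied[idx] <<- TRUE
    }
    free_at <- function(start, len) {
      start >= 1 && start + len - 1 <= L && !any(occupied[start:(start + len - 1)])
    }
    if (!is.null(spec$enriched)) {
      for (j in seq_len(nrow(spec$enriched))) {
        w <- spec$enriched$scs[j]
        wl <- stringi::stri_length(w)
        k <- rpois(1, spec$enriched$rate[j])
        placed <- 0; tries <- 0
        while (placed < k && tries < 50 * max(k, 1)) {
          s <- sample.int(L - wl + 1, 1)
          if (free_at(s, wl)) { place(w, s); placed <- placed + 1 }
          tries <- tries + 1
        }
      }
    }
    if (!is.null(spec$planted_idioms)) {
      for (j in seq_len(nrow(spec$planted_idioms))) {
        pi_ <- spec$planted_idioms[j, ]
        r <- pi_$relation
        # sub start relative to core start under the gap convention
        off <- if (r > 0) 2L + r else -abs(r) - 2L
        k <- rpois(1, pi_$rate)
        placed <- 0; tries <- 0
        while (placed < k && tries < 50 * max(k, 1)) {
          s <- sample.int(L - 2, 1)
          s2 <- s + off
          if (free_at(s, 3) && free_at(s2, 3)) {
            place(pi_$core, s); place(pi_$sub, s2)
            placed <- placed + 1
          }
          tries <- tries + 1
        }
      }
    }
    if (length(spec$forbidden) > 0) {
      pass <- 0
      repeat {
        seq_str <- paste0(chars, collapse = "")
        hit_any <- FALSE
        for (w in spec$forbidden) {
          loc <- stringi::stri_locate_all_fixed(seq_str, w,
                                                overlap = TRUE)[[1]]
          if (!is.na(loc[1, 1])) {
            hit_any <- TRUE
            for (s in loc[, 1]) {
              idx <- s:(s + stringi::stri_length(w) - 1)
              redo <- idx[!occupied[idx]]
              if (length(redo) == 0) {
                .stop_data(
                  "forbidden SCS '%s' overlaps a planted region entirely", w)
              }
              chars[redo] <- sample(.AA, length(redo), replace = TRUE,
                                    prob = spec$residue_probs)
            }
          }
        }
        if (!hit_any) break
        pass <- pass + 1
        if (pass > retry_cap) {
          .stop_data("could not remove forbidden SCSs within %d passes",
                     retry_cap)
        }
      }
    }
    seqs[i] <- paste0(chars, collapse = "")
  }
  seqs
}

#' Write / read a corpus spec as a flat key-value config
#'
#' Serializes every field of an [corpus_spec()] as `key = value` lines
#' (vectors comma-separated, plant tables as one `key` per row) so a
#' generated corpus can be reproduced from the config alone.
#'
#' @param spec An `scs_corpus_spec`.
#' @param path Output path.
#' @return `path` (write) or an `scs_corpus_spec` (read).
#' @export
write_corpus_spec <- function(spec, path) {
  lines <- c(
    sprintf("num_sequences = %d", spec$num_sequences),
    sprintf("length_range = %d,%d", spec$length_range[1],
            spec$length_range[2]),
    sprintf("residue_probs = %s",
            paste(sprintf("%s:%.10g", names(spec$residue_probs),
                          spec$residue_probs), collapse = ",")),
    sprintf("seed = %d", spec$seed),
    sprintf("label = %s", spec$label))
  if (!is.null(spec$enriched)) {
    lines <- c(lines, sprintf("enriched = %s,%.10g",
                              spec$enriched$scs, spec$enriched$rate))
  }
  if (length(spec$forbidden) > 0) {
    lines <- c(lines, sprintf("forbidden = %s", spec$forbidden))
  }
  if (!is.null(spec$planted_idioms)) {
    lines <- c(lines, sprintf("planted_idiom = %s,%s,%d,%.10g",
                              spec$planted_idioms$core,
                              spec$planted_idioms$sub,
                              spec$planted_idioms$relation,
                              spec$planted_idioms$rate))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_spec
#' @export
read_corpus_spec <- function(path) {
  if (!file.exists(path)) .stop_data("spec file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- stringi::stri_match_first_regex(lines, "^(\\S+)\\s*=\\s*(.*)$")
  keys <- kv[, 2]; vals <- trimws(kv[, 3])
  get1 <- function(k) vals[match(k, keys)]
  probs_raw <- stringi::stri_split_fixed(get1("residue_probs"), ",")[[1]]
  pm <- stringi::stri_match_first_regex(probs_raw, "^(\\w):(.*)$")
  probs <- setNames(as.numeric(pm[, 3]), pm[, 2])
  parse_rows <- function(key, cols, types) {
    rows <- vals[keys == key]
    if (length(rows) == 0) return(NULL)
    parts <- stringi::stri_split_fixed(rows, ",", simplify = TRUE)
    out <- as_tibble(setNames(as.data.frame(parts,
                                            stringsAsFactors = FALSE), cols))
    for (j in seq_along(cols)) {
      out[[j]] <- switch(types[j], c = out[[j]], i = as.integer(out[[j]]),
                         d = as.numeric(out[[j]]))
    }
    out
  }
  lr <- as.integer(stringi::stri_split_fixed(get1("length_range"), ",")[[1]])
  corpus_spec(
    num_sequences = as.integer(get1("num_sequences")),
    length_range = lr, residue_probs = probs,
    enriched = parse_rows("enriched", c("scs", "rate"), c("c", "d")),
    forbidden = vals[keys == "forbidden"],
    planted_idioms = parse_rows("planted_idiom",
                                c("core", "sub", "relation", "rate"),
                                c("c", "c", "i", "d")),
    seed = as.integer(get1("seed")), label = get1("label"))
}
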