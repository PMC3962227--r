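#' Assemble a protein corpus
#'
#' A corpus is a tibble with one row per protein record and columns
#' `identifier`, `description`, `species`, and `sequence`. It is the universe
#' over which all SCS counts are taken. Sequences are stored uppercase and may
#' contain, besides the 20 canonical residues, the tolerated non-canonical
#' letters `B J O U X Z` and `*`; those letters are retained in storage but
#' excluded at the window level (see [corpus_windows()]), which keeps input
#' fidelity while keeping the 20-letter SCS space exact.
#'
#' @param x A data frame with at least columns `identifier` and `sequence`
#'   (missing `description`/`species` columns are filled with `""`), or a
#'   character vector of sequences (identifiers are generated as `seq1`,
#'   `seq2`, ...).
#' @param label Corpus label (e.g. a species or database name), stored as the
#'   `scs_label` attribute and propagated into every table built from the
#'   corpus.
#' @return A tibble of class `scs_corpus`.
#' @examples
#' as_scs_corpus(c("ACDEF", "ACD"), label = "toy")
#' @export
as_scs_corpus <- function(x, label = "corpus") {
  if (is.character(x)) {
    x <- tibble(identifier = paste0("seq", seq_along(x)), sequence = x)
  }
  x <- as_tibble(x)
  if (!all(c("identifier", "sequence") %in% names(x))) {
    .stop_data("a corpus needs 'identifier' and 'sequence' columns")
  }
  if (!"description" %in% names(x)) x$description <- ""
  if (!"species" %in% names(x)) x$species <- ""
  x <- x[, c("identifier", "description", "species", "sequence")]
  x$sequence <- stringi::stri_trans_toupper(x$sequence)
  validate_corpus(x)
  structure(x, scs_label = label,
            class = c("scs_corpus", class(as_tibble(x))))
}

validate_corpus <- function(x) {
  if (nrow(x) == 0) .stop_data("no records in corpus")
  if (anyNA(x$identifier) || any(!nzchar(x$identifier))) {
    .stop_data("empty record identifier")
  }
  dup <- x$identifier[duplicated(x$identifier)]
  if (length(dup) > 0) {
    .stop_data("duplicate identifiers in corpus: %s",
               paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(x$sequence))) .stop_data("empty sequence in corpus")
  bad <- !stringi::stri_detect_regex(
    x$sequence, sprintf("^[%s]+$", paste0(c(LETTERS, "\\*"), collapse = "")))
  if (any(bad)) {
    .stop_data("sequence of record '%s' contains characters outside [A-Z*]",
               x$identifier[which(bad)[1]])
  }
  invisible(x)
}

#' Corpus label
#' @param corpus An `scs_corpus`.
#' @return The corpus label string.
#' @export
corpus_label <- function(corpus) attr(corpus, "scs_label") %||% "corpus"

#' Read a protein corpus from FASTA
#'
#' The header token before the first whitespace becomes the record identifier,
#' the remainder the description. Sequence lines are concatenated and
#' uppercased. Wrapped and unwrapped FASTA are both accepted.
#'
#' @param path Path to a FASTA file.
#' @param label Corpus label; defaults to the file name without extension.
#' @param species Species label applied to every record (FASTA header dialects
#'   vary, so species is supplied per file rather than parsed from headers).
#' @return An [as_scs_corpus()] tibble.
#' @export
read_fasta_corpus <- function(path, label = NULL,
                              species = label %||% "") {
  if (!file.exists(path)) .stop_data("FASTA file not found: %s", path)
  label <- label %||% tools::file_path_sans_ext(basename(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) .stop_data("cannot parse FASTA '%s': %s",
                                   path, conditionMessage(e)))
  if (length(set) == 0) .stop_data("no records in FASTA file '%s'", path)
  headers <- names(set)
  ids <- stringi::stri_extract_first_regex(headers, "^\\S+")
  descs <- stringi::stri_replace_first_regex(headers, "^\\S+\\s*", "")
  as_scs_corpus(
    tibble(identifier = ids, description = descs, species = species,
           sequence = as.character(set)),
    label = label)
}

#' Write a corpus to FASTA
#'
#' Round-trips exactly with [read_fasta_corpus()]: identifiers, descriptions
#' and sequences are preserved.
#'
#' @param corpus An `scs_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_corpus <- function(corpus, path) {
  headers <- ifelse(nzchar(corpus$description),
                    paste(corpus$identifier, corpus$description),
                    corpus$identifier)
  set <- Biostrings::BStringSet(setNames(corpus$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Canonical sliding windows of a sequence
#'
#' Every length-`n` window composed solely of the 20 canonical residues, with
#' its 1-based start position; windows containing any tolerated non-canonical
#' letter (`B J O U X Z *`) are omitted. A sequence of length `L` yields at
#' most `L - n + 1` windows, with equality iff all residues are canonical.
#'
#' @param sequence A residue string.
#' @param n Window (SCS) length.
#' @return A tibble with columns `start` (1-based) and `scs`.
#' @examples
#' sequence_windows("ACDEF", 3)
#' @export
sequence_windows <- function(sequence, n) {
  stopifnot(length(sequence) == 1, n >= 1)
  L <- stringi::stri_length(sequence)
  if (is.na(L) || L < n) {
    return(tibble(start = integer(), scs = character()))
  }
  starts <- seq_len(L - n + 1)
  scs <- stringi::stri_sub(sequence, from = starts, length = n)
  keep <- .is_canonical(scs, n)
  tibble(start = starts[keep], scs = scs[keep])
}

#' Canonical windows pooled over a corpus
#'
#' @param corpus An `scs_corpus`.
#' @param n Window length.
#' @return A tibble with columns `identifier`, `start`, `scs`.
#' @export
corpus_windows <- function(corpus, n) {
  per <- purrr::map(corpus$sequence, sequence_windows, n = n)
  sizes <- vapply(per, nrow, integer(1))
  out <- bind_rows(per)
  tibble(identifier = rep(corpus$identifier, sizes),
         start = out$start %||% integer(),
         scs = out$scs %||% character())
}

#' Tokenize natural-language text
#'
#' Lowercases the text and extracts maximal runs of letters/digits, keeping
#' internal apostrophes and hyphens (so "Zipf's" and "three-dimensional" are
#' single tokens); leading and trailing punctuation is stripped. Token order
#' is preserved. Idempotent on its own joined output.
#'
#' @param text A character scalar (or vector, concatenated in order).
#' @return A character vector of tokens; empty input yields `character(0)`.
#' @examples
#' tokenize_text("Zipf's law, a special case of power law.")
#' @export
tokenize_text <- function(text) {
  text <- paste(text, collapse = " ")
  if (!nzchar(text)) return(character())
  text <- stringi::stri_trans_tolower(text)
  # normalise typographic apostrophes/dashes so quoted passages tokenize
  # the same as plain ASCII text
  text <- stringi::stri_replace_all_regex(text, "[‘’ʼ]", "'")
  text <- stringi::stri_replace_all_regex(text, "[–—]", "-")
  tok <- stringi::stri_extract_all_regex(
    text, "[\\p{L}\\p{N}]+(?:['-][\\p{L}\\p{N}]+)*")[[1]]
  tok[!is.na(tok)]
}

#' Read and tokenize a UTF-8 text file
#' @param path Path to a plain-text file.
#' @return A character vector of tokens.
#' @export
read_text_tokens <- function(path) {
  if (!file.exists(path)) .stop_data("text file not found: %s", path)
  tokenize_text(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' @export
print.scs_corpus <- function(x, ...) {
  cat(sprintf("# SCS corpus '%s': %d record(s), %d residues\n",
              corpus_label(x), nrow(x),
              sum(stringi::stri_length(x$sequence))))
  NextMethod()
}
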