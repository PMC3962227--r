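#' Species-specific SCSs by availability distance
#'
#' Compares a focal species table against m comparison tables built at the
#' same SCS length. For each SCS the focal availability is multiplied by m
#' and the comparison availabilities subtracted:
#' `distance = m * A_focal - sum(A_other)` ("distance" means simple
#' subtraction; with two comparison species the focal score is doubled).
#' Positive distance means the SCS is more characteristic of the focal
#' species.
#'
#' SCSs unobserved in a species still participate with A = -1 — rarity in a
#' comparison species is exactly the signal sought. Entries whose
#' availability is undefined (E = 0) in any table are dropped, with the count
#' reported as the `dropped` attribute.
#'
#' @param focal The focal species' `scs_table`.
#' @param others A single `scs_table` or list of up to 10, all at the same n.
#' @param repertoire `"observed"` (default) scores the union of SCSs observed
#'   in at least one table — SCSs absent everywhere would have distance
#'   exactly 0 and are uninformative; `"full"` scores all 20^n (n <= 4).
#' @return A tibble of class `scs_distance`, sorted by distance descending,
#'   with columns `scs`, `distance`, `focal_score`, and one score column per
#'   comparison table (named after its corpus label); attributes `metric`,
#'   `n`, `dropped`.
#' @export
availability_distance <- function(focal, others,
                                  repertoire = c("observed", "full")) {
  .species_distance(focal, others, metric = "availability",
                    repertoire = match.arg(repertoire))
}

#' Species-specific SCSs by rank distance
#'
#' Each table's SCSs are ranked by availability descending (ordinal ranks,
#' lexicographic tie-break) and distances taken as
#' `distance = sum(rank_other) - m * rank_focal`, so positive distance again
#' means the SCS ranks better (more available) in the focal species.
#'
#' @inheritParams availability_distance
#' @return As [availability_distance()]; score columns hold ranks.
#' @export
rank_distance <- function(focal, others,
                          repertoire = c("observed", "full")) {
  .species_distance(focal, others, metric = "rank",
                    repertoire = match.arg(repertoire))
}

.species_distance <- function(focal, others, metric, repertoire) {
  if (inherits(others, "scs_table")) others <- list(others)
  m <- length(others)
  if (m < 1) .stop_data("at least one comparison table is required")
  if (m > 10) .stop_usage("at most 10 comparison tables are supported")
  tabs <- c(list(focal), others)
  ns <- vapply(tabs, scs_n, integer(1))
  if (length(unique(ns)) != 1) {
    .stop_data("all tables must share the same SCS length (got %s)",
               paste(ns, collapse = ", "))
  }
  n <- ns[1]
  universe <- if (repertoire == "full") {
    if (n > 4) .stop_data("full repertoire distances are limited to n <= 4")
    enumerate_repertoire(n)
  } else {
    sort(unique(unlist(lapply(tabs, function(t) t$scs[t$R > 0]))))
  }
  scores <- lapply(tabs, function(tab) {
    hit <- scs_lookup(tab, universe)
    if (metric == "availability") {
      hit$A
    } else {
      # ordinal rank by availability descending, lexicographic tie-break;
      # undefined availabilities keep NA and are dropped below
      r <- rep(NA_real_, length(universe))
      ok <- !is.na(hit$A)
      ord <- order(-hit$A[ok], universe[ok])
      r[ok][ord] <- seq_len(sum(ok))
      r
    }
  })
  focal_score <- scores[[1]]
  other_mat <- do.call(cbind, scores[-1])
  defined <- !is.na(focal_score) & rowSums(is.na(other_mat)) == 0
  dropped <- sum(!defined)
  if (dropped > 0) {
    message(sprintf("dropped %d SCS(s) with undefined availability", dropped))
  }
  dist <- if (metric == "availability") {
    m * focal_score - rowSums(other_mat)
  } else {
    rowSums(other_mat) - m * focal_score
  }
  labels <- make.unique(c(vapply(others, scs_label, character(1))))
  out <- tibble(scs = universe[defined], distance = dist[defined],
                focal_score = focal_score[defined])
  for (j in seq_len(m)) out[[labels[j]]] <- other_mat[defined, j]
  out <- out |> arrange(desc(.data$distance), .data$scs)
  structure(out, metric = metric, n = n, dropped = dropped,
            class = c("scs_distance", class(as_tibble(out))))
}

#' Top and bottom species-specific SCSs
#'
#' @param entries An [availability_distance()] / [rank_distance()] result.
#' @param t,b Numbers of top and bottom entries to keep (defaults 100 each);
#'   values exceeding the available entries return everything.
#' @return A list with elements `top` (distance descending) and `bottom`
#'   (distance ascending).
#' @export
top_bottom <- function(entries, t = 100, b = 100) {
  stopifnot(t >= 0, b >= 0)
  sorted <- as_tibble(entries) |> arrange(desc(.data$distance), .data$scs)
  list(top = head(sorted, t),
       bottom = head(arrange(sorted, .data$distance, .data$scs), b))
}

#' Find proteins containing an SCS
#'
#' Plain substring search (overlaps included) over every record of a corpus;
#' one row per matching protein regardless of occurrence count.
#'
#' @param corpus An `scs_corpus`.
#' @param scs Canonical query SCS of any length >= 1.
#' @return A tibble with columns `identifier`, `description`, `n_matches`,
#'   and `positions` (list-column of 1-based match start positions).
#' @examples
#' find_proteins(as_scs_corpus(c(a = "KENTAKENTA"), label = "toy"), "KENTA")
#' @export
find_proteins <- function(corpus, scs) {
  stopifnot(length(scs) == 1)
  if (!nzchar(scs) || !.is_canonical(scs)) {
    .stop_data("query SCS must be a non-empty canonical residue string")
  }
  loc <- stringi::stri_locate_all_fixed(corpus$sequence, scs, overlap = TRUE)
  pos <- purrr::map(loc, function(mat) {
    p <- mat[, 1]
    as.integer(p[!is.na(p)])
  })
  hit <- lengths(pos) > 0
  tibble(identifier = corpus$identifier[hit],
         description = corpus$description[hit],
         n_matches = lengths(pos)[hit],
         positions = pos[hit])
}

#' Write a species-distance table as TSV
#'
#' Mirrors the comparison layout: scs, distance, focal score, one column per
#' comparison species.
#' @param entries An `scs_distance` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(entries, path) {
  readr::write_tsv(as_tibble(entries), path, progress = FALSE)
  invisible(path)
}

#' Write protein search hits as TSV
#' @param hits A [find_proteins()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- as_tibble(hits)
  out$positions <- vapply(out$positions, paste, character(1), collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
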