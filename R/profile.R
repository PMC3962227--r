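#' Availability profile of a query sequence
#'
#' Scores every canonical window of the query against pre-built SCS tables
#' and assigns the availability to the window's center residue (index
#' `start + floor((n-1)/2)`; the second residue for n = 4). Terminal residues
#' do not form complete SCSs and therefore carry no score. Each series is
#' rescaled so that its highest raw availability is 100% and other scores are
#' adjusted proportionally (negative values can fall below 0%).
#'
#' @param sequence Query residue string; windows with non-canonical letters
#'   are skipped. SCSs absent from a table are treated as unobserved
#'   (R = 0, A = -1), not as errors.
#' @param tables A named list of `scs_table`s keyed by their n (e.g. from
#'   [build_scs_table()] at n = 3, 4, 5), or a single table.
#' @param scaling `"per_series"` (default) rescales each n independently to
#'   its own maximum; `"global"` uses one maximum across all series.
#' @return A tibble of class `scs_profile` with columns `n`, `position`
#'   (1-based center residue), `start`, `scs`, `raw`, `relative`, and
#'   attributes `sequence` and `scaling`. Series whose maximum raw score is
#'   not positive get `relative = NA` with a warning.
#' @examples
#' t3 <- build_scs_table(as_scs_corpus(c("ACDEFG", "ACDKLM")), 3)
#' availability_profile("ACDEF", list(t3))
#' @export
availability_profile <- function(sequence, tables,
                                 scaling = c("per_series", "global")) {
  scaling <- match.arg(scaling)
  if (inherits(tables, "scs_table")) tables <- list(tables)
  ns <- vapply(tables, scs_n, integer(1))
  if (anyDuplicated(ns)) .stop_data("multiple tables share the same n")
  series <- purrr::map2(tables, ns, function(tab, n) {
    win <- sequence_windows(sequence, n)
    if (nrow(win) == 0) {
      return(tibble(n = integer(), position = integer(), start = integer(),
                    scs = character(), raw = numeric()))
    }
    hits <- scs_lookup(tab, win$scs)
    raw <- hits$A
    # unobserved SCSs score -1 even when the background probability model
    # gives them E = 0 (a residue absent from the table's corpus)
    raw[is.na(raw) & hits$R == 0] <- -1
    tibble(n = as.integer(n),
           position = win$start + (n - 1L) %/% 2L,
           start = win$start, scs = win$scs, raw = raw)
  })
  out <- bind_rows(series)
  if (nrow(out) > 0) {
    out <- out |>
      group_by(.data$n) |>
      mutate(relative = {
        mx <- max(.data$raw, na.rm = TRUE)
        if (!is.finite(mx) || mx <= 0) {
          warn(sprintf(
            "series n = %d has no positive availability; relative scores undefined",
            .data$n[1]))
          rep(NA_real_, length(.data$raw))
        } else 100 * .data$raw / mx
      }) |>
      ungroup()
    if (scaling == "global") {
      mx <- suppressWarnings(max(out$raw, na.rm = TRUE))
      out$relative <- if (is.finite(mx) && mx > 0) 100 * out$raw / mx
                      else NA_real_
    }
  } else {
    out$relative <- numeric()
  }
  structure(out, sequence = sequence, scaling = scaling,
            class = c("scs_profile", class(as_tibble(out))))
}

#' Per-residue wide table of an availability profile
#'
#' One row per residue of the query with raw and relative availability
#' columns per SCS length (`raw_3`, `rel_3`, ...); positions without a score
#' (chain ends, non-canonical windows) are `NA`, rendered as `.` by
#' [write_profile_tsv()]. Spreadsheet-friendly.
#'
#' @param profile An [availability_profile()] result.
#' @return A tibble with columns `position`, `residue`, then `raw_n`/`rel_n`
#'   pairs for each n in the profile.
#' @export
profile_table <- function(profile) {
  sequence <- attr(profile, "sequence")
  L <- stringi::stri_length(sequence)
  base <- tibble(position = seq_len(L),
                 residue = stringi::stri_sub(sequence, seq_len(L), length = 1))
  ns <- sort(unique(profile$n))
  if (length(ns) == 0) ns <- integer()
  for (nn in ns) {
    ser <- as_tibble(profile) |>
      filter(.data$n == nn) |>
      select("position", "raw", "relative")
    names(ser) <- c("position", paste0("raw_", nn), paste0("rel_", nn))
    base <- left_join(base, ser, by = "position")
  }
  base
}

#' Write an availability profile as TSV
#' @param profile An `scs_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(profile_table(profile), path, na = ".", progress = FALSE)
  invisible(path)
}

#' Availability plot
#'
#' Line plot of relative availability along the query, triplets in red,
#' quartets in blue, pentats in green.
#'
#' @param object An `scs_profile`.
#' @param value `"relative"` (default) or `"raw"`.
#' @param ... Unused.
#' @export
autoplot.scs_profile <- function(object, value = c("relative", "raw"), ...) {
  value <- match.arg(value)
  dat <- as_tibble(object)
  dat$series <- factor(dat$n)
  pal <- c(`3` = "red", `4` = "blue", `5` = "green")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position,
                                    y = .data[[value]],
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = pal, name = "SCS length") +
    ggplot2::labs(x = "residue position",
                  y = if (value == "relative") "relative availability (%)"
                      else "availability A",
                  title = "Availability plot")
}
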