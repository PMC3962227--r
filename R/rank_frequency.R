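#' Count tokens or SCSs
#'
#' @param items Character vector of observed items (words or SCSs), one entry
#'   per occurrence.
#' @return A tibble with columns `item`, `frequency` sorted by decreasing
#'   frequency then item.
#' @export
count_items <- function(items) {
  if (length(items) == 0) .stop_data("no items to count")
  tibble(item = items) |>
    count(.data$item, name = "frequency") |>
    arrange(desc(.data$frequency), .data$item)
}

#' Rank-frequency table
#'
#' Associates every item with its frequency and rank, the surface on which
#' Zipf's law (frequency inversely proportional to rank) is examined.
#' Under the default competition policy, items with equal frequency share the
#' minimal rank of their block (1, 2, 2, 4, ...), matching how tied words are
#' listed in word-count tables; the ordinal policy assigns distinct ranks
#' 1..N with a lexicographic tie-break, which is what a Zipf plot needs.
#'
#' @param counts A named numeric vector (names = items, values = counts), or
#'   a data frame with columns `item` and `frequency`.
#' @param tie_policy `"competition"` (default) or `"ordinal"`.
#' @return A tibble of class `scs_rankfreq` with columns `item`, `frequency`,
#'   `rank`, sorted by frequency descending (lexicographic within ties).
#' @examples
#' rank_frequency(c(x = 5, y = 3, z = 3, w = 1))
#' @export
rank_frequency <- function(counts, tie_policy = c("competition", "ordinal")) {
  tie_policy <- match.arg(tie_policy)
  if (is.data.frame(counts)) {
    stopifnot(all(c("item", "frequency") %in% names(counts)))
    tab <- as_tibble(counts)[, c("item", "frequency")]
  } else {
    if (length(counts) == 0) .stop_data("empty counts")
    tab <- tibble(item = names(counts), frequency = as.numeric(counts))
  }
  if (nrow(tab) == 0) .stop_data("empty counts")
  if (any(tab$frequency <= 0)) .stop_data("frequencies must be positive")
  tab <- tab |> arrange(desc(.data$frequency), .data$item)
  tab$rank <- if (tie_policy == "competition") {
    min_rank(desc(tab$frequency))
  } else {
    seq_len(nrow(tab))
  }
  structure(tab, tie_policy = tie_policy,
            class = c("scs_rankfreq", class(as_tibble(tab))))
}

#' Fit a power law to a rank-frequency table
#'
#' Ordinary least squares of log10(frequency) on log10(rank), optionally
#' restricted to an inclusive rank range. A slope near -1 is the Zipf
#' regime. The fit is descriptive (no heavy-tail MLE): it mirrors the
#' straight-line reading of a log-log rank-frequency plot.
#'
#' @param table An [rank_frequency()] table.
#' @param rank_range Inclusive `c(lo, hi)` interval of ranks to fit, or
#'   `NULL` for all.
#' @return An object of class `scs_powerlaw` with elements `slope`,
#'   `intercept`, `r_squared`, `n_points`, `rank_range`, and the underlying
#'   `lm` fit; supports [generics::tidy()] and [generics::glance()].
#' @examples
#' rf <- rank_frequency(setNames(round(1000 / 1:100), paste0("w", 1:100)))
#' power_law_fit(rf)
#' @export
power_law_fit <- function(table, rank_range = NULL) {
  dat <- as_tibble(table)
  if (!is.null(rank_range)) {
    stopifnot(length(rank_range) == 2)
    dat <- dat |> filter(.data$rank >= rank_range[1],
                         .data$rank <= rank_range[2])
  }
  if (length(unique(dat$rank)) < 2) {
    .stop_data("power-law fit needs at least 2 distinct ranks in range")
  }
  fit <- lm(log10(frequency) ~ log10(rank), data = dat)
  y <- log10(dat$frequency)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_points = nrow(dat),
         rank_range = rank_range %||% range(dat$rank), fit = fit),
    class = "scs_powerlaw")
}

#' @export
print.scs_powerlaw <- function(x, ...) {
  cat(sprintf(
    "Power-law fit over ranks %d..%d (%d points):\n  log10(f) = %.4f %+.4f * log10(r)   R^2 = %.4f\n",
    x$rank_range[1], x$rank_range[2], x$n_points,
    x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
tidy.scs_powerlaw <- function(x, ...) {
  # summary.lm warns on numerically exact fits; the coefficients are fine
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("intercept", "log10(rank)"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @export
glance.scs_powerlaw <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n_points = x$n_points)
}

#' Rank-frequency (Zipf) plot
#' @param object An `scs_rankfreq` table.
#' @param ... Unused.
#' @export
autoplot.scs_rankfreq <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$frequency)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "frequency",
                  title = "Rank-frequency distribution")
}

#' Write a rank-frequency table as TSV
#' @param table An `scs_rankfreq` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_frequency <- function(table, path) {
  readr::write_tsv(as_tibble(table)[, c("item", "frequency", "rank")], path,
                   progress = FALSE)
  invisible(path)
}
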