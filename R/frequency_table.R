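#' Frequency table of confidence ratings
#'
#' Per-group counts of signal and noise items at each level of an ordinal
#' confidence scale, ordered from the most-"noise" label (e.g. "very
#' confident new") to the most-"signal" label (e.g. "very confident old").
#' This is the tabulated form in which confidence-rating recognition data are
#' usually reported.
#'
#' @param signal_counts non-negative integer counts of signal (old) items at
#'   each level, length `K >= 2`, summing to at least 1.
#' @param noise_counts non-negative integer counts of noise (new) items at
#'   each level, same length.
#' @param levels optional character labels for the K levels; defaults to
#'   `"level 1" ... "level K"`.
#' @param group optional group label.
#'
#' @return An object of class `"frequency_table"`.
#' @seealso [expand_frequency_table()], [tabulate_ratings()], [recognition_tables()]
#' @export
#' @examples
#' ft <- frequency_table(
#'   signal_counts = c(100, 150, 300, 100, 200, 150),
#'   noise_counts  = c(300, 200, 100, 150, 150, 100),
#'   group = "alcohol"
#' )
#' auc(compute_roc(expand_frequency_table(ft)))
frequency_table <- function(signal_counts, noise_counts, levels = NULL,
                            group = NULL) {
  k <- length(signal_counts)
  if (k < 2L || length(noise_counts) != k) {
    stop("need K >= 2 levels with matching signal and noise counts")
  }
  if (any(signal_counts < 0) || any(noise_counts < 0) ||
    any(signal_counts != round(signal_counts)) ||
    any(noise_counts != round(noise_counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(signal_counts) < 1 || sum(noise_counts) < 1) {
    stop("degenerate table: each class needs at least one observation")
  }
  if (is.null(levels)) levels <- paste("level", seq_len(k))
  if (length(levels) != k) stop("`levels` must have length K")
  structure(
    list(
      group = group, levels = as.character(levels),
      signal_counts = as.integer(signal_counts),
      noise_counts = as.integer(noise_counts)
    ),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf(
    "frequency table%s: %d levels, %d signal / %d noise items\n",
    if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
    length(x$levels), sum(x$signal_counts), sum(x$noise_counts)
  ))
  print(data.frame(
    level = x$levels, signal = x$signal_counts, noise = x$noise_counts
  ), row.names = FALSE)
  invisible(x)
}

#' Expand a frequency table to observation-level rating data
#'
#' Each count becomes that many observations whose score is the level index
#' (1 = most-noise label, K = most-signal label). Totals are preserved
#' exactly, so re-tabulating the expansion reproduces the table.
#'
#' @param table a [frequency_table()].
#' @return A [rating_data()] object with
#'   `sum(signal_counts) + sum(noise_counts)` rows.
#' @export
expand_frequency_table <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  k <- length(table$levels)
  rating_data(
    labels = c(
      rep(1L, sum(table$signal_counts)),
      rep(0L, sum(table$noise_counts))
    ),
    scores = c(
      rep(seq_len(k), table$signal_counts),
      rep(seq_len(k), table$noise_counts)
    ),
    group = table$group
  )
}

#' Tabulate rating data back into a frequency table
#'
#' Inverse of [expand_frequency_table()] for ordinal data: counts the
#' (label, level) pairs.
#'
#' @param data a [rating_data()] object with integer scores in `1..k_levels`.
#' @param k_levels number of scale levels; defaults to `max(data$score)`.
#' @param levels optional level labels passed to [frequency_table()].
#' @return A [frequency_table()].
#' @export
tabulate_ratings <- function(data, k_levels = NULL, levels = NULL) {
  validate_rating_data(data)
  if (any(data$score != round(data$score)) || any(data$score < 1)) {
    stop("scores must be ordinal (integers >= 1) to tabulate")
  }
  if (is.null(k_levels)) k_levels <- max(data$score)
  s <- .split_scores(data)
  frequency_table(
    signal_counts = tabulate(s$signal, nbins = k_levels),
    noise_counts = tabulate(s$noise, nbins = k_levels),
    levels = levels, group = attr(data, "group")
  )
}

#' Read/write frequency tables as CSV
#'
#' CSV dialect: columns `group`, `level_index`, `signal_count`,
#' `noise_count`, one row per group x level. `read_frequency_table()` returns
#' a named list of `frequency_table` objects, one per group (a single table
#' if the file holds one group).
#'
#' @param path file path.
#' @return `read_frequency_table()`: a named list of [frequency_table()]
#'   objects (or one table when the file contains a single group).
#' @export
read_frequency_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "level_index", "signal_count", "noise_count")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$group), function(g) {
    g <- g[order(g$level_index), , drop = FALSE]
    frequency_table(g$signal_count, g$noise_count, group = g$group[1])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @param tables a `frequency_table` or list of them, to write.
#' @rdname read_frequency_table
#' @export
write_frequency_table <- function(tables, path) {
  if (inherits(tables, "frequency_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(
      group = if (is.null(tb$group)) "group1" else tb$group,
      level_index = seq_along(tb$levels),
      signal_count = tb$signal_counts,
      noise_count = tb$noise_counts
    )
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
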