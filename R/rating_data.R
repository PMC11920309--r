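#' Observation-level rating data
#'
#' Constructs the observation-level container used throughout the package:
#' one row per rated item, with a binary class label (1 = signal, e.g. an old
#' item; 0 = noise, e.g. a new item) and a score. Scores are either ordinal
#' confidence ratings (integers `1..K`, higher = more confident the item is
#' signal) or continuous values on the latent scale. Higher scores are always
#' treated as more signal-like; the package never flips the direction
#' automatically, so sign-reversed effects surface as such.
#'
#' @param labels integer vector of 0/1 class labels (1 = signal, 0 = noise).
#' @param scores numeric vector of ratings, same length as `labels`. Finite.
#' @param participant optional participant identifier per observation.
#' @param pairing optional identifier linking paired observations across two
#'   conditions of a within-subject design; must induce a bijection between
#'   the two conditions when used in paired comparisons.
#' @param group optional group label attached as an attribute.
#'
#' @return A `data.frame` of class `"rating_data"` with columns `label`,
#'   `score`, and optionally `participant` and `pairing`.
#' @seealso [compute_roc()], [auc()], [auc_ci()], [generate_ratings()]
#' @export
#' @examples
#' rating_data(labels = c(1, 1, 0, 0), scores = c(6, 4, 3, 1))
rating_data <- function(labels, scores, participant = NULL, pairing = NULL,
                        group = NULL) {
  labels <- as.integer(labels)
  scores <- as.numeric(scores)
  df <- data.frame(label = labels, score = scores)
  if (!is.null(participant)) df$participant <- participant
  if (!is.null(pairing)) df$pairing <- pairing
  attr(df, "group") <- group
  class(df) <- c("rating_data", "data.frame")
  validate_rating_data(df)
  df
}

#' Validate a rating_data object
#'
#' Checks the container invariants: both classes present, finite scores,
#' 0/1 labels. Called by the constructor and by every estimator that accepts
#' externally built data.
#'
#' @param data a `rating_data` object (or a data.frame with `label`/`score`).
#' @return `data`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_rating_data <- function(data) {
  stopifnot(is.data.frame(data), all(c("label", "score") %in% names(data)))
  if (!all(data$label %in% c(0L, 1L))) {
    stop("labels must be 0 (noise) or 1 (signal)")
  }
  if (!all(is.finite(data$score))) stop("scores must be finite")
  if (sum(data$label == 1L) < 1L || sum(data$label == 0L) < 1L) {
    stop("degenerate data: need at least one observation of each class")
  }
  invisible(data)
}

#' @export
print.rating_data <- function(x, ...) {
  m <- sum(x$label == 1L)
  n <- sum(x$label == 0L)
  grp <- attr(x, "group")
  cat(sprintf(
    "rating data%s: %d signal + %d noise observations\n",
    if (!is.null(grp)) paste0(" [", grp, "]") else "", m, n
  ))
  if (all(x$score == round(x$score))) {
    cat(sprintf(
      "ordinal scores in %d..%d\n", min(x$score), max(x$score)
    ))
  } else {
    cat("continuous scores\n")
  }
  invisible(x)
}

#' Read/write rating data as CSV
#'
#' The CSV dialect has columns `group`, `participant`, `label`, `rating`.
#' `read_rating_data()` returns a single `rating_data` object (use `group=`
#' to select one group from a multi-group file); `write_rating_data()` writes
#' one.
#'
#' @param path file path.
#' @param group optional group label to filter on when reading.
#' @return `read_rating_data()`: a `rating_data` object.
#' @export
read_rating_data <- function(path, group = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "participant", "label", "rating")
  if (!all(need %in% names(df))) {
    stop("expected columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows (check `group`)")
  rating_data(df$label, df$rating,
    participant = df$participant,
    group = if (!is.null(group)) group else unique(df$group)[1]
  )
}

#' @param data a `rating_data` object to write.
#' @rdname read_rating_data
#' @export
write_rating_data <- function(data, path) {
  validate_rating_data(data)
  grp <- attr(data, "group")
  out <- data.frame(
    group = if (is.null(grp)) "group1" else grp,
    participant = if ("participant" %in% names(data)) data$participant else NA,
    label = data$label,
    rating = data$score
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# internal: split scores by class
.split_scores <- function(data) {
  list(
    signal = data$score[data$label == 1L],
    noise = data$score[data$label == 0L]
  )
}
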