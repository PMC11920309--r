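#' Empirical ROC curve from rating data
#'
#' Builds the ROC curve by cumulative thresholding: for each cutoff `c`
#' (taken over the observed score values from most conservative, i.e.
#' highest, to most liberal), the true-positive rate is
#' `TPR = P(score >= c | signal)` and the false-positive rate is
#' `FPR = P(score >= c | noise)`. Anchor points (0, 0) and (1, 1) are always
#' included, so a curve over K distinct scores has K + 2 rows (the row at the
#' lowest cutoff coincides with the (1, 1) anchor).
#'
#' Higher score always means more signal-like; no automatic direction
#' flipping is performed.
#'
#' @param data a [rating_data()] object.
#' @return A `data.frame` of class `"roc_points"` with columns `threshold`
#'   (`Inf` for the (0,0) anchor, `-Inf` for the final (1,1) anchor), `fpr`
#'   and `tpr`, ordered from conservative to liberal (both rates
#'   non-decreasing). If all scores are identical the curve consists of the
#'   anchors only and carries the attribute
#'   `no_discrimination = TRUE`.
#' @seealso [auc()], [partial_auc()], [write_roc_points()]
#' @export
#' @examples
#' d <- rating_data(c(1, 1, 1, 0, 0, 0), c(6, 5, 2, 4, 2, 1))
#' compute_roc(d)
compute_roc <- function(data) {
  validate_rating_data(data)
  s <- .split_scores(data)
  cuts <- sort(unique(data$score), decreasing = TRUE)
  no_info <- length(cuts) == 1L
  if (no_info) {
    # single observed value: every cumulative cutoff is (1,1); keep anchors
    pts <- data.frame(
      threshold = c(Inf, cuts, -Inf), fpr = c(0, 1, 1), tpr = c(0, 1, 1)
    )
  } else {
    tpr <- vapply(cuts, function(ct) mean(s$signal >= ct), numeric(1))
    fpr <- vapply(cuts, function(ct) mean(s$noise >= ct), numeric(1))
    pts <- data.frame(
      threshold = c(Inf, cuts, -Inf),
      fpr = c(0, fpr, 1),
      tpr = c(0, tpr, 1)
    )
  }
  attr(pts, "group") <- attr(data, "group")
  attr(pts, "no_discrimination") <- no_info
  class(pts) <- c("roc_points", "data.frame")
  pts
}

#' Area under an ROC curve
#'
#' `auc()` is a generic. For an ROC curve it is the trapezoidal area under
#' the (FPR, TPR) polyline; for rating data it is the tie-corrected
#' two-sample rank statistic
#' `P(S_signal > S_noise) + 0.5 * P(S_signal = S_noise)`. The two are
#' mathematically identical for cumulative-threshold curves; the rating-data
#' method shares its code path with the DeLong components so the two module
#' surfaces agree bit-for-bit.
#'
#' @param x an object: `roc_points` or `rating_data`.
#' @param ... unused.
#' @return The AUC, a number in `[0, 1]`.
#' @export
auc <- function(x, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.roc_points <- function(x, ...) {
  .trapezoid(x$fpr, x$tpr)
}

#' @rdname auc
#' @export
auc.rating_data <- function(x, ...) {
  validate_rating_data(x)
  s <- .split_scores(x)
  .auc_rank(s$signal, s$noise)
}

#' @rdname auc
#' @export
auc.frequency_table <- function(x, ...) {
  auc(expand_frequency_table(x))
}

#' Partial area under an ROC curve
#'
#' Trapezoidal area of the curve restricted to an FPR interval, with linear
#' interpolation of the TPR at interval boundaries that fall between observed
#' points. Reported raw (not standardized), so the partial area of the chance
#' diagonal over `[0, t]` is `t^2 / 2`.
#'
#' @param curve a `roc_points` object (or a `rating_data` object, which is
#'   converted via [compute_roc()]).
#' @param fpr_lo,fpr_hi the FPR range, `0 <= fpr_lo < fpr_hi <= 1`.
#' @return The partial AUC (raw area).
#' @export
#' @examples
#' d <- rating_data(c(1, 1, 1, 0, 0, 0), c(6, 5, 2, 4, 2, 1))
#' partial_auc(compute_roc(d), 0, 0.5)
partial_auc <- function(curve, fpr_lo, fpr_hi) {
  if (inherits(curve, "rating_data")) curve <- compute_roc(curve)
  stopifnot(inherits(curve, "roc_points"))
  .check_fpr_range(c(fpr_lo, fpr_hi))
  .pauc_xy(curve$fpr, curve$tpr, fpr_lo, fpr_hi)
}

.check_fpr_range <- function(r) {
  if (length(r) != 2L || !all(is.finite(r)) || r[1] < 0 || r[2] > 1 ||
    r[1] >= r[2]) {
    stop("fpr range must satisfy 0 <= lo < hi <= 1")
  }
  invisible(r)
}

#' Export ROC coordinates to CSV
#'
#' Writes the `threshold, fpr, tpr` coordinates of a curve, the hook for
#' plotting in external tools.
#'
#' @param curve a `roc_points` object.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_roc_points <- function(curve, path) {
  stopifnot(inherits(curve, "roc_points"))
  write.csv(
    data.frame(
      threshold = curve$threshold, fpr = curve$fpr, tpr = curve$tpr
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @export
print.roc_points <- function(x, ...) {
  grp <- attr(x, "group")
  cat(sprintf(
    "ROC curve%s: %d points (incl. anchors), AUC = %.2f\n",
    if (!is.null(grp)) paste0(" [", grp, "]") else "",
    nrow(x), auc(x)
  ))
  if (isTRUE(attr(x, "no_discrimination"))) {
    cat("note: no discrimination information (all scores identical)\n")
  }
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# ---- internal numerics ----------------------------------------------------

# trapezoid over an ascending polyline
.trapezoid <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# area of the polyline restricted to [lo, hi]; vertical segments (dx = 0)
# contribute nothing, which makes pAUC additive across subranges
.pauc_xy <- function(fpr, tpr, lo, hi) {
  x1 <- head(fpr, -1L)
  x2 <- tail(fpr, -1L)
  y1 <- head(tpr, -1L)
  y2 <- tail(tpr, -1L)
  a <- pmax(x1, lo)
  b <- pmin(x2, hi)
  w <- b - a
  keep <- w > 0
  if (!any(keep)) {
    return(0)
  }
  slope <- ifelse(x2 > x1, (y2 - y1) / (x2 - x1), 0)
  ya <- y1 + slope * (a - x1)
  yb <- y1 + slope * (b - x1)
  sum((w * (ya + yb) / 2)[keep])
}

# DeLong placement values (midrank form). Returns the placements of each
# signal observation against the noise sample and vice versa; mean placement
# is the tie-corrected rank-statistic AUC.
.placements <- function(sx, sy) {
  m <- length(sx)
  n <- length(sy)
  r <- rank(c(sx, sy), ties.method = "average")
  v10 <- (r[seq_len(m)] - rank(sx, ties.method = "average")) / n
  v01 <- 1 - (r[m + seq_len(n)] - rank(sy, ties.method = "average")) / m
  # AUC from the midrank sum: exact integer/half-integer arithmetic up to a
  # single final division, so e.g. a rational AUC of 123/200 lands on the
  # nearest double to 0.615 (mean(v10) is the same value but accumulates
  # per-element rounding)
  auc <- (sum(r[seq_len(m)]) - as.numeric(m) * (m + 1) / 2) /
    (as.numeric(m) * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

.auc_rank <- function(sx, sy) {
  .placements(sx, sy)$auc
}
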