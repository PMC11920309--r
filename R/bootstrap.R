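#' Stratified bootstrap confidence interval for (partial) AUC
#'
#' Percentile bootstrap for the partial (or full) AUC of one group, or for
#' the difference in partial AUCs between two groups. Resampling is
#' stratified: signal and noise observations are resampled separately within
#' each group, preserving the class sizes. Replicates in which a resampled
#' group carries no discrimination information (all pooled scores identical)
#' are redrawn and counted. Fully reproducible given `seed`.
#'
#' @param data1 a [rating_data()] object.
#' @param data2 optional second group; when supplied the statistic is
#'   `pAUC(data1) - pAUC(data2)`.
#' @param fpr_range FPR interval `c(lo, hi)` within `[0, 1]`; `c(0, 1)` gives
#'   the full AUC.
#' @param n_boot number of bootstrap replicates (`>= 200`).
#' @param alpha type-I error rate; percentile intervals at `1 - alpha` and
#'   `1 - 2 * alpha` are reported.
#' @param seed RNG seed (required: bootstrap results must be reproducible).
#' @return An `"auc_estimate"` (one group) or `"delta_auc_estimate"` (two
#'   groups) with `method = "bootstrap"`; `variance`/`se` are taken from the
#'   bootstrap replicate distribution, and the attribute `n_redrawn` counts
#'   redrawn degenerate replicates.
#' @export
#' @examples
#' d <- expand_frequency_table(recognition_tables()$alcohol)
#' bootstrap_pauc_ci(d, fpr_range = c(0, 0.25), n_boot = 200, seed = 7)
bootstrap_pauc_ci <- function(data1, data2 = NULL, fpr_range = c(0, 1),
                              n_boot = 2000L, alpha = 0.05, seed = NULL) {
  validate_rating_data(data1)
  .check_fpr_range(fpr_range)
  if (n_boot < 200L) stop("n_boot must be at least 200")
  if (is.null(seed)) stop("a `seed` is required for bootstrap intervals")
  two <- !is.null(data2)
  if (two) validate_rating_data(data2)

  s1 <- .split_scores(data1)
  s2 <- if (two) .split_scores(data2) else NULL
  point <- .pauc_scores(s1$signal, s1$noise, fpr_range)
  if (two) point <- point - .pauc_scores(s2$signal, s2$noise, fpr_range)

  redrawn <- 0L
  reps <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      for (attempt in 1:100) {
        r1 <- .resample_pauc(s1, fpr_range)
        if (two) {
          r2 <- .resample_pauc(s2, fpr_range)
          if (!is.na(r1) && !is.na(r2)) {
            return(r1 - r2)
          }
        } else if (!is.na(r1)) {
          return(r1)
        }
        redrawn <<- redrawn + 1L
      }
      stop("bootstrap: too many degenerate replicates")
    }, numeric(1))
  })

  z <- 1 - alpha
  ci95 <- unname(quantile(reps, c((1 - z) / 2, (1 + z) / 2)))
  z90 <- 1 - 2 * alpha
  ci90 <- unname(quantile(reps, c((1 - z90) / 2, (1 + z90) / 2)))
  v <- var(reps)
  rng <- if (all(fpr_range == c(0, 1))) NULL else fpr_range
  out <- if (two) {
    .delta_estimate(point,
      se = sqrt(v), design = "unpaired", method = "bootstrap",
      alpha = alpha, fpr_range = rng, n_boot = n_boot, seed = seed,
      ci95 = ci95, ci90 = ci90, degenerate = v == 0
    )
  } else {
    .auc_estimate(point, v,
      method = "bootstrap", alpha = alpha,
      fpr_range = rng, n_boot = n_boot, seed = seed,
      ci95 = ci95, ci90 = ci90, degenerate = v == 0,
      m = length(s1$signal), n = length(s1$noise)
    )
  }
  attr(out, "n_redrawn") <- redrawn
  out
}

# one stratified resample of a group -> pAUC, or NA if degenerate
.resample_pauc <- function(s, fpr_range) {
  sx <- s$signal[sample.int(length(s$signal), replace = TRUE)]
  sy <- s$noise[sample.int(length(s$noise), replace = TRUE)]
  if (length(unique(c(sx, sy))) == 1L) {
    return(NA_real_)
  }
  .pauc_scores(sx, sy, fpr_range)
}

# (partial) AUC straight from score vectors; fast path for small-integer
# ratings (tabulate + cumulative sums), generic path otherwise
.pauc_scores <- function(sx, sy, fpr_range) {
  full <- fpr_range[1] == 0 && fpr_range[2] == 1
  ints <- all(sx == round(sx)) && all(sy == round(sy)) &&
    min(sx, sy) >= 1 && max(sx, sy) <= 64
  if (full && !ints) {
    return(.auc_rank(sx, sy))
  }
  if (ints) {
    k <- max(sx, sy)
    cs <- tabulate(sx, nbins = k)
    cn <- tabulate(sy, nbins = k)
    # cumulative P(score >= level) from the most conservative cutoff (level
    # k) to the most liberal (level 1, which is the (1,1) point), + anchor
    tpr <- c(0, cumsum(rev(cs)) / length(sx))
    fpr <- c(0, cumsum(rev(cn)) / length(sy))
  } else {
    cuts <- sort(unique(c(sx, sy)), decreasing = TRUE)
    tpr <- c(0, vapply(cuts, function(ct) mean(sx >= ct), numeric(1)), 1)
    fpr <- c(0, vapply(cuts, function(ct) mean(sy >= ct), numeric(1)), 1)
  }
  if (full) .trapezoid(fpr, tpr) else .pauc_xy(fpr, tpr, fpr_range[1], fpr_range[2])
}
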