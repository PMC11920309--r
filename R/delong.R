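#' DeLong components of the AUC
#'
#' Nonparametric U-statistic estimate of the AUC and its variance via
#' placement values computed from midranks. Each signal observation's
#' placement is the fraction of noise observations it outranks (ties counted
#' one half), and symmetrically for noise observations. The AUC is the mean
#' signal placement; its variance is
#' `var(signal placements)/m + var(noise placements)/n` with sample variances
#' (denominator count - 1).
#'
#' The returned AUC is bit-for-bit identical to [auc()] on the same rating
#' data: both go through the same placement computation.
#'
#' @param data a [rating_data()] object with at least 2 observations per
#'   class.
#' @return A list with elements `auc`, `variance`, `se`, `m` (signal count),
#'   `n` (noise count), and the placement vectors `v10` (signal) and `v01`
#'   (noise).
#' @references DeLong, DeLong & Clarke-Pearson (1988), Biometrics 44;
#'   Sun & Xu (2014), IEEE Signal Processing Letters 21 (midrank form).
#' @export
delong_components <- function(data) {
  validate_rating_data(data)
  s <- .split_scores(data)
  m <- length(s$signal)
  n <- length(s$noise)
  if (m < 2L || n < 2L) {
    stop("degenerate data: DeLong variance needs >= 2 observations per class")
  }
  pl <- .placements(s$signal, s$noise)
  v <- var(pl$v10) / m + var(pl$v01) / n
  list(
    auc = pl$auc, variance = v, se = sqrt(v), m = m, n = n,
    v10 = pl$v10, v01 = pl$v01
  )
}

# internal constructor for single-curve estimates
.auc_estimate <- function(auc, variance, method, alpha = 0.05,
                          fpr_range = NULL, n_boot = NULL, seed = NULL,
                          ci95 = NULL, ci90 = NULL, degenerate = FALSE,
                          m = NA_integer_, n = NA_integer_) {
  z <- .z_quantiles(alpha)
  se <- sqrt(variance)
  if (is.null(ci95)) ci95 <- auc + c(-1, 1) * z["z2"] * se
  if (is.null(ci90)) ci90 <- auc + c(-1, 1) * z["z1"] * se
  structure(
    list(
      auc = auc, variance = variance, se = se,
      ci95 = unname(ci95), ci90 = unname(ci90),
      method = method, alpha = alpha, fpr_range = fpr_range,
      n_boot = n_boot, seed = seed, degenerate = degenerate, m = m, n = n
    ),
    class = "auc_estimate"
  )
}

.delta_estimate <- function(delta, se, design, method = "delong",
                            alpha = 0.05, fpr_range = NULL, n_boot = NULL,
                            seed = NULL, ci95 = NULL, ci90 = NULL,
                            degenerate = FALSE) {
  z <- .z_quantiles(alpha)
  if (is.null(ci95)) ci95 <- delta + c(-1, 1) * z["z2"] * se
  if (is.null(ci90)) ci90 <- delta + c(-1, 1) * z["z1"] * se
  structure(
    list(
      delta = delta, se = se, ci95 = unname(ci95), ci90 = unname(ci90),
      design = design, method = method, alpha = alpha,
      fpr_range = fpr_range, n_boot = n_boot, seed = seed,
      degenerate = degenerate
    ),
    class = "delta_auc_estimate"
  )
}

#' AUC estimate with confidence intervals
#'
#' Point estimate of the (partial) AUC together with Wald (DeLong) or
#' percentile-bootstrap 95% and 90% confidence intervals. Wald intervals are
#' `auc +/- z * se` with `z = 1.96` (95%) and `1.645` (90%) at
#' `alpha = 0.05`; they are deliberately not clamped to `[0, 1]` because the
#' decision rules in [run_power()] operate on the raw bounds. A zero DeLong
#' variance (perfect separation) yields a zero-width interval flagged
#' `degenerate`.
#'
#' @param data a [rating_data()] object.
#' @param method `"delong"` (full curves) or `"bootstrap"` (required for
#'   partial curves, see `fpr_range`).
#' @param alpha type-I error rate; the intervals are at levels `1 - alpha`
#'   and `1 - 2 * alpha` (the latter for equivalence/TOST decisions).
#' @param fpr_range optional FPR interval `c(lo, hi)` for a partial AUC;
#'   forces the bootstrap method.
#' @param n_boot bootstrap replicates (used when `method = "bootstrap"`).
#' @param seed RNG seed for the bootstrap; required for reproducibility.
#' @return An object of class `"auc_estimate"`: a list with `auc`,
#'   `variance`, `se`, `ci95`, `ci90`, `method`, `alpha`, `fpr_range`,
#'   `n_boot`, `seed`, `degenerate`, and the class sizes `m`, `n`.
#' @export
#' @examples
#' d <- expand_frequency_table(recognition_tables()$alcohol)
#' auc_ci(d)
auc_ci <- function(data, method = c("delong", "bootstrap"), alpha = 0.05,
                   fpr_range = NULL, n_boot = 2000L, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(fpr_range)) {
    .check_fpr_range(fpr_range)
    if (method == "delong") {
      stop("partial AUC intervals require method = \"bootstrap\"")
    }
  }
  if (method == "delong") {
    dl <- delong_components(data)
    est <- .auc_estimate(dl$auc, dl$variance,
      method = "delong",
      alpha = alpha, m = dl$m, n = dl$n
    )
    if (dl$variance == 0) {
      est$ci95 <- est$ci90 <- c(dl$auc, dl$auc)
      est$degenerate <- TRUE
    }
    est
  } else {
    bootstrap_pauc_ci(data,
      fpr_range = if (is.null(fpr_range)) c(0, 1) else fpr_range,
      n_boot = n_boot, alpha = alpha, seed = seed
    )
  }
}

#' Confidence interval for the difference of two unpaired AUCs
#'
#' `delta = auc(data1) - auc(data2)`; the standard error is
#' `sqrt(V1 + V2)` from each group's DeLong variance. This is algebraically
#' identical to deriving the SE from DeLong's unpaired z statistic but
#' remains well defined when the difference is 0 (as the equivalence-test
#' simulations require). Intervals are `delta +/- z * se` with the same z
#' quantiles as [auc_ci()].
#'
#' @param data1,data2 [rating_data()] objects for the two independent groups.
#' @param alpha type-I error rate (see [auc_ci()]).
#' @return An object of class `"delta_auc_estimate"`: a list with `delta`,
#'   `se`, `ci95`, `ci90`, `design = "unpaired"`, `method`, `degenerate`.
#' @export
#' @examples
#' t1 <- recognition_tables()
#' delta_auc_unpaired(
#'   expand_frequency_table(t1$alcohol),
#'   expand_frequency_table(t1$placebo)
#' )
delta_auc_unpaired <- function(data1, data2, alpha = 0.05) {
  d1 <- delong_components(data1)
  d2 <- delong_components(data2)
  .delta_estimate(
    delta = d1$auc - d2$auc,
    se = sqrt(d1$variance + d2$variance),
    design = "unpaired", alpha = alpha,
    degenerate = (d1$variance + d2$variance) == 0
  )
}

#' Confidence interval for the difference of two paired AUCs
#'
#' For within-subject designs where each item is rated under both
#' conditions. The SE uses the paired DeLong variance
#' `V1 + V2 - 2 * cov(A1, A2)`, with the covariance computed from the paired
#' placement components aligned by `pairing` identifier.
#'
#' @param data1,data2 [rating_data()] objects for the two conditions, both
#'   carrying a `pairing` column that induces a bijection between their
#'   observations (within each class).
#' @param alpha type-I error rate (see [auc_ci()]).
#' @return A `"delta_auc_estimate"` with `design = "paired"`.
#' @export
delta_auc_paired <- function(data1, data2, alpha = 0.05) {
  if (!("pairing" %in% names(data1)) || !("pairing" %in% names(data2))) {
    stop("paired comparison requires a `pairing` column in both conditions")
  }
  for (lab in c(1L, 0L)) {
    p1 <- sort(data1$pairing[data1$label == lab])
    p2 <- sort(data2$pairing[data2$label == lab])
    if (length(p1) != length(p2) || any(p1 != p2) || anyDuplicated(p1)) {
      stop("broken pairing: `pairing` must be a bijection within each class")
    }
  }
  o1 <- order(data1$label, data1$pairing)
  o2 <- order(data2$label, data2$pairing)
  d1 <- data1[o1, , drop = FALSE]
  d2 <- data2[o2, , drop = FALSE]
  c1 <- delong_components(rating_data(d1$label, d1$score))
  c2 <- delong_components(rating_data(d2$label, d2$score))
  # placements are ordered like the sorted data, so paired elementwise
  cv <- cov(c1$v10, c2$v10) / c1$m + cov(c1$v01, c2$v01) / c1$n
  v <- c1$variance + c2$variance - 2 * cv
  v <- max(v, 0) # guard tiny negative from cancellation
  .delta_estimate(
    delta = c1$auc - c2$auc, se = sqrt(v),
    design = "paired", alpha = alpha, degenerate = v == 0
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  what <- if (is.null(x$fpr_range)) {
    "AUC"
  } else {
    sprintf("pAUC[%.3f, %.3f]", x$fpr_range[1], x$fpr_range[2])
  }
  # display bounds clamped to [0, 1]; decisions always use raw bounds
  cat(sprintf(
    "%s = %.2f, 95%% CI [%.2f; %.2f], 90%% CI [%.2f; %.2f] (%s)\n",
    what, x$auc,
    max(x$ci95[1], 0), min(x$ci95[2], 1),
    max(x$ci90[1], 0), min(x$ci90[2], 1), x$method
  ))
  if (x$degenerate) cat("note: degenerate (zero-variance) estimate\n")
  invisible(x)
}

#' @export
print.delta_auc_estimate <- function(x, ...) {
  what <- if (is.null(x$fpr_range)) "dAUC" else "dpAUC"
  cat(sprintf(
    "%s = %.2f, SE = %.3f, 95%% CI [%.2f; %.2f], 90%% CI [%.2f; %.2f] (%s, %s)\n",
    what, x$delta, x$se, x$ci95[1], x$ci95[2], x$ci90[1], x$ci90[2],
    x$design, x$method
  ))
  if (x$degenerate) cat("note: degenerate (zero-variance) estimate\n")
  invisible(x)
}

#' Serialize an estimate to JSON
#'
#' @param est an `auc_estimate` or `delta_auc_estimate`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly the path when writing to file).
#' @export
estimate_json <- function(est, path = NULL) {
  stopifnot(inherits(est, c("auc_estimate", "delta_auc_estimate")))
  x <- unclass(est)
  x <- x[!vapply(x, is.null, logical(1))]
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}
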