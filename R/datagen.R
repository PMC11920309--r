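#' Binormal design specification
#'
#' Describes the data-generating process used by the power simulations: a
#' latent equal- or unequal-variance signal-detection model in which each
#' rated item has a normally distributed latent strength — `N(mu_noise,
#' sd_noise)` for noise (new) items and `N(mu_signal, sd_signal)` for signal
#' (old) items — that is then redistributed onto an ordinal confidence scale
#' `1..k_levels`. Under this model the continuous-data AUC has the closed
#' form `pnorm((mu_signal - mu_noise) / sqrt(sd_signal^2 + sd_noise^2))`.
#'
#' The default redistribution rule is equal-frequency (quantile) binning of
#' the pooled latent values of a dataset into `k_levels` ordered categories.
#' Because within-class ranks are almost unchanged by a monotone
#' equal-frequency binning, the ordinal AUC tracks the continuous AUC closely
#' (e.g. a signal mean of 0.38 yields an AUC of about 0.60, 0.57 about 0.65,
#' 0.78 about 0.70, and 1.0 about 0.75 on the 6-point scale). Equal-width
#' binning of the pooled range and user-supplied fixed cutpoints are
#' available via `discretize`/`cutpoints`.
#'
#' @param mu_signal latent mean of the signal distribution.
#' @param mu_noise latent mean of the noise distribution (default 0).
#' @param sd_signal,sd_noise latent standard deviations (default 1; must be
#'   positive). Unequal values give the bowed, asymmetric ROC shapes.
#' @param k_levels number of confidence levels (default 6, integer >= 2).
#' @param n_participants number of participants.
#' @param items_signal,items_noise signal/noise items per participant.
#' @param rho latent correlation across the two conditions of a paired
#'   design, in `[-1, 1]`; ignored for single-group/unpaired use.
#' @param continuous if `TRUE`, skip the redistribution step and keep latent
#'   values as scores.
#' @param discretize `"quantile"` (default) or `"equal_width"`.
#' @param cutpoints optional increasing vector of fixed latent cutpoints
#'   (length `k_levels - 1`); overrides `discretize`.
#' @return An object of class `"binormal_spec"`.
#' @seealso [generate_ratings()], [closed_form_auc()],
#'   [estimate_auc_empirical()], [power_config()]
#' @export
#' @examples
#' spec <- binormal_spec(
#'   mu_signal = 0.38, n_participants = 100,
#'   items_signal = 2, items_noise = 2
#' )
#' closed_form_auc(spec)
binormal_spec <- function(mu_signal, mu_noise = 0, sd_signal = 1,
                          sd_noise = 1, k_levels = 6L, n_participants,
                          items_signal, items_noise, rho = 0,
                          continuous = FALSE,
                          discretize = c("quantile", "equal_width"),
                          cutpoints = NULL) {
  discretize <- match.arg(discretize)
  stopifnot(
    is.finite(mu_signal), is.finite(mu_noise),
    sd_signal > 0, sd_noise > 0,
    k_levels >= 2, k_levels == round(k_levels),
    n_participants >= 1, n_participants == round(n_participants),
    items_signal >= 1, items_noise >= 1,
    items_signal == round(items_signal), items_noise == round(items_noise),
    rho >= -1, rho <= 1
  )
  if (!is.null(cutpoints)) {
    if (length(cutpoints) != k_levels - 1 || is.unsorted(cutpoints, strictly = TRUE)) {
      stop("`cutpoints` must be ", k_levels - 1, " strictly increasing values")
    }
  }
  structure(
    list(
      mu_signal = mu_signal, mu_noise = mu_noise,
      sd_signal = sd_signal, sd_noise = sd_noise,
      k_levels = as.integer(k_levels),
      n_participants = as.integer(n_participants),
      items_signal = as.integer(items_signal),
      items_noise = as.integer(items_noise),
      rho = rho, continuous = continuous,
      discretize = discretize, cutpoints = cutpoints
    ),
    class = "binormal_spec"
  )
}

#' @export
print.binormal_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "binormal design: signal N(%g, %g), noise N(%g, %g)\n",
      "%d participants x (%d signal + %d noise items); %s\n",
      "closed-form (continuous) AUC = %.3f\n"
    ),
    x$mu_signal, x$sd_signal, x$mu_noise, x$sd_noise,
    x$n_participants, x$items_signal, x$items_noise,
    if (x$continuous) {
      "continuous scores"
    } else {
      sprintf("%d-level ratings (%s)", x$k_levels, if (is.null(x$cutpoints)) x$discretize else "fixed cutpoints")
    },
    closed_form_auc(x)
  ))
  invisible(x)
}

#' Closed-form binormal AUC
#'
#' The AUC implied by the latent model before discretization:
#' `pnorm((mu_signal - mu_noise) / sqrt(sd_signal^2 + sd_noise^2))`. Used as
#' the analytic anchor for the simulation-estimated AUCs.
#'
#' @param spec a [binormal_spec()].
#' @return The AUC in `(0, 1)`.
#' @export
closed_form_auc <- function(spec) {
  stopifnot(inherits(spec, "binormal_spec"))
  pnorm((spec$mu_signal - spec$mu_noise) /
    sqrt(spec$sd_signal^2 + spec$sd_noise^2))
}

# redistribute latent values onto 1..k
.discretize <- function(x, spec) {
  k <- spec$k_levels
  if (!is.null(spec$cutpoints)) {
    breaks <- c(-Inf, spec$cutpoints, Inf)
  } else if (spec$discretize == "quantile") {
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1)))
  } else {
    breaks <- seq(min(x), max(x), length.out = k + 1)
  }
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Generate a confidence-rating dataset from a binormal design
#'
#' Draws the latent strengths, redistributes them onto the ordinal scale
#' (unless `spec$continuous`), and returns observation-level data. Each
#' participant contributes `items_signal` signal and `items_noise` noise
#' observations; the participant structure is recorded but treated as
#' independent by the estimators (see the package vignette for what this
#' aggregation ignores).
#'
#' @param spec a [binormal_spec()].
#' @param seed RNG seed (required; same seed, same dataset).
#' @return A [rating_data()] object.
#' @export
#' @examples
#' d <- generate_ratings(
#'   binormal_spec(0.38, n_participants = 10, items_signal = 2, items_noise = 2),
#'   seed = 1
#' )
#' auc(d)
generate_ratings <- function(spec, seed) {
  stopifnot(inherits(spec, "binormal_spec"))
  if (missing(seed) || is.null(seed)) stop("a `seed` is required")
  m <- spec$n_participants * spec$items_signal
  n <- spec$n_participants * spec$items_noise
  lat <- .with_seed(seed, c(
    rnorm(m, spec$mu_signal, spec$sd_signal),
    rnorm(n, spec$mu_noise, spec$sd_noise)
  ))
  scores <- if (spec$continuous) lat else .discretize(lat, spec)
  rating_data(
    labels = c(rep(1L, m), rep(0L, n)),
    scores = scores,
    participant = c(
      rep(seq_len(spec$n_participants), each = spec$items_signal),
      rep(seq_len(spec$n_participants), each = spec$items_noise)
    )
  )
}

#' Generate paired rating datasets for two conditions
#'
#' For within-subject designs: every item is rated under both conditions,
#' and the two latent strengths of an item are bivariate normal with
#' correlation `rho` (applied to signal and noise items alike). Condition
#' means/SDs come from `spec1` and `spec2`; the design dimensions and `rho`
#' must agree between the two specs. Each condition is redistributed onto the
#' ordinal scale separately (the AUC is invariant to monotone within-
#' condition rescaling).
#'
#' @param spec1,spec2 [binormal_spec()] objects for the two conditions.
#' @param seed RNG seed.
#' @return A list of two [rating_data()] objects (`cond1`, `cond2`) whose
#'   `pairing` columns link the same item across conditions.
#' @export
generate_paired_ratings <- function(spec1, spec2, seed) {
  stopifnot(inherits(spec1, "binormal_spec"), inherits(spec2, "binormal_spec"))
  if (spec1$n_participants != spec2$n_participants ||
    spec1$items_signal != spec2$items_signal ||
    spec1$items_noise != spec2$items_noise) {
    stop("paired conditions must share the design dimensions")
  }
  if (spec1$rho != spec2$rho) stop("paired conditions must share `rho`")
  rho <- spec1$rho
  m <- spec1$n_participants * spec1$items_signal
  n <- spec1$n_participants * spec1$items_noise
  zz <- .with_seed(seed, {
    z1 <- rnorm(m + n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m + n)
    list(z1 = z1, z2 = z2)
  })
  build <- function(spec, z) {
    lat <- c(
      spec$mu_signal + spec$sd_signal * z[seq_len(m)],
      spec$mu_noise + spec$sd_noise * z[m + seq_len(n)]
    )
    scores <- if (spec$continuous) lat else .discretize(lat, spec)
    rating_data(
      labels = c(rep(1L, m), rep(0L, n)),
      scores = scores,
      participant = c(
        rep(seq_len(spec$n_participants), each = spec$items_signal),
        rep(seq_len(spec$n_participants), each = spec$items_noise)
      ),
      pairing = seq_len(m + n)
    )
  }
  list(cond1 = build(spec1, zz$z1), cond2 = build(spec2, zz$z2))
}

#' Empirical AUC implied by a binormal design
#'
#' Generates one large dataset (`n_items` per class, participant structure
#' collapsed) and returns its AUC — the simulation analogue of
#' [closed_form_auc()] on the discretized scale, used to map latent means to
#' target AUCs (e.g. signal mean 0.38 on the default 6-point scale gives
#' about 0.60). Display at two decimals mirrors how such estimates are
#' usually reported.
#'
#' @param spec a [binormal_spec()] (its `n_participants`/items are ignored
#'   here).
#' @param n_items observations per class (`>= 1000`; default 10000).
#' @param seed RNG seed.
#' @return The empirical AUC (full precision).
#' @export
estimate_auc_empirical <- function(spec, n_items = 10000L, seed) {
  stopifnot(inherits(spec, "binormal_spec"), n_items >= 1000)
  flat <- spec
  flat$n_participants <- 1L
  flat$items_signal <- as.integer(n_items)
  flat$items_noise <- as.integer(n_items)
  auc(generate_ratings(flat, seed = seed))
}
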