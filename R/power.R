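#' Power-analysis configuration
#'
#' Full specification of a simulation-based power analysis: the design, the
#' data-generating binormal spec(s), the smallest effect size of interest
#' (SESOI), the alpha level, and the Monte Carlo settings. Validated up
#' front so inconsistencies fail before any simulation runs.
#'
#' Designs:
#' * `"single"` — one ROC curve; effects on the AUC scale, null 0.5; the
#'   SESOI is an AUC in `(0.5, 1)`.
#' * `"two_unpaired"` — two independent groups; effects on the AUC-difference
#'   scale, null 0; the SESOI is a difference in `(0, 0.5]`.
#' * `"two_paired"` — two within-subject conditions (requires `rho` in the
#'   specs); same effect scale as unpaired.
#'
#' When `fpr_range` is set the design runs on the partial-AUC scale:
#' inference switches to the stratified bootstrap, the single-curve null is
#' the chance-diagonal area `(hi^2 - lo^2) / 2`, and the SESOI is interpreted
#' on the raw pAUC (or pAUC-difference) scale. Partial runs default to
#' `n_sims = 200` and `n_boot = 500` (with a warning) because each simulated
#' dataset is itself bootstrapped; full-fidelity runs are reachable by
#' setting both explicitly.
#'
#' @param design `"single"`, `"two_unpaired"`, or `"two_paired"`.
#' @param spec1 a [binormal_spec()]; the only spec for single designs, group
#'   1 / condition 1 otherwise.
#' @param spec2 a [binormal_spec()] for group 2 / condition 2 (two-group
#'   designs only).
#' @param sesoi smallest effect size of interest, on the effect scale of the
#'   design (see above). `NULL` disables the MET and EQ rules.
#' @param alpha type-I error rate (default 0.05): decisions use the
#'   `1 - alpha` CI (NHST, MET) and the `1 - 2 * alpha` CI (EQ/TOST).
#' @param n_sims number of simulated datasets (default 1000).
#' @param seed master seed; spawns one independent substream per dataset.
#' @param fpr_range optional FPR interval for partial-AUC designs.
#' @param n_boot bootstrap replicates per dataset for partial designs.
#' @return An object of class `"power_config"`.
#' @seealso [run_power()], [type1_check()]
#' @export
#' @examples
#' cfg <- power_config(
#'   design = "single",
#'   spec1 = binormal_spec(0.38, n_participants = 100, items_signal = 2, items_noise = 2),
#'   sesoi = 0.60, n_sims = 100, seed = 1
#' )
power_config <- function(design = c("single", "two_unpaired", "two_paired"),
                         spec1, spec2 = NULL, sesoi = NULL, alpha = 0.05,
                         n_sims = 1000L, seed, fpr_range = NULL,
                         n_boot = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(spec1, "binormal_spec"))
  if (missing(seed) || is.null(seed)) stop("a `seed` is required")
  stopifnot(alpha > 0, alpha < 0.5)
  two <- design != "single"
  if (two && is.null(spec2)) stop("two-group designs require `spec2`")
  if (!two && !is.null(spec2)) stop("single design takes no `spec2`")
  if (two) stopifnot(inherits(spec2, "binormal_spec"))
  partial <- !is.null(fpr_range)
  if (partial) .check_fpr_range(fpr_range)

  if (!is.null(sesoi)) {
    if (partial) {
      area_max <- fpr_range[2] - fpr_range[1]
      chance <- (fpr_range[2]^2 - fpr_range[1]^2) / 2
      ok <- if (two) {
        sesoi > 0 && sesoi <= area_max
      } else {
        sesoi > chance && sesoi <= area_max
      }
      if (!ok) stop("`sesoi` is outside the admissible pAUC range")
    } else if (two) {
      if (sesoi <= 0 || sesoi > 0.5) {
        stop("two-group `sesoi` must be an AUC difference in (0, 0.5]")
      }
    } else if (sesoi <= 0.5 || sesoi >= 1) {
      stop("single-curve `sesoi` must be an AUC in (0.5, 1)")
    }
  }

  if (partial) {
    scaled <- is.null(n_boot) || missing(n_sims)
    if (is.null(n_boot)) n_boot <- 500L
    if (missing(n_sims)) n_sims <- 200L
    if (scaled) {
      warning(
        "partial-AUC power run scaled down to n_sims = ", n_sims,
        ", n_boot = ", n_boot,
        "; set both explicitly for a full-fidelity run",
        call. = FALSE
      )
    }
    if (n_boot < 200L) stop("n_boot must be at least 200")
  }
  stopifnot(n_sims >= 1, n_sims == round(n_sims))

  structure(
    list(
      design = design, spec1 = spec1, spec2 = spec2, sesoi = sesoi,
      alpha = alpha, n_sims = as.integer(n_sims), seed = as.integer(seed),
      fpr_range = fpr_range,
      n_boot = if (partial) as.integer(n_boot) else NULL
    ),
    class = "power_config"
  )
}

# null value of an estimate's effect scale
.null_value <- function(est) {
  if (inherits(est, "delta_auc_estimate")) {
    return(0)
  }
  if (is.null(est$fpr_range)) {
    return(0.5)
  }
  (est$fpr_range[2]^2 - est$fpr_range[1]^2) / 2 # chance-diagonal pAUC
}

#' Confidence-interval decision rules
#'
#' The three decisions applied to each simulated estimate. All bounds are
#' compared strictly, on the raw (unclamped) interval endpoints. A
#' `degenerate` estimate returns `FALSE` for every rule.
#'
#' * `decide_nhst()`: the 95% CI excludes the null value (0.5 for a single
#'   full-curve AUC, the chance-diagonal area for a single pAUC, 0 for a
#'   difference).
#' * `decide_met()`: the whole 95% CI lies beyond the SESOI in the
#'   hypothesized direction (lower bound above the SESOI).
#' * `decide_eq()`: the whole 90% CI lies strictly inside the equivalence
#'   region — for a single AUC the region symmetric about the null,
#'   `(null - (sesoi - null), sesoi)`; for a difference, `(-sesoi, sesoi)`.
#'
#' @param est an `auc_estimate` or `delta_auc_estimate`.
#' @param sesoi the smallest effect size of interest, on `est`'s effect
#'   scale.
#' @return `TRUE` or `FALSE`.
#' @export
decide_nhst <- function(est) {
  if (isTRUE(est$degenerate)) {
    return(FALSE)
  }
  null <- .null_value(est)
  est$ci95[1] > null || est$ci95[2] < null
}

#' @rdname decide_nhst
#' @export
decide_met <- function(est, sesoi) {
  if (isTRUE(est$degenerate)) {
    return(FALSE)
  }
  est$ci95[1] > sesoi
}

#' @rdname decide_nhst
#' @export
decide_eq <- function(est, sesoi) {
  if (isTRUE(est$degenerate)) {
    return(FALSE)
  }
  if (inherits(est, "delta_auc_estimate")) {
    lo <- -sesoi
    hi <- sesoi
  } else {
    null <- .null_value(est)
    lo <- null - (sesoi - null)
    hi <- sesoi
  }
  est$ci90[1] > lo && est$ci90[2] < hi
}

#' Run a simulation-based power analysis
#'
#' For each of `n_sims` independent substreams: generate the dataset(s) from
#' the binormal spec(s), estimate the (partial) AUC or AUC difference with
#' the design's inference method (DeLong for full curves, stratified
#' bootstrap for partial curves), and apply the three CI decision rules.
#' Power for each test is the proportion of decisions that came out `TRUE`;
#' its Monte Carlo standard error is `sqrt(p * (1 - p) / n_sims)`.
#'
#' For two-group designs the difference is oriented so the hypothesized
#' effect (the sign of the closed-form AUC difference of the two specs) is
#' positive; datasets whose estimate comes out sign-reversed therefore count
#' as MET failures rather than being silently corrected. Datasets with a
#' degenerate (zero-variance) estimate count as `FALSE` for all three rules
#' and are tallied in `n_degenerate`.
#'
#' @param config a [power_config()].
#' @return An object of class `"power_report"`: a list with `power_nhst`,
#'   `power_met`, `power_eq` (proportions, `NA` for MET/EQ when no SESOI is
#'   set), `mc_se` (per proportion), `n_sims`, `n_degenerate`, `config`,
#'   `seed`.
#' @export
#' @examples
#' cfg <- power_config(
#'   design = "single",
#'   spec1 = binormal_spec(0.38, n_participants = 100, items_signal = 2, items_noise = 2),
#'   sesoi = 0.60, n_sims = 50, seed = 1
#' )
#' run_power(cfg)
run_power <- function(config) {
  stopifnot(inherits(config, "power_config"))
  seeds <- .spawn_seeds(config$seed, config$n_sims)
  two <- config$design != "single"
  partial <- !is.null(config$fpr_range)
  # orientation: hypothesized-positive difference (group with larger
  # closed-form AUC minus the other); +1 when the truth is a zero difference
  flip <- two &&
    closed_form_auc(config$spec1) > closed_form_auc(config$spec2)

  nhst <- met <- eq <- logical(config$n_sims)
  degen <- 0L
  for (i in seq_len(config$n_sims)) {
    est <- tryCatch(
      .simulate_estimate(config, seeds[i], two, partial, flip),
      error = function(e) NULL
    )
    if (is.null(est) || isTRUE(est$degenerate)) {
      degen <- degen + 1L
      next # decisions stay FALSE
    }
    nhst[i] <- decide_nhst(est)
    if (!is.null(config$sesoi)) {
      met[i] <- decide_met(est, config$sesoi)
      eq[i] <- decide_eq(est, config$sesoi)
    }
  }

  p <- c(nhst = mean(nhst), met = mean(met), eq = mean(eq))
  if (is.null(config$sesoi)) p[c("met", "eq")] <- NA_real_
  structure(
    list(
      power_nhst = unname(p["nhst"]),
      power_met = unname(p["met"]),
      power_eq = unname(p["eq"]),
      mc_se = sqrt(p * (1 - p) / config$n_sims),
      n_sims = config$n_sims,
      n_degenerate = degen,
      config = config,
      seed = config$seed
    ),
    class = "power_report"
  )
}

# one simulated dataset -> oriented estimate
.simulate_estimate <- function(config, seed, two, partial, flip) {
  sub <- .spawn_seeds(seed, 3L) # gen seed(s) + bootstrap seed
  if (!two) {
    dat <- generate_ratings(config$spec1, seed = sub[1])
    if (partial) {
      return(bootstrap_pauc_ci(dat,
        fpr_range = config$fpr_range,
        n_boot = config$n_boot, alpha = config$alpha, seed = sub[3]
      ))
    }
    return(auc_ci(dat, method = "delong", alpha = config$alpha))
  }
  if (config$design == "two_paired") {
    pair <- generate_paired_ratings(config$spec1, config$spec2, seed = sub[1])
    d1 <- pair$cond1
    d2 <- pair$cond2
  } else {
    d1 <- generate_ratings(config$spec1, seed = sub[1])
    d2 <- generate_ratings(config$spec2, seed = sub[2])
  }
  if (flip) {
    tmp <- d1
    d1 <- d2
    d2 <- tmp
  }
  # delta is (hypothesized-larger group) - (smaller): positive under H1
  if (partial) {
    bootstrap_pauc_ci(d2, d1,
      fpr_range = config$fpr_range,
      n_boot = config$n_boot, alpha = config$alpha, seed = sub[3]
    )
  } else if (config$design == "two_paired") {
    delta_auc_paired(d2, d1, alpha = config$alpha)
  } else {
    delta_auc_unpaired(d2, d1, alpha = config$alpha)
  }
}

#' Type-I error / calibration check at the decision boundary
#'
#' Runs [run_power()] on a configuration whose true effect sits exactly at
#' the decision boundary of the chosen test (the null value for NHST, the
#' SESOI for MET and EQ) and returns the observed rejection/pass rate. At
#' the boundary, NHST and EQ rates should be near `alpha` and the one-sided
#' MET rate at most `alpha`.
#'
#' @param config a [power_config()] whose true effect is at the boundary of
#'   `test`.
#' @param test which decision rule's rate to return.
#' @return The observed proportion (a number in `[0, 1]`).
#' @export
type1_check <- function(config, test = c("nhst", "met", "eq")) {
  test <- match.arg(test)
  rep <- run_power(config)
  switch(test,
    nhst = rep$power_nhst,
    met = rep$power_met,
    eq = rep$power_eq
  )
}

#' @export
print.power_report <- function(x, ...) {
  cfg <- x$config
  two <- cfg$design != "single"
  cat("Simulation-based power analysis\n")
  cat(sprintf(
    "  design: %s%s\n", cfg$design,
    if (!is.null(cfg$fpr_range)) {
      sprintf(
        " (partial AUC, FPR in [%g, %g], %d bootstrap replicates)",
        cfg$fpr_range[1], cfg$fpr_range[2], cfg$n_boot
      )
    } else {
      ""
    }
  ))
  cat(sprintf(
    "  group 1: signal N(%g, %g), noise N(%g, %g), %d x (%d + %d items)\n",
    cfg$spec1$mu_signal, cfg$spec1$sd_signal, cfg$spec1$mu_noise,
    cfg$spec1$sd_noise, cfg$spec1$n_participants, cfg$spec1$items_signal,
    cfg$spec1$items_noise
  ))
  if (two) {
    cat(sprintf(
      "  group 2: signal N(%g, %g), noise N(%g, %g), %d x (%d + %d items)\n",
      cfg$spec2$mu_signal, cfg$spec2$sd_signal, cfg$spec2$mu_noise,
      cfg$spec2$sd_noise, cfg$spec2$n_participants, cfg$spec2$items_signal,
      cfg$spec2$items_noise
    ))
  }
  cat(sprintf(
    "  sesoi: %s | alpha: %g | n_sims: %d | seed: %d | degenerate: %d\n",
    if (is.null(cfg$sesoi)) "none" else format(cfg$sesoi),
    cfg$alpha, x$n_sims, x$seed, x$n_degenerate
  ))
  tab <- data.frame(
    test = c(
      "null-hypothesis significance", "minimum-effect", "equivalence"
    ),
    power = c(x$power_nhst, x$power_met, x$power_eq),
    mc_se = unname(x$mc_se)
  )
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}
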