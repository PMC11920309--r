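# Independent oracles used across the suite. These never call the package's
# own code paths for the quantity they check.

# brute-force tie-corrected rank statistic: P(X > Y) + 0.5 P(X = Y)
oracle_auc_pairwise <- function(sx, sy) {
  tot <- 0
  for (x in sx) tot <- tot + sum(x > sy) + 0.5 * sum(x == sy)
  tot / (length(sx) * length(sy))
}

# trapezoid over the cumulative-threshold points, computed from counts
oracle_auc_trapezoid <- function(signal_counts, noise_counts) {
  tpr <- c(0, cumsum(rev(signal_counts)) / sum(signal_counts))
  fpr <- c(0, cumsum(rev(noise_counts)) / sum(noise_counts))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Hanley-McNeil normal-approximation SE of an AUC
oracle_se_hanley <- function(a, m, n) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / (m * n))
}

# analytic two-sided NHST power for a single AUC under the normal
# approximation with the Hanley-McNeil SE
oracle_power_nhst_single <- function(true_auc, m, n, null = 0.5, z = 1.96) {
  se <- oracle_se_hanley(true_auc, m, n)
  d <- (true_auc - null) / se
  pnorm(d - z) + pnorm(-d - z)
}

# random ordinal rating dataset (both classes guaranteed non-empty)
random_rating_data <- function(seed, max_k = 8, max_n = 60) {
  set.seed(seed)
  k <- sample(2:max_k, 1)
  m <- sample(2:max_n, 1)
  n <- sample(2:max_n, 1)
  rating_data(
    labels = c(rep(1, m), rep(0, n)),
    scores = c(
      sample.int(k, m, replace = TRUE, prob = sort(runif(k))),
      sample.int(k, n, replace = TRUE, prob = rev(sort(runif(k))))
    )
  )
}

# stratified bootstrap variance of the full-curve AUC, independent of the
# package's bootstrap code (plain resampling + pairwise oracle on ranks)
oracle_bootstrap_var <- function(data, n_boot, seed) {
  sx <- data$score[data$label == 1]
  sy <- data$score[data$label == 0]
  set.seed(seed)
  reps <- replicate(n_boot, {
    x <- sample(sx, replace = TRUE)
    y <- sample(sy, replace = TRUE)
    r <- rank(c(x, y))
    (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
      (length(x) * length(y))
  })
  var(reps)
}

# fabricate estimate objects for exercising the decision rules directly
fake_auc_estimate <- function(ci95, ci90 = ci95, fpr_range = NULL,
                              degenerate = FALSE) {
  structure(
    list(
      auc = mean(ci95), ci95 = ci95, ci90 = ci90,
      fpr_range = fpr_range, degenerate = degenerate, method = "delong"
    ),
    class = "auc_estimate"
  )
}

fake_delta_estimate <- function(ci95, ci90 = ci95, degenerate = FALSE) {
  structure(
    list(
      delta = mean(ci95), ci95 = ci95, ci90 = ci90,
      design = "unpaired", degenerate = degenerate, method = "delong"
    ),
    class = "delta_auc_estimate"
  )
}

recognition_counts <- function() {
  list(
    alcohol = list(
      signal = c(100, 150, 300, 100, 200, 150),
      noise = c(300, 200, 100, 150, 150, 100)
    ),
    placebo = list(
      signal = c(50, 100, 350, 150, 250, 100),
      noise = c(350, 250, 150, 100, 100, 50)
    )
  )
}
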