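alcohol_data <- expand_frequency_table(recognition_tables()$alcohol)

test_that("DeLong interval for the fixture rounds to the reported bounds", {
  est <- auc_ci(alcohol_data)
  expect_identical(sprintf("%.2f", est$auc), "0.61")
  expect_equal(round(est$ci95, 2), c(0.59, 0.64))
  expect_true(all(est$ci90[1] >= est$ci95[1] & est$ci90[2] <= est$ci95[2]))
})

test_that("DeLong AUC is bit-identical to the rank-statistic AUC", {
  for (seed in 1:25) {
    d <- random_rating_data(seed)
    expect_identical(delong_components(d)$auc, auc(d))
  }
})

test_that("DeLong agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  for (seed in c(2, 7)) {
    d <- generate_ratings(
      binormal_spec(0.5, n_participants = 60, items_signal = 2, items_noise = 2),
      seed = seed
    )
    est <- auc_ci(d)
    ref <- pROC::ci.auc(
      pROC::roc(d$label, d$score, direction = "<", quiet = TRUE),
      method = "delong"
    )
    expect_equal(est$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(est$variance, pROC::var(
      pROC::roc(d$label, d$score, direction = "<", quiet = TRUE),
      method = "delong"
    ), tolerance = 1e-10)
    # bounds differ only through z = 1.96 vs qnorm(0.975)
    expect_equal(est$ci95[1], as.numeric(ref[1]), tolerance = 1e-4)
    expect_equal(est$ci95[2], as.numeric(ref[3]), tolerance = 1e-4)
  }
})

test_that("perfect separation gives variance 0 and a flagged interval", {
  d <- rating_data(c(1, 1, 1, 0, 0, 0), c(6, 6, 5, 2, 1, 1))
  dl <- delong_components(d)
  expect_equal(dl$auc, 1)
  expect_equal(dl$variance, 0)
  est <- auc_ci(d)
  expect_true(est$degenerate)
  expect_equal(est$ci95, c(1, 1))
})

test_that("a class of size one is rejected as degenerate", {
  expect_error(
    delong_components(rating_data(c(1, 0, 0), c(3, 2, 1))),
    "degenerate"
  )
})

test_that("DeLong variance matches a stratified bootstrap variance", {
  d <- generate_ratings(
    binormal_spec(0.57, n_participants = 125, items_signal = 2, items_noise = 2),
    seed = 21
  )
  v_delong <- delong_components(d)$variance
  v_boot <- oracle_bootstrap_var(d, n_boot = 2000, seed = 22)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.15)
})

test_that("unpaired difference: identical groups and fixture delta", {
  est0 <- delta_auc_unpaired(alcohol_data, alcohol_data)
  expect_equal(est0$delta, 0)
  expect_equal(est0$ci95[1], -est0$ci95[2])

  placebo_data <- expand_frequency_table(recognition_tables()$placebo)
  est <- delta_auc_unpaired(alcohol_data, placebo_data)
  expect_equal(est$delta, 0.615 - 0.735)
  expect_equal(
    est$se,
    sqrt(delong_components(alcohol_data)$variance +
      delong_components(placebo_data)$variance)
  )
})

test_that("paired difference: exact copy, rho = 0, and rho = 0.8 behaviour", {
  spec <- binormal_spec(0.4,
    n_participants = 40, items_signal = 3,
    items_noise = 3, rho = 0.8
  )
  pair <- generate_paired_ratings(spec, spec, seed = 5)
  same <- delta_auc_paired(pair$cond1, pair$cond1)
  expect_equal(same$delta, 0)
  expect_equal(same$se, 0)
  expect_true(same$degenerate)

  # rho = 0.8: pairing should shrink the SE vs treating groups as unpaired
  wins <- 0L
  for (seed in 1:50) {
    pr <- generate_paired_ratings(spec, spec, seed = seed)
    se_p <- delta_auc_paired(pr$cond1, pr$cond2)$se
    se_u <- delta_auc_unpaired(pr$cond1, pr$cond2)$se
    if (se_p < se_u) wins <- wins + 1L
  }
  expect_gte(wins / 50, 0.95)

  # rho = 0: paired and unpaired SEs agree on average
  spec0 <- binormal_spec(0.4,
    n_participants = 40, items_signal = 3,
    items_noise = 3, rho = 0
  )
  ratios <- vapply(1:40, function(seed) {
    pr <- generate_paired_ratings(spec0, spec0, seed = seed)
    delta_auc_paired(pr$cond1, pr$cond2)$se /
      delta_auc_unpaired(pr$cond1, pr$cond2)$se
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("broken pairing is rejected", {
  spec <- binormal_spec(0.4, n_participants = 10, items_signal = 2, items_noise = 2)
  pair <- generate_paired_ratings(spec, spec, seed = 1)
  d2 <- pair$cond2
  d2$pairing[1] <- d2$pairing[2] # duplicate -> not a bijection
  expect_error(delta_auc_paired(pair$cond1, d2), "pairing")
  expect_error(
    delta_auc_paired(pair$cond1, pair$cond2[-1, ]),
    "pairing"
  )
})

test_that("Wald CI width shrinks like 1/sqrt(n) when n doubles", {
  width <- function(n_part, seed) {
    d <- generate_ratings(
      binormal_spec(0.38,
        n_participants = n_part, items_signal = 2,
        items_noise = 2
      ),
      seed = seed
    )
    est <- auc_ci(d)
    est$ci95[2] - est$ci95[1]
  }
  w1 <- vapply(1:150, function(s) width(50, s), numeric(1))
  w2 <- vapply(1:150, function(s) width(100, 1000 + s), numeric(1))
  expect_gt(mean(w2) / mean(w1), 0.65)
  expect_lt(mean(w2) / mean(w1), 0.75)
})

test_that("nominal 95% DeLong intervals cover the true AUC at ~95%", {
  # binormal ordinal data, true AUC ~0.6, 200/200 observations
  spec <- binormal_spec(0.38,
    n_participants = 100, items_signal = 2,
    items_noise = 2
  )
  true_auc <- estimate_auc_empirical(spec, n_items = 200000, seed = 999)
  seeds <- 1:1000
  covered <- vapply(seeds, function(s) {
    est <- auc_ci(generate_ratings(spec, seed = s))
    est$ci95[1] <= true_auc && true_auc <= est$ci95[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.975)
})

test_that("estimates serialize to JSON and parse back", {
  est <- auc_ci(alcohol_data)
  parsed <- jsonlite::fromJSON(estimate_json(est))
  expect_equal(parsed$auc, est$auc)
  expect_equal(parsed$ci95, est$ci95)
  expect_equal(parsed$method, "delong")
})
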