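spec22 <- function(mu, n = 100) {
  binormal_spec(mu, n_participants = n, items_signal = 2, items_noise = 2)
}

test_that("NHST decision: 95% CI must exclude the null value", {
  expect_true(decide_nhst(fake_auc_estimate(c(0.55, 0.65))))
  expect_false(decide_nhst(fake_auc_estimate(c(0.48, 0.62))))
  expect_false(decide_nhst(fake_delta_estimate(c(-0.01, 0.15))))
  expect_true(decide_nhst(fake_delta_estimate(c(0.02, 0.15))))
  # partial single curve: the null is the chance-diagonal area
  chance <- 0.167^2 / 2
  expect_true(decide_nhst(
    fake_auc_estimate(c(chance + 0.001, 0.1), fpr_range = c(0, 0.167))
  ))
  expect_false(decide_nhst(
    fake_auc_estimate(c(chance - 0.001, 0.1), fpr_range = c(0, 0.167))
  ))
  # boundary touches do not reject; degenerate estimates never decide
  expect_false(decide_nhst(fake_auc_estimate(c(0.5, 0.6))))
  expect_false(decide_nhst(fake_auc_estimate(c(0.55, 0.65), degenerate = TRUE)))
})

test_that("MET decision: whole 95% CI beyond the SESOI", {
  expect_true(decide_met(fake_auc_estimate(c(0.61, 0.70)), sesoi = 0.60))
  expect_false(decide_met(fake_auc_estimate(c(0.55, 0.65)), sesoi = 0.60))
  expect_true(decide_met(fake_delta_estimate(c(0.11, 0.20)), sesoi = 0.10))
  expect_false(decide_met(fake_delta_estimate(c(0.10, 0.20)), sesoi = 0.10))
})

test_that("EQ decision: whole 90% CI inside the equivalence region", {
  expect_true(decide_eq(fake_auc_estimate(c(0.4, 0.6), ci90 = c(0.45, 0.55)),
    sesoi = 0.60
  ))
  expect_false(decide_eq(fake_auc_estimate(c(0.5, 0.62), ci90 = c(0.52, 0.61)),
    sesoi = 0.60
  ))
  # the single-curve region is symmetric about 0.5
  expect_false(decide_eq(fake_auc_estimate(c(0.3, 0.5), ci90 = c(0.39, 0.5)),
    sesoi = 0.60
  ))
  expect_true(decide_eq(fake_delta_estimate(c(-0.06, 0.05), ci90 = c(-0.05, 0.04)),
    sesoi = 0.10
  ))
  expect_false(decide_eq(fake_delta_estimate(c(-0.12, 0.05), ci90 = c(-0.11, 0.04)),
    sesoi = 0.10
  ))
})

test_that("configurations are validated before any simulation", {
  expect_error(power_config("single", spec22(0.38), sesoi = 0.4, seed = 1), "sesoi")
  expect_error(power_config("single", spec22(0.38), sesoi = 1.0, seed = 1), "sesoi")
  expect_error(
    power_config("two_unpaired", spec22(0.38),
      spec2 = spec22(0.78),
      sesoi = 0.6, seed = 1
    ),
    "sesoi"
  )
  expect_error(power_config("two_unpaired", spec22(0.38), seed = 1), "spec2")
  expect_error(
    power_config("single", spec22(0.38), spec2 = spec22(0.5), seed = 1),
    "spec2"
  )
  expect_error(power_config("single", spec22(0.38)), "seed")
  expect_warning(
    power_config("single", spec22(0.38),
      seed = 1,
      fpr_range = c(0, 0.167)
    ),
    "scaled down"
  )
})

test_that("power runs are byte-identical under the same seed", {
  cfg <- power_config("single", spec22(0.38, 40),
    sesoi = 0.6,
    n_sims = 60, seed = 123
  )
  r1 <- run_power(cfg)
  r2 <- run_power(cfg)
  expect_identical(report_json(r1), report_json(r2))
  r3 <- run_power(power_config("single", spec22(0.38, 40),
    sesoi = 0.6,
    n_sims = 60, seed = 124
  ))
  expect_false(identical(r1$power_nhst, r3$power_nhst))
})

test_that("a single simulation yields power in {0, 1} with zero MC error", {
  cfg <- power_config("single", spec22(0.38), sesoi = 0.6, n_sims = 1, seed = 2)
  r <- run_power(cfg)
  expect_true(r$power_nhst %in% c(0, 1))
  expect_equal(unname(r$mc_se["nhst"]), 0)
})

test_that("without a SESOI only the NHST power is reported", {
  r <- run_power(power_config("single", spec22(0.38, 30), n_sims = 20, seed = 3))
  expect_false(is.na(r$power_nhst))
  expect_true(is.na(r$power_met) && is.na(r$power_eq))
})

test_that("power is monotone in sample size (up to Monte Carlo slack)", {
  pow <- function(n, seed) {
    run_power(power_config("single", spec22(0.57, n),
      sesoi = 0.6,
      n_sims = 250, seed = seed
    ))
  }
  small <- pow(50, 21)
  big <- pow(200, 22)
  slack <- 2 * (small$mc_se["met"] + big$mc_se["met"])
  expect_gte(big$power_met - small$power_met, -slack)
  expect_gt(big$power_met, small$power_met) # clearly separated here
})

test_that("perfectly separated designs are tallied as degenerate", {
  cfg <- power_config("single", spec22(20, 10), n_sims = 10, seed = 4)
  r <- run_power(cfg)
  expect_equal(r$n_degenerate, 10)
  expect_equal(r$power_nhst, 0) # conservative: degenerate never decides
})

test_that("simulated NHST power agrees with the analytic normal oracle", {
  # full-curve single design; oracle = Hanley-McNeil SE + Wald rejection
  spec <- spec22(0.38)
  true_auc <- estimate_auc_empirical(spec, n_items = 200000, seed = 88)
  analytic <- oracle_power_nhst_single(true_auc, 200, 200)
  r <- run_power(power_config("single", spec, n_sims = 500, seed = 31))
  expect_lt(abs(r$power_nhst - analytic), 0.05)
})

test_that("type1_check returns the boundary rate of the requested test", {
  cfg <- power_config("single", spec22(0, 40), sesoi = 0.6, n_sims = 200, seed = 5)
  rate <- type1_check(cfg, "nhst")
  expect_gte(rate, 0)
  expect_lte(rate, 0.12) # nominal 0.05 within generous binomial slack
  expect_equal(type1_check(cfg, "eq"), run_power(cfg)$power_eq)
})

test_that("paired designs run end to end and gain power from rho", {
  mk <- function(mu, rho) {
    binormal_spec(mu,
      n_participants = 60, items_signal = 2, items_noise = 2,
      rho = rho
    )
  }
  r_cor <- run_power(power_config("two_paired", mk(0.38, 0.8),
    spec2 = mk(0.78, 0.8), sesoi = 0.1, n_sims = 150, seed = 6
  ))
  r_ind <- run_power(power_config("two_unpaired", mk(0.38, 0),
    spec2 = mk(0.78, 0), sesoi = 0.1, n_sims = 150, seed = 6
  ))
  expect_gt(r_cor$power_nhst, r_ind$power_nhst)
})

test_that("power reports serialize with their resolved configuration", {
  cfg <- power_config("single", spec22(0.38, 20), sesoi = 0.6, n_sims = 10, seed = 9)
  r <- run_power(cfg)
  parsed <- jsonlite::fromJSON(report_json(r))
  expect_equal(parsed$power$nhst, r$power_nhst)
  expect_equal(parsed$config$seed, 9)
  expect_equal(parsed$config$spec1$mu_signal, 0.38)
  expect_equal(parsed$n_sims, 10)
})
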