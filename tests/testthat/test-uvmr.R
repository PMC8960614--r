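# Univariate MR estimators and diagnostics.

test_that("wald_ratio computes the single-variant ratio and its SE", {
  r <- wald_ratio(0.5, 0.02, 0.25, 0.1)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(wald_ratio(0.5, 0.02, 0, 0.1)$estimate, 0)
  expect_error(wald_ratio(0, 0.02, 0.25, 0.1), "beta_exp")
})

test_that("ivw matches the hand-computed two-variant case", {
  h <- mk_h(beta_exp = c(1, 1), beta_out = c(0.4, 0.6),
            se_out = c(1, 1))
  r <- mr_ivw(h)
  expect_equal(r$estimate, 0.5)
  q <- cochran_q(h, r$estimate)
  expect_equal(q$q, 0.02)
  # residual scale sqrt(0.02) floored at 1
  expect_equal(r$se, sqrt(1 / 2) * max(1, sqrt(0.02)))
})

test_that("ivw recovers exact proportionality and zero effects", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- mk_h(bx, 0.7 * bx, se_out = rep(0.1, 4))
  r <- mr_ivw(h)
  expect_equal(r$estimate, 0.7)
  expect_equal(cochran_q(h, r$estimate)$q, 0, tolerance = 1e-12)
  expect_equal(mr_ivw(mk_h(bx, rep(0, 4)))$estimate, 0)
  expect_error(mr_ivw(mk_h(c(0, 0), c(0.1, 0.2))), "degenerate")
})

test_that("ivw equals a weighted least-squares oracle", {
  set.seed(21)
  for (rep in 1:20) {
    h <- rand_h(sample(3:15, 1))
    r <- mr_ivw(h)
    w <- 1 / h$se_out^2
    fit <- lm(beta_out ~ 0 + beta_exp, data = as.data.frame(h),
              weights = w)
    expect_equal(r$estimate, unname(coef(fit)), tolerance = 1e-10)
    # the oracle SE rescaled by the floored residual scale
    s <- summary(fit)$sigma
    expect_equal(r$se,
                 unname(sqrt(diag(vcov(fit)))) / s * max(1, s),
                 tolerance = 1e-10)
  }
})

test_that("a single variant reduces the suite estimate to the Wald ratio", {
  h <- mk_h(0.5, 0.2, se_out = 0.1)
  expect_equal(mr_ivw(h)$estimate, wald_ratio(0.5, 0.01, 0.2, 0.1)$estimate)
  expect_equal(mr_ivw(h)$se, wald_ratio(0.5, 0.01, 0.2, 0.1)$se)
})

test_that("egger recovers an exact line and flags rank deficiency", {
  bx <- c(0.1, 0.2, 0.3)
  h <- mk_h(bx, 0.1 + 0.3 * bx, se_out = rep(1, 3))
  r <- mr_egger(h)
  expect_equal(r$intercept$estimate, 0.1, tolerance = 1e-12)
  expect_equal(r$slope$estimate, 0.3, tolerance = 1e-12)
  expect_equal(r$heterogeneity$q, 0, tolerance = 1e-12)
  expect_error(mr_egger(mk_h(rep(0.2, 3), c(0.1, 0.2, 0.3))),
               "rank-deficient")
  expect_error(mr_egger(mk_h(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("egger intercept recovers directional pleiotropy and is centred under balanced pleiotropy", {
  set.seed(22)
  n_rep <- 200
  intercepts_dir <- intercepts_bal <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg_dir <- sim_config(n_snps_trait = 60, n_snps_mediator = 0,
                          beta_XM = 0, pleiotropy_mode = "directional",
                          pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                          invalid_fraction = 1, eaf_range = c(0.35, 0.65))
    sim <- simulate_study(cfg_dir)
    h <- harmonise(sim$trait, sim$outcome)
    intercepts_dir[i] <- mr_egger(h)$intercept$estimate
    cfg_bal <- sim_config(n_snps_trait = 60, n_snps_mediator = 0,
                          beta_XM = 0, pleiotropy_mode = "balanced",
                          pleiotropy_sd = 0.02, invalid_fraction = 1,
                          eaf_range = c(0.35, 0.65))
    sim2 <- simulate_study(cfg_bal)
    h2 <- harmonise(sim2$trait, sim2$outcome)
    intercepts_bal[i] <- mr_egger(h2)$intercept$estimate
  }
  mc_dir <- 3 * sd(intercepts_dir) / sqrt(n_rep)
  expect_lt(abs(mean(intercepts_dir) - 0.05), mc_dir)
  mc_bal <- 3 * sd(intercepts_bal) / sqrt(n_rep)
  expect_lt(abs(mean(intercepts_bal)), mc_bal)
})

test_that("i2gx follows its closed form and truncation", {
  # k = 11, Q_GX = 100: exposure betas engineered via direct formula
  h <- mk_h(beta_exp = c(1, 1), beta_out = c(1, 1), se_exp = c(0.1, 0.1))
  expect_equal(i2gx(h), 0)  # identical betas, Q_GX = 0
  # closed form: i2gx = (Q - (k-1))/Q; construct k=2 with known Q
  h2 <- mk_h(beta_exp = c(0, 2), beta_out = c(0, 0), se_exp = c(0.1, 0.1))
  # v = 100 each, mean = 1, Q = 100*1 + 100*1 = 200; (200 - 1)/200
  expect_equal(i2gx(h2), 199 / 200)
  # truncation at zero when Q <= k - 1
  h3 <- mk_h(beta_exp = c(0.1, 0.1001), beta_out = c(0, 0),
             se_exp = c(1, 1))
  expect_equal(i2gx(h3), 0)
})

test_that("weighted median interpolates cumulative percentiles", {
  h <- mk_h(beta_exp = c(1, 1, 1), beta_out = c(1, 2, 3),
            se_out = c(1, 1, 1))
  r <- weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(r$estimate, 2)
  h2 <- mk_h(beta_exp = c(1, 2, 4), beta_out = 0.4 * c(1, 2, 4))
  expect_equal(weighted_median(h2, n_boot = 50, seed = 1)$estimate, 0.4)
})

test_that("weighted median matches the exhaustive oracle and resists invalid instruments", {
  set.seed(23)
  for (rep in 1:20) {
    h <- rand_h(sample(3:7, 1))
    r <- weighted_median(h, n_boot = 10, seed = 1)
    theta <- h$beta_out / h$beta_exp
    w <- (h$beta_exp / h$se_out)^2
    expect_equal(r$estimate, wm_oracle(theta, w), tolerance = 1e-12)
  }
  # a minority of invalid instruments with strong additive pleiotropy:
  # the weighted median stays on the valid cluster (sample sizes large so
  # the breakdown property, not sampling noise, is what is tested)
  ests <- replicate(50, {
    cfg <- sim_config(n_snps_trait = 40, n_snps_mediator = 0, beta_XM = 0,
                      n_trait = 1e10, n_outcome_gwas = 1e10,
                      pleiotropy_mode = "directional",
                      pleiotropy_mean = 0.08, pleiotropy_sd = 0.005,
                      invalid_fraction = 0.4)
    sim <- simulate_study(cfg)
    h <- harmonise(sim$trait, sim$outcome)
    weighted_median(h, n_boot = 2, seed = 1)$estimate
  })
  expect_lt(abs(mean(ests) - 0.2), 0.005)
})

test_that("mode estimators locate the dominant ratio cluster", {
  bx <- rep(1, 5)
  by <- c(0.3, 0.3, 0.3, 0.3, 2.0)
  h <- mk_h(bx, by, se_out = rep(0.1, 5))
  r <- mode_estimator(h, weighted = FALSE, n_boot = 10, seed = 1)
  theta <- by / bx
  bw <- stats::bw.nrd0(theta)
  grid_step <- (diff(range(theta)) + 6 * bw) / 511
  expect_lt(abs(r$estimate - 0.3), grid_step + 1e-12)
  # independent density-argmax oracle on the same grid
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = 512)
  dens <- sapply(grid, function(g)
    mean(stats::dnorm((g - theta) / bw)) / bw)
  expect_equal(r$estimate, grid[which.max(dens)])
  # weighted mode with the outlier down-weighted
  h2 <- mk_h(bx, by, se_out = c(rep(0.1, 4), 10))
  r2 <- mode_estimator(h2, weighted = TRUE, n_boot = 10, seed = 1)
  expect_lt(abs(r2$estimate - 0.3), grid_step + 1e-12)
  # constant ratios return that value exactly
  h3 <- mk_h(c(1, 2, 3), 0.4 * c(1, 2, 3))
  expect_equal(mode_estimator(h3, n_boot = 5, seed = 1)$estimate, 0.4)
})

test_that("cochran_q scales with weights and vanishes at exact fit", {
  h <- mk_h(c(1, 1), c(0.4, 0.6), se_out = c(1, 1))
  q <- cochran_q(h, 0.5)
  expect_equal(q$q, 0.02)
  expect_equal(q$df, 1)
  h2 <- mk_h(c(1, 1), c(0.4, 0.6), se_out = c(2, 2))
  expect_equal(cochran_q(h2, 0.5)$q, 0.02 / 4)
  h3 <- mk_h(c(1, 2), c(0.5, 1.0))
  expect_equal(cochran_q(h3, 0.5)$q, 0)
  expect_equal(cochran_q(h3, 0.5)$pval, 1)
})

test_that("leave-one-out isolates an outlying variant", {
  bx <- rep(0.2, 6)
  by <- c(rep(0.06, 5), 0.3)   # last variant is a gross outlier
  h <- mk_h(bx, by, se_out = rep(0.05, 6))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 6)
  full <- mr_ivw(h)$estimate
  deltas <- abs(loo$estimate - full)
  expect_equal(which.max(deltas), 6)
  # homogeneous set: all leave-one-out results agree
  h2 <- mk_h(bx, 0.3 * bx)
  expect_equal(var(leave_one_out(h2)$estimate), 0, tolerance = 1e-20)
})

test_that("estimators are order-invariant and equivariant under exposure rescaling", {
  set.seed(24)
  h <- rand_h(12)
  perm <- sample(12)
  hp <- structure(as.data.frame(h)[perm, ],
                  class = c("harmonised_set", "data.frame"))
  expect_equal(mr_ivw(hp)$estimate, mr_ivw(h)$estimate)
  expect_equal(mr_egger(hp)$slope$estimate, mr_egger(h)$slope$estimate)
  expect_equal(weighted_median(hp, 5, 1)$estimate,
               weighted_median(h, 5, 1)$estimate)
  expect_equal(mode_estimator(hp, TRUE, n_boot = 5, seed = 1)$estimate,
               mode_estimator(h, TRUE, n_boot = 5, seed = 1)$estimate)
  for (c_scale in c(0.5, 2, 10)) {
    hs <- h
    hs$beta_exp <- h$beta_exp * c_scale
    hs$se_exp <- h$se_exp * c_scale
    expect_equal(mr_ivw(hs)$estimate, mr_ivw(h)$estimate / c_scale)
    expect_equal(mr_egger(hs)$slope$estimate,
                 mr_egger(h)$slope$estimate / c_scale)
    expect_equal(weighted_median(hs, 5, 1)$estimate,
                 weighted_median(h, 5, 1)$estimate / c_scale)
  }
})

test_that("the suite gates on the minimum instrument count", {
  sim <- simulate_study(sim_config(n_snps_trait = 9, n_snps_mediator = 0,
                                   seed = 31))
  suite <- run_uvmr_suite(sim$trait, sim$outcome, study_config(n_boot = 20))
  expect_false(suite$eligible)
  expect_equal(nrow(suite$results), 0)
  sim2 <- simulate_study(sim_config(n_snps_trait = 25, n_snps_mediator = 0,
                                    seed = 31))
  suite2 <- run_uvmr_suite(sim2$trait, sim2$outcome,
                           study_config(n_boot = 20, seed = 5))
  expect_true(suite2$eligible)
  expect_setequal(suite2$results$method,
                  c("ivw", "egger-slope", "egger-intercept",
                    "weighted-median", "simple-mode", "weighted-mode"))
  ivw_row <- suite2$results[suite2$results$method == "ivw", ]
  expect_false(is.na(ivw_row$q))
  expect_true(ivw_row$ci_low <= ivw_row$estimate &
                ivw_row$estimate <= ivw_row$ci_high)
})
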