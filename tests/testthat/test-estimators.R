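test_that("Wald ratios and their first-order SEs are exact", {
  h <- harmonized_dataset(c(1, 1), c(0.1, 0.1), c(0.5, 0.5), c(0.1, 0.1))
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.5, 0.5))
  expect_equal(wr$se, c(0.1, 0.1))

  h2 <- harmonized_dataset(2, 0.1, 0.8, 0.2)
  wr2 <- wald_ratios(h2)
  expect_equal(wr2$ratio, 0.4)
  expect_equal(wr2$se, 0.1)

  # flipping a SNP's orientation leaves its ratio unchanged
  h3 <- harmonized_dataset(c(1, -1), c(0.1, 0.1), c(0.5, -0.5), c(0.1, 0.1))
  expect_equal(wald_ratios(h3)$ratio, c(0.5, 0.5))

  h4 <- harmonized_dataset(c(0, 1), c(0.1, 0.1), c(0.5, 0.5), c(0.1, 0.1))
  expect_warning(wr4 <- wald_ratios(h4), "zero exposure beta")
  expect_equal(nrow(wr4), 1)
})

test_that("IVW matches the hand-computed weighted least squares oracle", {
  h <- harmonized_dataset(c(1, 2), c(0.01, 0.01), c(0.3, 0.8), c(0.1, 0.2))
  e <- mr_ivw(h)
  # w = (100, 25): theta = (100*0.3 + 25*2*0.8) / (100 + 25*4) = 0.35
  expect_equal(e$beta, 0.35, tolerance = 1e-12)
  expect_equal(e$se_fixed, 1 / sqrt(200), tolerance = 1e-10)
  expect_equal(e$se_fixed, 0.070711, tolerance = 1e-5)
  expect_equal(e$q_stat, 0.5, tolerance = 1e-12)
  expect_equal(e$q_df, 1)
  expect_equal(e$q_pval, pchisq(0.5, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(e$q_pval, 4), 0.4795)
})

test_that("homogeneous ratios give zero Q and no random-effects inflation", {
  h <- harmonized_dataset(c(1, 2, 4), c(0.01, 0.01, 0.01),
                          c(0.3, 0.6, 1.2), c(0.1, 0.1, 0.1))
  e <- mr_ivw(h)
  expect_equal(e$q_stat, 0, tolerance = 1e-20)
  expect_equal(e$se, e$se_fixed)
  q <- cochrans_q(h, e$beta)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
})

test_that("ratio-form and regression-form IVW agree to machine precision", {
  for (seed in 1:50) {
    h <- random_harmonized(sample(3:12, 1), seed)
    e <- mr_ivw(h, model = "fixed")
    wr <- wald_ratios(h)
    ratio_form <- sum(wr$weight * wr$ratio) / sum(wr$weight)
    expect_equal(e$beta, ratio_form, tolerance = 1e-10)
    fit <- lm(h$beta_outcome ~ 0 + h$beta_exposure,
              weights = 1 / h$se_outcome^2)
    expect_equal(e$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("scale equivariance: rescaling exposure betas rescales estimates", {
  h <- random_harmonized(10, 42)
  h2 <- h
  h2$beta_exposure <- h$beta_exposure * 4
  h2$se_exposure <- h$se_exposure * 4
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta / 4, tolerance = 1e-10)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta / 4, tolerance = 1e-10)
  wm1 <- mr_weighted_median(h, n_boot = 100, seed = 1)
  wm2 <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_equal(wm2$beta, wm1$beta / 4, tolerance = 1e-10)
})

test_that("MR-Egger fits collinear points exactly", {
  h <- harmonized_dataset(c(1, 2, 3), c(0.01, 0.01, 0.01),
                          c(0.4, 0.7, 1.0), c(0.1, 0.1, 0.1))
  e <- mr_egger(h)
  expect_equal(e$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
})

test_that("MR-Egger recovers directional pleiotropy as its intercept", {
  # strong, variable instruments; constant pleiotropic offset alpha = 0.02
  ints <- vapply(1:200, function(seed) {
    st <- simulate_two_sample(sim_config(
      n_snps = 60, theta = 0.1, gamma_fixed = c(0.05, 0.15),
      pleiotropy_mode = "directional", pleiotropy_mean = 0.02,
      pleiotropy_sd = 0, palindromic_frac = 0, seed = seed))
    mr_egger(harmonize_synthetic(st))$intercept
  }, numeric(1))
  mc_se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - 0.02), 3 * mc_se + 1e-4)
})

test_that("weighted median interpolates the standardized cumulative weights", {
  expect_equal(mrlink:::weighted_median_estimate(c(0.2, 0.5, 0.9),
                                                 c(1, 1, 1)), 0.5)
  expect_equal(mrlink:::weighted_median_estimate(c(0.1, 0.4, 1.0),
                                                 c(1, 1, 2)), 0.6)
  # invariant to input order
  expect_equal(mrlink:::weighted_median_estimate(c(1.0, 0.1, 0.4),
                                                 c(2, 1, 1)), 0.6)
})

test_that("weighted median tracks the weighted absolute-deviation minimizer", {
  # with equal weights and odd J it is exactly the sample median
  set.seed(31)
  x <- rnorm(11)
  expect_equal(mrlink:::weighted_median_estimate(x, rep(1, 11)), median(x))
  # with random weights it lies within one inter-ratio gap of the grid
  # minimizer (interpolation smooths the order-statistic solution)
  for (seed in 1:10) {
    set.seed(seed)
    x <- sort(rnorm(51))
    w <- runif(51, 0.5, 2)
    est <- mrlink:::weighted_median_estimate(x, w)
    opt <- wad_grid_minimizer(x, w, step = 1e-3)
    gap <- max(diff(x))
    expect_lt(abs(est - opt), gap + 1e-3)
  }
})

test_that("weighted-median bootstrap SE is reproducible and seed-mandatory", {
  h <- random_harmonized(10, 7)
  a <- mr_weighted_median(h, n_boot = 200, seed = 5)
  b <- mr_weighted_median(h, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(h, n_boot = 200),
               class = "mrlink_config_error")
})

test_that("leave-one-out flags the dominant SNP and has length J", {
  h <- harmonized_dataset(rep(1, 6), rep(0.01, 6),
                          c(rep(0.5, 5), 0.5), rep(0.1, 6))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 6)
  expect_equal(loo$beta, rep(0.5, 6), tolerance = 1e-12)

  h2 <- harmonized_dataset(rep(1, 6), rep(0.01, 6),
                           c(rep(0.5, 5), 1.5), rep(0.1, 6))
  loo2 <- mr_leave_one_out(h2)
  shifts <- abs(loo2$beta - attr(loo2, "full")$beta)
  expect_equal(which.max(shifts), 6)
})

test_that("estimator means converge to theta without pleiotropy", {
  res <- vapply(1:120, function(seed) {
    st <- simulate_two_sample(sim_config(
      n_snps = 30, theta = 0.157, gamma_fixed = c(0.05, 0.15),
      palindromic_frac = 0, seed = seed))
    h <- harmonize_synthetic(st)
    c(mr_ivw(h)$beta,
      mr_weighted_median(h, n_boot = 100, seed = seed)$beta,
      mr_egger(h)$beta)
  }, numeric(3))
  for (i in 1:3) {
    mc_se <- sd(res[i, ]) / sqrt(ncol(res))
    expect_lt(abs(mean(res[i, ]) - 0.157), 3 * mc_se,
              label = sprintf("estimator %d bias", i))
  }
})
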