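make_mvmr <- function(j, e, seed, beta = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(j * e, 0, 0.1), j, e,
              dimnames = list(NULL, sprintf("x%d", seq_len(e))))
  se_y <- runif(j, 0.01, 0.05)
  by <- if (is.null(beta)) rnorm(j, 0, 0.05) else as.vector(x %*% beta)
  structure(list(snp = sprintf("rs%d", seq_len(j)),
                 beta_exposure = x,
                 se_exposure = matrix(0.01, j, e,
                                      dimnames = dimnames(x)),
                 beta_outcome = by, se_outcome = se_y),
            class = "mvmr_dataset")
}

test_that("an exact linear construction is recovered exactly", {
  d <- make_mvmr(8, 2, 1, beta = c(0.5, 0))
  fit <- mvmr_ivw(d)
  expect_equal(fit$estimates$x1$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$estimates$x2$beta, 0, tolerance = 1e-10)
})

test_that("coefficients match the weighted normal-equations oracle", {
  for (seed in 1:25) {
    d <- make_mvmr(8, 2, seed)
    fit <- mvmr_ivw(d)
    w <- 1 / d$se_outcome^2
    xtwx <- t(d$beta_exposure) %*% (w * d$beta_exposure)
    xtwy <- t(d$beta_exposure) %*% (w * d$beta_outcome)
    oracle <- solve(xtwx, xtwy)
    expect_equal(fit$estimates$x1$beta, oracle[1], tolerance = 1e-10)
    expect_equal(fit$estimates$x2$beta, oracle[2], tolerance = 1e-10)
  }
})

test_that("with one exposure the multivariable fit is univariable IVW", {
  h <- random_harmonized(12, 3)
  d <- structure(list(snp = h$snp,
                      beta_exposure = matrix(h$beta_exposure,
                                             dimnames = list(NULL, "x")),
                      se_exposure = matrix(h$se_exposure,
                                           dimnames = list(NULL, "x")),
                      beta_outcome = h$beta_outcome,
                      se_outcome = h$se_outcome),
                 class = "mvmr_dataset")
  fit <- mvmr_ivw(d)
  uni <- mr_ivw(h)
  expect_equal(fit$estimates$x$beta, uni$beta, tolerance = 1e-12)
  expect_equal(fit$estimates$x$se, uni$se, tolerance = 1e-12)
})

test_that("collinear exposures raise an error naming the culprit", {
  d <- make_mvmr(8, 2, 4)
  d$beta_exposure[, 2] <- 2 * d$beta_exposure[, 1]
  expect_error(mvmr_ivw(d), "collinear",
               class = "mrlink_estimation_error")
  expect_error(mvmr_ivw(make_mvmr(3, 2, 1)),
               class = "mrlink_estimation_error")
})

test_that("adjusting for a full mediator attenuates the direct effect", {
  # exposure acts on the outcome only through the mediator: the direct
  # effect of the exposure conditional on the mediator is beta_direct
  reps <- vapply(1:100, function(seed) {
    st <- simulate_mediation_chain(sim_config(
      gamma_fixed = c(0.05, 0.15), n_outcome = 1000000,
      palindromic_frac = 0,
      mediator_spec = list(beta_xm = 0.5, beta_my = 0.4, beta_direct = 0.1,
                           n_mediator = 300000, n_mediator_snps = 60),
      seed = seed))
    ds <- make_mvmr_dataset(
      exposures = list(exposure = st$exposure_stats,
                       mediator = st$mediator_stats),
      outcome = st$outcome_stats)
    mvmr_ivw(ds)$estimates$exposure$beta
  }, numeric(1))
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.1), 3 * mc_se + 0.005)
})

test_that("delta-method combination matches hand-computed values", {
  m <- two_step_mediation(0.4, 0, 0.5, 0, 0.8, 0)
  expect_equal(m$indirect$beta, 0.2)
  expect_equal(m$indirect$se, 0)
  expect_equal(m$proportion$estimate, 0.25)

  m2 <- two_step_mediation(0.4, 0.1, 0.5, 0.2, 0.8, 0.05)
  expect_equal(m2$indirect$se, sqrt(0.25 * 0.01 + 0.16 * 0.04),
               tolerance = 1e-12)
  expect_equal(m2$indirect$se, 0.094340, tolerance = 1e-5)
  expect_lt(m2$proportion$ci_low, m2$proportion$ci_high)
})

test_that("the indirect effect is sign-consistent", {
  base <- two_step_mediation(0.4, 0.1, 0.5, 0.2, 0.8, 0.05)
  both <- two_step_mediation(-0.4, 0.1, -0.5, 0.2, 0.8, 0.05)
  one <- two_step_mediation(-0.4, 0.1, 0.5, 0.2, 0.8, 0.05)
  expect_equal(both$indirect$beta, base$indirect$beta)
  expect_equal(both$indirect$se, base$indirect$se)
  expect_equal(one$indirect$beta, -base$indirect$beta)
})

test_that("a zero total effect leaves the proportion undefined", {
  expect_warning(m <- two_step_mediation(0.4, 0.1, 0.5, 0.2, 0, 0.05),
                 "undefined")
  expect_equal(m$indirect$beta, 0.2)
  expect_true(is.na(m$proportion$estimate))
})

test_that("the noiseless chain recovers its proportion to numerical precision", {
  cfg <- sim_config(gamma_fixed = c(0.03, 0.08), noiseless = TRUE,
                    palindromic_frac = 0,
                    mediator_spec = list(beta_xm = 0.5, beta_my = 0.4,
                                         beta_direct = 0.6,
                                         n_mediator = 300000,
                                         n_mediator_snps = 30),
                    seed = 12)
  st <- simulate_mediation_chain(cfg)
  expect_equal(st$truth$proportion_mediated, 0.25)
  med <- run_mediation(st$exposure_stats, st$mediator_stats,
                       st$outcome_stats)
  expect_equal(med$proportion$estimate, 0.25, tolerance = 1e-6)
  expect_equal(med$indirect$beta, 0.2, tolerance = 1e-6)
})

test_that("with no direct path the noiseless proportion mediated is 100%", {
  cfg <- sim_config(gamma_fixed = c(0.03, 0.08), noiseless = TRUE,
                    palindromic_frac = 0,
                    mediator_spec = list(beta_xm = 0.5, beta_my = 0.4,
                                         beta_direct = 0,
                                         n_mediator = 300000,
                                         n_mediator_snps = 30),
                    seed = 13)
  st <- simulate_mediation_chain(cfg)
  med <- run_mediation(st$exposure_stats, st$mediator_stats,
                       st$outcome_stats)
  expect_equal(med$proportion$estimate, 1, tolerance = 1e-6)
})

test_that("mediation step failures carry their step label", {
  st <- simulate_mediation_chain(sim_config(
    gamma_fixed = 0.001,  # far too weak to reach genome-wide significance
    mediator_spec = list(beta_xm = 0.5, beta_my = 0.4, beta_direct = 0.6,
                         n_mediator = 300000, n_mediator_snps = 5),
    seed = 14))
  expect_error(run_mediation(st$exposure_stats, st$mediator_stats,
                             st$outcome_stats),
               "step1", class = "mrlink_instrument_error")
})
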