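test_that("identical config and seed reproduce the study exactly", {
  cfg <- sim_config(n_snps = 60, theta = 0.1, seed = 7)
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a$exposure_stats, b$exposure_stats)
  expect_identical(a$outcome_stats, b$outcome_stats)
  expect_identical(a$truth$gamma, b$truth$gamma)
})

test_that("noiseless limit makes every Wald ratio equal theta", {
  cfg <- sim_config(n_snps = 20, theta = 0.5, gamma_fixed = c(0.02, 0.08),
                    noiseless = TRUE, seed = 3)
  st <- simulate_two_sample(cfg)
  ratios <- st$outcome_stats$beta / st$exposure_stats$beta
  expect_equal(ratios, rep(0.5, 20), tolerance = 1e-12)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_two_sample(sim_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("observed exposure betas have the advertised sampling SD", {
  cfg <- sim_config(n_snps = 3, gamma_fixed = 0.05, maf_low = 0.3,
                    maf_high = 0.3001, n_exposure = 50000)
  reps <- 1500
  betas <- vapply(seq_len(reps), function(r) {
    c2 <- cfg; c2$seed <- r
    simulate_two_sample(c2)$exposure_stats$beta[2]
  }, numeric(1))
  se_expected <- 1 / sqrt(2 * 0.3 * 0.7 * 50000)
  expect_lt(abs(sd(betas) / se_expected - 1), 0.05)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(maf_low = 0), "maf_low",
               class = "mrlink_config_error")
  expect_error(sim_config(maf_high = 0.6), "maf_high",
               class = "mrlink_config_error")
  expect_error(sim_config(n_snps = 2), "n_snps",
               class = "mrlink_config_error")
  expect_error(sim_config(pleiotropy_sd = -1), "pleiotropy_sd",
               class = "mrlink_config_error")
  expect_error(sim_config(n_snps = 6,
                          ld_spec = list(block_sizes = c(3, 3), rho = 1)),
               "rho", class = "mrlink_config_error")
  expect_error(sim_config(n_snps = 6,
                          ld_spec = list(block_sizes = c(3, 2), rho = 0.5)),
               "block_sizes", class = "mrlink_config_error")
})

test_that("palindromic allele pairs appear at the configured fraction", {
  cfg <- sim_config(n_snps = 50, palindromic_frac = 0.2, seed = 5)
  st <- simulate_two_sample(cfg)
  pal <- with(st$exposure_stats,
              paste0(effect_allele, other_allele) %in%
                c("AT", "TA", "GC", "CG"))
  expect_equal(sum(pal), 10)
  expect_identical(st$exposure_stats$effect_allele,
                   st$outcome_stats$effect_allele)
})

test_that("mediation truth bookkeeping matches the generating algebra", {
  grid <- expand.grid(bxm = c(-0.4, 0, 0.5), bmy = c(0.2, 0.4),
                      bd = c(0.3, 0.8))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- sim_config(mediator_spec = list(
      beta_xm = g$bxm, beta_my = g$bmy, beta_direct = g$bd,
      n_mediator = 100000, n_mediator_snps = 5), seed = i)
    st <- simulate_mediation_chain(cfg)
    expect_equal(st$truth$proportion_mediated,
                 g$bxm * g$bmy / (g$bd + g$bxm * g$bmy), tolerance = 1e-12)
  }
})

test_that("a broken chain has zero proportion mediated", {
  cfg <- sim_config(mediator_spec = list(
    beta_xm = 0, beta_my = 0.4, beta_direct = 0.8, n_mediator = 100000),
    seed = 1)
  st <- simulate_mediation_chain(cfg)
  expect_equal(st$truth$proportion_mediated, 0)
  expect_length(st$truth$mediator_specific_snps, 60)
})

test_that("mediator_spec is mandatory for the chain simulator", {
  expect_error(simulate_mediation_chain(sim_config(seed = 1)),
               "mediator_spec", class = "mrlink_config_error")
})

test_that("LD panel structure matches its specification", {
  cfg <- sim_config(n_snps = 6, ld_spec = list(block_sizes = c(3, 3),
                                               rho = 0), seed = 2)
  st <- simulate_ld_panel(cfg)
  expect_equal(unname(st$ld_matrix), diag(6))

  cfg2 <- sim_config(n_snps = 6, ld_spec = list(block_sizes = c(3, 3),
                                                rho = 0.9), seed = 2)
  st2 <- simulate_ld_panel(cfg2)
  expect_true(isSymmetric(st2$ld_matrix))
  expect_equal(unname(diag(st2$ld_matrix)), rep(1, 6))
  expect_equal(st2$ld_matrix["rs1", "rs2"], 0.9)
  expect_equal(st2$ld_matrix["rs1", "rs4"], 0)
  # blocks are placed farther apart than the default clumping window
  expect_gt(abs(st2$exposure_stats$pos[4] - st2$exposure_stats$pos[3]),
            10000 * 1000)
})

test_that("near-perfect LD within a single block leaves one clumping survivor", {
  cfg <- sim_config(n_snps = 5, gamma_fixed = 0.05,
                    ld_spec = list(block_sizes = 5, rho = 0.99), seed = 4)
  st <- simulate_ld_panel(cfg)
  surv <- clump(st$exposure_stats, st$ld_matrix)
  expect_equal(nrow(surv), 1)
})
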