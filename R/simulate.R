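#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Builds and validates the parameter set that drives [simulate_two_sample()],
#' [simulate_mediation_chain()] and [simulate_ld_panel()]. The generative
#' model works entirely on the summary-statistic scale: for SNP `j` a minor
#' allele frequency `p_j ~ Uniform(maf_low, maf_high)` is drawn, the true
#' SNP-exposure effect is `gamma_j ~ Normal(0, gamma_sd^2)` (or a fixed
#' magnitude `gamma_fixed`), and the per-study standard errors follow the
#' standardized-trait approximation `1 / sqrt(2 p (1 - p) n)`. Observed
#' effects are `beta_X ~ Normal(gamma, se_X^2)` and
#' `beta_Y ~ Normal(theta * gamma + alpha, se_Y^2)`, where `alpha` is the
#' direct (horizontally pleiotropic) SNP-outcome effect controlled by
#' `pleiotropy_mode`. Binary outcomes are simulated directly on the log-odds
#' scale; the analysis never sees individual-level data.
#'
#' @param n_snps Number of exposure instruments to simulate (>= 3).
#' @param n_exposure,n_outcome GWAS sample sizes for the exposure and the
#'   outcome study; drive the per-SNP standard errors.
#' @param theta True causal effect of the exposure on the outcome (log-odds
#'   per SD for a binary outcome).
#' @param maf_low,maf_high Bounds of the uniform allele-frequency
#'   distribution; must satisfy `0 < maf_low <= maf_high < 0.5`.
#' @param gamma_sd Standard deviation of the true SNP-exposure effects. The
#'   default 0.022 gives the instrument set a total variance explained of
#'   about 1% at the default `n_snps = 60` and allele-frequency range.
#' @param gamma_fixed Optional fixed magnitude for the true SNP-exposure
#'   effects (all positive), or a length-2 `(low, high)` range from which
#'   magnitudes are drawn uniformly; overrides `gamma_sd`. Useful for
#'   oracle tests and strong-instrument regimes (a range keeps the
#'   exposure-beta spread MR-Egger needs for identification).
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (`alpha ~ N(0, s^2)`),
#'   `"directional"` (`alpha ~ N(m, s^2)`) or `"inside_violated"`
#'   (`alpha = kappa * gamma + N(m, s^2)`, correlated pleiotropy).
#' @param pleiotropy_mean,pleiotropy_sd Mean `m` and SD `s` of the direct
#'   SNP-outcome effects.
#' @param pleiotropy_frac Fraction of SNPs carrying a pleiotropic effect
#'   (the count is deterministic, `round(frac * n_snps)`; membership is
#'   drawn from the seed).
#' @param kappa Slope linking `alpha` to `gamma` under `"inside_violated"`.
#' @param n_outliers,outlier_shift Number of planted gross outliers and the
#'   size of their outcome-beta shift in units of the SNP's outcome SE.
#' @param palindromic_frac Fraction of SNPs given palindromic (A/T or G/C)
#'   allele pairs so that harmonization logic is exercised.
#' @param mediator_spec Optional list for [simulate_mediation_chain()]:
#'   `beta_xm` (exposure to mediator), `beta_my` (mediator to outcome),
#'   `beta_direct` (exposure to outcome not via the mediator), `n_mediator`
#'   (mediator GWAS sample size), `n_mediator_snps` (mediator-specific
#'   instruments, default 60) and `gamma_sd_mediator` (their effect SD,
#'   default `gamma_sd`).
#' @param ld_spec Optional list for [simulate_ld_panel()]: `block_sizes`
#'   (integer vector summing to `n_snps`), `rho` (within-block pairwise
#'   correlation, `|rho| < 1`), `spacing_kb` (within-block SNP spacing,
#'   default 1) and `gap_kb` (distance between blocks, default 20000 so
#'   blocks fall outside the default 10,000-kb clumping window).
#' @param noiseless If `TRUE`, observed betas equal their expectations
#'   (standard errors are still reported), so every Wald ratio equals
#'   `theta` exactly; used for identifiability oracles.
#' @param seed Integer seed; the same configuration and seed always
#'   reproduce the same study byte for byte.
#'
#' @return An object of class `mr_sim_config` (a validated list).
#' @export
sim_config <- function(n_snps = 60,
                       n_exposure = 329821,
                       n_outcome = 403124,
                       theta = 0,
                       maf_low = 0.05,
                       maf_high = 0.45,
                       gamma_sd = 0.022,
                       gamma_fixed = NULL,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violated"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       pleiotropy_frac = 1,
                       kappa = 0,
                       n_outliers = 0,
                       outlier_shift = 10,
                       palindromic_frac = 0.1,
                       mediator_spec = NULL,
                       ld_spec = NULL,
                       noiseless = FALSE,
                       seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  config <- list(
    n_snps = n_snps, n_exposure = n_exposure, n_outcome = n_outcome,
    theta = theta, maf_low = maf_low, maf_high = maf_high,
    gamma_sd = gamma_sd, gamma_fixed = gamma_fixed,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_frac = pleiotropy_frac,
    kappa = kappa, n_outliers = n_outliers, outlier_shift = outlier_shift,
    palindromic_frac = palindromic_frac, mediator_spec = mediator_spec,
    ld_spec = ld_spec, noiseless = isTRUE(noiseless), seed = seed
  )
  class(config) <- "mr_sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  fail <- function(field, msg) {
    stop_mrlink(sprintf("invalid configuration field '%s': %s", field, msg),
                "mrlink_config_error")
  }
  for (f in c("n_snps", "n_exposure", "n_outcome", "theta", "maf_low",
              "maf_high", "gamma_sd", "pleiotropy_mean", "pleiotropy_sd",
              "pleiotropy_frac", "kappa", "n_outliers", "outlier_shift",
              "palindromic_frac")) {
    assert_scalar_number(config[[f]], f)
  }
  if (config$n_snps < 3) fail("n_snps", "must be >= 3")
  if (config$n_exposure < 2) fail("n_exposure", "must be >= 2")
  if (config$n_outcome < 2) fail("n_outcome", "must be >= 2")
  if (!(config$maf_low > 0)) fail("maf_low", "must be > 0")
  if (config$maf_low > config$maf_high) fail("maf_low", "must be <= maf_high")
  if (!(config$maf_high < 0.5)) fail("maf_high", "must be < 0.5")
  if (config$gamma_sd < 0) fail("gamma_sd", "must be >= 0")
  if (config$pleiotropy_sd < 0) fail("pleiotropy_sd", "must be >= 0")
  if (config$pleiotropy_frac < 0 || config$pleiotropy_frac > 1) {
    fail("pleiotropy_frac", "must lie in [0, 1]")
  }
  if (config$palindromic_frac < 0 || config$palindromic_frac > 1) {
    fail("palindromic_frac", "must lie in [0, 1]")
  }
  if (config$n_outliers < 0 || config$n_outliers > config$n_snps) {
    fail("n_outliers", "must lie in [0, n_snps]")
  }
  gf <- config$gamma_fixed
  if (!is.null(gf)) {
    if (!is.numeric(gf) || !length(gf) %in% 1:2 || any(!is.finite(gf))) {
      fail("gamma_fixed", "must be one magnitude or a (low, high) range")
    }
  }
  ms <- config$mediator_spec
  if (!is.null(ms)) {
    for (f in c("beta_xm", "beta_my", "beta_direct", "n_mediator")) {
      if (is.null(ms[[f]])) fail(paste0("mediator_spec$", f), "is required")
      assert_scalar_number(ms[[f]], paste0("mediator_spec$", f))
    }
    if (ms$n_mediator < 2) fail("mediator_spec$n_mediator", "must be >= 2")
  }
  ls <- config$ld_spec
  if (!is.null(ls)) {
    if (is.null(ls$block_sizes) || is.null(ls$rho)) {
      fail("ld_spec", "must supply block_sizes and rho")
    }
    if (sum(ls$block_sizes) != config$n_snps) {
      fail("ld_spec$block_sizes", "must sum to n_snps")
    }
    if (any(ls$block_sizes < 1)) fail("ld_spec$block_sizes", "must be >= 1")
    if (abs(ls$rho) >= 1) fail("ld_spec$rho", "must satisfy |rho| < 1")
    m <- max(ls$block_sizes)
    if (m > 1 && ls$rho <= -1 / (m - 1)) {
      fail("ld_spec$rho", "implied block correlation is not positive definite")
    }
  }
  invisible(config)
}

# Deterministic allele pairs with a configurable palindromic fraction.
draw_alleles <- function(n, palindromic_frac) {
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
  nonpal <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("G", "T"),
                 c("C", "A"), c("C", "T"), c("T", "G"), c("T", "C"))
  n_pal <- round(palindromic_frac * n)
  is_pal <- rep(FALSE, n)
  if (n_pal > 0) is_pal[sample.int(n, n_pal)] <- TRUE
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    pair <- if (is_pal[i]) pal_pairs[[sample.int(4, 1)]] else
      nonpal[[sample.int(8, 1)]]
    ea[i] <- pair[1]
    oa[i] <- pair[2]
  }
  data.frame(effect_allele = ea, other_allele = oa, palindromic = is_pal,
             stringsAsFactors = FALSE)
}

draw_gamma <- function(config, n) {
  gf <- config$gamma_fixed
  if (is.null(gf)) {
    stats::rnorm(n, 0, config$gamma_sd)
  } else if (length(gf) == 2) {
    stats::runif(n, abs(gf[1]), abs(gf[2]))   # strong, variable magnitudes
  } else {
    rep(abs(gf), n)
  }
}

draw_alpha <- function(config, gamma) {
  n <- length(gamma)
  alpha <- switch(config$pleiotropy_mode,
    none = rep(0, n),
    balanced = stats::rnorm(n, 0, config$pleiotropy_sd),
    directional = stats::rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd),
    inside_violated = config$kappa * gamma +
      stats::rnorm(n, config$pleiotropy_mean, config$pleiotropy_sd)
  )
  k <- round(config$pleiotropy_frac * n)
  active <- rep(FALSE, n)
  if (k > 0 && config$pleiotropy_mode != "none") {
    active[sample.int(n, k)] <- TRUE
  }
  list(alpha = ifelse(active, alpha, 0), active = active)
}

make_stats <- function(snp, chrom, pos, alleles, eaf, mean_beta, se, n,
                       noiseless) {
  beta <- if (noiseless) mean_beta else stats::rnorm(length(snp), mean_beta, se)
  data.frame(
    snp = snp, chrom = chrom, pos = pos,
    effect_allele = alleles$effect_allele,
    other_allele = alleles$other_allele,
    eaf = eaf, beta = beta, se = se,
    pval = pmax(two_sided_p(beta / se), .Machine$double.xmin),
    samplesize = n, stringsAsFactors = FALSE
  )
}

#' Simulate a two-sample MR study with known ground truth
#'
#' Generates matched exposure and outcome GWAS summary tables under the
#' generative model described in [sim_config()], including optional
#' horizontal pleiotropy and planted gross outliers. The returned `truth`
#' element records every generating quantity so estimator bias, test
#' calibration and outlier detection can be scored exactly.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `mr_synthetic_study`: a list with
#'   `exposure_stats` and `outcome_stats` summary tables (columns `snp`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `samplesize`), a `truth` list, and `NULL` placeholders for
#'   `mediator_stats` and `ld_matrix`.
#' @export
simulate_two_sample <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    j <- config$n_snps
    snp <- sprintf("rs%d", seq_len(j))
    chrom <- rep("1", j)
    pos <- seq_len(j) * 1e6
    maf <- stats::runif(j, config$maf_low, config$maf_high)
    alleles <- draw_alleles(j, config$palindromic_frac)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    gamma <- draw_gamma(config, j)
    pl <- draw_alpha(config, gamma)

    exposure <- make_stats(snp, chrom, pos, alleles, maf, gamma, se_x,
                           config$n_exposure, config$noiseless)
    outcome <- make_stats(snp, chrom, pos, alleles, maf,
                          config$theta * gamma + pl$alpha, se_y,
                          config$n_outcome, config$noiseless)
    outlier_snps <- character(0)
    if (config$n_outliers > 0) {
      idx <- sample.int(j, config$n_outliers)
      outcome$beta[idx] <- outcome$beta[idx] +
        config$outlier_shift * outcome$se[idx]
      outcome$pval <- pmax(two_sided_p(outcome$beta / outcome$se),
                           .Machine$double.xmin)
      outlier_snps <- snp[idx]
    }
    structure(list(
      exposure_stats = exposure,
      outcome_stats = outcome,
      mediator_stats = NULL,
      exposure2_stats = NULL,
      ld_matrix = NULL,
      truth = list(
        theta = config$theta, gamma = stats::setNames(gamma, snp),
        alpha = stats::setNames(pl$alpha, snp),
        pleiotropic_snps = snp[pl$active],
        outlier_snps = outlier_snps,
        config = config
      )
    ), class = "mr_synthetic_study")
  })
}

#' Simulate an exposure-mediator-outcome chain
#'
#' Extends [simulate_two_sample()] with a mediator study: for the exposure's
#' instruments the mediator effect is `beta_xm * gamma`, and the outcome
#' effect decomposes into a direct path `beta_direct * gamma` and an
#' indirect path `beta_xm * beta_my * gamma`. The mediator additionally
#' carries its own instruments (null for the exposure) so that
#' mediator-to-outcome effects are identifiable. The true proportion
#' mediated, `beta_xm * beta_my / (beta_direct + beta_xm * beta_my)`, is
#' recorded in `truth$proportion_mediated`.
#'
#' @inheritParams simulate_two_sample
#' @return An `mr_synthetic_study` whose `mediator_stats` table covers both
#'   the shared-pathway SNPs and the mediator-specific instruments; the
#'   latter are flagged in `truth$mediator_specific_snps`.
#' @export
simulate_mediation_chain <- function(config) {
  validate_sim_config(config)
  ms <- config$mediator_spec
  if (is.null(ms)) {
    stop_mrlink("mediator_spec is required for simulate_mediation_chain",
                "mrlink_config_error")
  }
  with_seed(config$seed, {
    j <- config$n_snps
    k <- as.integer(ms$n_mediator_snps %||% 60)
    gamma_sd_m <- ms$gamma_sd_mediator %||% config$gamma_sd
    n <- j + k
    snp <- sprintf("rs%d", seq_len(n))
    chrom <- rep("1", n)
    pos <- seq_len(n) * 1e6
    maf <- stats::runif(n, config$maf_low, config$maf_high)
    alleles <- draw_alleles(n, config$palindromic_frac)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_m <- 1 / sqrt(2 * maf * (1 - maf) * ms$n_mediator)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)

    gamma <- c(draw_gamma(config, j), rep(0, k))          # exposure effects
    cfg_m <- config
    cfg_m$gamma_sd <- gamma_sd_m
    gamma_m <- c(rep(0, j), draw_gamma(cfg_m, k))
    pl <- draw_alpha(config, gamma)

    mean_x <- gamma
    mean_m <- ms$beta_xm * gamma + gamma_m
    total_slope <- ms$beta_direct + ms$beta_xm * ms$beta_my
    mean_y <- total_slope * gamma + ms$beta_my * gamma_m + pl$alpha

    exposure <- make_stats(snp, chrom, pos, alleles, maf, mean_x, se_x,
                           config$n_exposure, config$noiseless)
    mediator <- make_stats(snp, chrom, pos, alleles, maf, mean_m, se_m,
                           ms$n_mediator, config$noiseless)
    outcome <- make_stats(snp, chrom, pos, alleles, maf, mean_y, se_y,
                          config$n_outcome, config$noiseless)
    structure(list(
      exposure_stats = exposure,
      outcome_stats = outcome,
      mediator_stats = mediator,
      exposure2_stats = NULL,
      ld_matrix = NULL,
      truth = list(
        theta = total_slope,
        beta_xm = ms$beta_xm, beta_my = ms$beta_my,
        beta_direct = ms$beta_direct,
        indirect = ms$beta_xm * ms$beta_my,
        total = total_slope,
        proportion_mediated = if (total_slope == 0) NA_real_ else
          ms$beta_xm * ms$beta_my / total_slope,
        gamma = stats::setNames(gamma, snp),
        gamma_mediator = stats::setNames(gamma_m, snp),
        mediator_specific_snps = snp[seq.int(j + 1, length.out = k)],
        pleiotropic_snps = snp[pl$active],
        config = config
      )
    ), class = "mr_synthetic_study")
  })
}

#' Simulate a block-structured LD panel
#'
#' Builds a block-diagonal SNP correlation matrix (pairwise correlation
#' `rho` within each block, zero across blocks) and draws exposure and
#' outcome effects whose signal and noise are correlated accordingly, so
#' SNPs within a block share association signal. SNPs within a block are
#' placed `spacing_kb` apart and successive blocks `gap_kb` apart on one
#' chromosome, making the clumping window rule testable.
#'
#' @inheritParams simulate_two_sample
#' @return An `mr_synthetic_study` with a populated `ld_matrix` (symmetric,
#'   unit diagonal, dimnames = SNP ids).
#' @export
simulate_ld_panel <- function(config) {
  validate_sim_config(config)
  ls <- config$ld_spec
  if (is.null(ls)) {
    stop_mrlink("ld_spec is required for simulate_ld_panel",
                "mrlink_config_error")
  }
  with_seed(config$seed, {
    j <- config$n_snps
    blocks <- as.integer(ls$block_sizes)
    rho <- ls$rho
    spacing <- (ls$spacing_kb %||% 1) * 1000
    gap <- (ls$gap_kb %||% 20000) * 1000

    snp <- sprintf("rs%d", seq_len(j))
    block_id <- rep(seq_along(blocks), blocks)
    within_idx <- unlist(lapply(blocks, seq_len))
    pos <- (block_id - 1) * gap + (within_idx - 1) * spacing + 1
    chrom <- rep("1", j)

    ld <- matrix(0, j, j, dimnames = list(snp, snp))
    for (b in seq_along(blocks)) {
      idx <- which(block_id == b)
      ld[idx, idx] <- rho
    }
    diag(ld) <- 1

    maf <- stats::runif(j, config$maf_low, config$maf_high)
    alleles <- draw_alleles(j, config$palindromic_frac)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)

    # one causal signal per block; marginal effects are LD-propagated
    causal <- rep(0, j)
    causal[match(unique(block_id), block_id)] <- draw_gamma(config,
                                                            length(blocks))
    marginal <- as.vector(ld %*% causal)

    # correlated sampling noise via the (positive-definite) block cholesky
    cl <- chol(ld)
    noise_x <- as.vector(t(cl) %*% stats::rnorm(j)) * se_x
    noise_y <- as.vector(t(cl) %*% stats::rnorm(j)) * se_y
    beta_x <- if (config$noiseless) marginal else marginal + noise_x
    beta_y <- if (config$noiseless) config$theta * marginal else
      config$theta * marginal + noise_y

    mk <- function(beta, se, n) data.frame(
      snp = snp, chrom = chrom, pos = pos,
      effect_allele = alleles$effect_allele,
      other_allele = alleles$other_allele,
      eaf = maf, beta = beta, se = se,
      pval = pmax(two_sided_p(beta / se), .Machine$double.xmin),
      samplesize = n, stringsAsFactors = FALSE
    )
    structure(list(
      exposure_stats = mk(beta_x, se_x, config$n_exposure),
      outcome_stats = mk(beta_y, se_y, config$n_outcome),
      mediator_stats = NULL,
      exposure2_stats = NULL,
      ld_matrix = ld,
      truth = list(theta = config$theta, block_id = stats::setNames(block_id, snp),
                   causal = stats::setNames(causal, snp), config = config)
    ), class = "mr_synthetic_study")
  })
}
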