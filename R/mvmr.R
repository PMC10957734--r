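#' Assemble a multivariable MR dataset
#'
#' Builds the per-SNP design for multivariable MR: an instrument set (by
#' default the union of each exposure's genome-wide significant SNPs,
#' clumped across exposures on the smallest per-SNP p-value when an LD
#' matrix is supplied), with every exposure's effects and the outcome's
#' effects harmonized to the first exposure's effect alleles. SNPs missing
#' from any table are dropped.
#'
#' @param exposures Named list (length >= 2) of summary tables; the first
#'   exposure's alleles are the reference orientation.
#' @param outcome Outcome summary table.
#' @param p_threshold Instrument-selection threshold per exposure.
#' @param instruments Optional explicit character vector of SNP ids to use
#'   as the instrument set (overrides selection), e.g. only the mediator's
#'   instruments in a two-step mediation.
#' @param ld_matrix,r2_threshold,window_kb Optional clumping inputs, see
#'   [clump()].
#' @param palindrome_policy,eaf_threshold Harmonization settings.
#' @return Object of class `mvmr_dataset`: list with `snp`,
#'   `beta_exposure` / `se_exposure` (J x E matrices, colnames = exposure
#'   labels), `beta_outcome`, `se_outcome`.
#' @export
make_mvmr_dataset <- function(exposures, outcome, p_threshold = 5e-8,
                              instruments = NULL, ld_matrix = NULL,
                              r2_threshold = 0.001, window_kb = 10000,
                              palindrome_policy = "conservative",
                              eaf_threshold = 0.42) {
  stopifnot(is.list(exposures), length(exposures) >= 2)
  labels <- names(exposures)
  if (is.null(labels) || any(labels == "")) {
    stop_mrlink("exposures must be a named list", "mrlink_config_error")
  }
  if (is.null(instruments)) {
    sel <- lapply(labels, function(l) {
      inst <- select_instruments(exposures[[l]], p_threshold)
      inst[, intersect(c("snp", "chrom", "pos", "pval"), names(inst)),
           drop = FALSE]
    })
    pool <- do.call(rbind, sel)
    pool <- pool[order(pool$pval), , drop = FALSE]
    pool <- pool[!duplicated(pool$snp), , drop = FALSE]   # min p per SNP
    if (!is.null(ld_matrix)) {
      pool <- clump(pool, ld_matrix, r2_threshold, window_kb)
    }
    instruments <- pool$snp
  }
  ref <- exposures[[1]]
  ref <- ref[ref$snp %in% instruments, , drop = FALSE]
  h_out <- harmonize(ref, outcome, palindrome_policy = palindrome_policy,
                     eaf_threshold = eaf_threshold)
  snps <- h_out$snp
  bx <- se_x <- matrix(NA_real_, length(snps), length(labels),
                       dimnames = list(snps, labels))
  bx[, 1] <- ref$beta[match(snps, ref$snp)]
  se_x[, 1] <- ref$se[match(snps, ref$snp)]
  for (e in seq_along(labels)[-1]) {
    h_e <- harmonize(ref, exposures[[e]],
                     palindrome_policy = palindrome_policy,
                     eaf_threshold = eaf_threshold)
    idx <- match(snps, h_e$snp)
    bx[, e] <- h_e$beta_outcome[idx]
    se_x[, e] <- h_e$se_outcome[idx]
  }
  ok <- stats::complete.cases(bx)
  structure(list(
    snp = snps[ok],
    beta_exposure = bx[ok, , drop = FALSE],
    se_exposure = se_x[ok, , drop = FALSE],
    beta_outcome = h_out$beta_outcome[ok],
    se_outcome = h_out$se_outcome[ok]
  ), class = "mvmr_dataset")
}

#' Multivariable IVW estimator
#'
#' Weighted multivariable regression of outcome betas on the exposure-beta
#' columns without intercept, weights `1 / se_Y^2`; each coefficient is the
#' direct effect of that exposure conditional on the others. Standard
#' errors use multiplicative overdispersion floored at 1 (with one exposure
#' this reproduces the univariable random-effects IVW exactly); p-values
#' are two-sided normal. A per-exposure conditional instrument-strength F
#' approximation (residual instrument signal after weighted projection on
#' the other exposures) is attached; values at or below 10 trigger a
#' warning.
#'
#' @param dataset An `mvmr_dataset` (or a list with `beta_exposure`,
#'   `se_exposure` matrices and `beta_outcome`, `se_outcome` vectors); needs
#'   more SNPs than exposures plus one.
#' @param warn_weak Warn when an exposure is conditionally weak (default
#'   `TRUE`; a two-step mediation deliberately instruments only the
#'   mediator, so it disables the warning for the auxiliary exposure).
#' @return List of class `mvmr_result`: `estimates` (one `mr_estimate` per
#'   exposure), `conditional_f`, `sigma`.
#' @export
mvmr_ivw <- function(dataset, warn_weak = TRUE) {
  x <- as.matrix(dataset$beta_exposure)
  by <- dataset$beta_outcome
  sey <- dataset$se_outcome
  j <- nrow(x); e <- ncol(x)
  labels <- colnames(x) %||% sprintf("exposure%d", seq_len(e))
  if (j <= e + 1) {
    stop_mrlink("multivariable IVW needs more SNPs than exposures + 1",
                "mrlink_estimation_error")
  }
  w <- 1 / sey^2
  xw <- x * sqrt(w)
  qr_x <- qr(xw)
  if (qr_x$rank < e) {
    bad <- labels[qr_x$pivot[seq.int(qr_x$rank + 1, e)]]
    stop_mrlink(sprintf("exposure matrix is rank deficient (collinear: %s)",
                        paste(bad, collapse = ", ")),
                "mrlink_estimation_error")
  }
  fit <- stats::lm(by ~ 0 + x, weights = w)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  cf <- sm$coefficients
  sigma <- sm$sigma
  adj <- if (sigma > 0) 1 / min(1, sigma) else 1
  est <- lapply(seq_len(e), function(i) {
    b <- cf[i, "Estimate"]
    s <- cf[i, "Std. Error"] * adj
    p <- if (s == 0) as.numeric(b == 0) else two_sided_p(b / s)
    new_mr_estimate(paste0("mvmr_ivw:", labels[i]), b, s, p, j)
  })
  names(est) <- labels

  cond_f <- vapply(seq_len(e), function(i) {
    se_i <- dataset$se_exposure[, i]
    if (anyNA(se_i)) return(NA_real_)
    r <- if (e == 1) x[, 1] else
      stats::resid(stats::lm(x[, i] ~ 0 + x[, -i, drop = FALSE], weights = w))
    sum(r^2 / se_i^2) / (j - e + 1)
  }, numeric(1))
  names(cond_f) <- labels
  if (warn_weak && any(!is.na(cond_f) & cond_f <= 10)) {
    warning(sprintf("conditionally weak instruments (F <= 10): %s",
                    paste(labels[!is.na(cond_f) & cond_f <= 10],
                          collapse = ", ")))
  }
  structure(list(estimates = est, conditional_f = cond_f, sigma = sigma,
                 n_snps = j),
            class = "mvmr_result")
}

#' Delta-method combination of two-step MR effects
#'
#' Combines the exposure-to-mediator effect (`beta1`) and the
#' mediator-to-outcome effect (`beta2`) into the indirect effect
#' `beta1 * beta2` with first-order delta variance
#' `beta1^2 se2^2 + beta2^2 se1^2` (the two steps use non-overlapping
#' samples, so zero covariance is assumed; the second-order cross term
#' `se1^2 se2^2` can be added with `second_order = TRUE`). The proportion
#' mediated is `indirect / total`, with delta variance assuming zero
#' covariance between indirect and total effects. Wald tests and the CI use
#' the normal distribution.
#'
#' @param beta1,se1 Exposure-to-mediator estimate and SE.
#' @param beta2,se2 Mediator-to-outcome estimate and SE.
#' @param total,se_total Total exposure-to-outcome estimate and SE.
#' @param level Confidence level, default 0.95.
#' @param second_order Add the `se1^2 se2^2` variance term.
#' @return Object of class `mediation_result` with components `beta1`,
#'   `beta2`, `total` (each `list(beta, se)`), `indirect`
#'   (`list(beta, se, pval)`) and `proportion` (`list(estimate, se, ci_low,
#'   ci_high, pval)`; all `NA` with a warning when `total == 0`).
#' @export
two_step_mediation <- function(beta1, se1, beta2, se2, total, se_total,
                               level = 0.95, second_order = FALSE) {
  stopifnot(se1 >= 0, se2 >= 0, se_total >= 0)
  indirect <- beta1 * beta2
  var_ind <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (second_order) var_ind <- var_ind + se1^2 * se2^2
  se_ind <- sqrt(var_ind)
  p_ind <- if (se_ind == 0) as.numeric(indirect == 0) else
    two_sided_p(indirect / se_ind)

  if (total == 0) {
    warning("total effect is zero; proportion mediated is undefined")
    prop <- list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, pval = NA_real_)
  } else {
    p_est <- indirect / total
    # expanded delta form, finite at indirect = 0
    var_p <- var_ind / total^2 + indirect^2 * se_total^2 / total^4
    se_p <- sqrt(var_p)
    z <- z_crit(level)
    prop <- list(estimate = p_est, se = se_p,
                 ci_low = p_est - z * se_p, ci_high = p_est + z * se_p,
                 pval = if (se_p == 0) as.numeric(p_est == 0) else
                   two_sided_p(p_est / se_p))
  }
  structure(list(
    beta1 = list(beta = beta1, se = se1),
    beta2 = list(beta = beta2, se = se2),
    total = list(beta = total, se = se_total),
    indirect = list(beta = indirect, se = se_ind, pval = p_ind),
    proportion = prop, level = level
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta1 (exposure -> mediator) = %.6g (SE %.6g)\n",
              x$beta1$beta, x$beta1$se))
  cat(sprintf("  beta2 (mediator -> outcome)  = %.6g (SE %.6g)\n",
              x$beta2$beta, x$beta2$se))
  cat(sprintf("  indirect = %.6g (SE %.6g, p = %.3g)\n",
              x$indirect$beta, x$indirect$se, x$indirect$pval))
  if (!is.na(x$proportion$estimate)) {
    cat(sprintf("  proportion mediated = %.1f%% (%d%% CI %.1f%%-%.1f%%, p = %.3g)\n",
                100 * x$proportion$estimate, round(100 * x$level),
                100 * x$proportion$ci_low, 100 * x$proportion$ci_high,
                x$proportion$pval))
  }
  invisible(x)
}

#' Two-step MR mediation analysis
#'
#' Runs the full two-step design on three summary tables. Step 1 estimates
#' the exposure-to-mediator effect (`beta1`) by univariable IVW on the
#' exposure's instruments. Step 2 estimates the mediator-to-outcome effect
#' (`beta2`); by default through multivariable IVW of the outcome on
#' (mediator, exposure) over the mediator's instruments, which blocks
#' contamination through the exposure pathway (`beta2_method =
#' "univariable"` uses a plain IVW instead). The total effect comes from
#' univariable IVW of the outcome on the exposure's instruments. The three
#' estimates are combined by [two_step_mediation()].
#'
#' @param exposure_stats,mediator_stats,outcome_stats Summary tables.
#' @param p_threshold Instrument-selection threshold.
#' @param beta2_method `"mvmr"` (default) or `"univariable"`.
#' @param ld_matrix,r2_threshold,window_kb Optional clumping inputs.
#' @param palindrome_policy,eaf_threshold Harmonization settings.
#' @param level Confidence level.
#' @return A `mediation_result`; attribute `provenance` records the SNP
#'   count used at each step.
#' @export
run_mediation <- function(exposure_stats, mediator_stats, outcome_stats,
                          p_threshold = 5e-8,
                          beta2_method = c("mvmr", "univariable"),
                          ld_matrix = NULL, r2_threshold = 0.001,
                          window_kb = 10000,
                          palindrome_policy = "conservative",
                          eaf_threshold = 0.42, level = 0.95) {
  beta2_method <- match.arg(beta2_method)
  step <- function(label, expr) {
    tryCatch(expr, mrlink_error = function(e) {
      stop_mrlink(sprintf("[%s] %s", label, conditionMessage(e)), class(e)[1])
    })
  }
  exp_inst <- step("step1: exposure instruments", {
    inst <- select_instruments(exposure_stats, p_threshold)
    if (!is.null(ld_matrix)) inst <- clump(inst, ld_matrix, r2_threshold,
                                           window_kb)
    inst
  })
  h_xm <- step("step1: harmonize exposure-mediator",
               harmonize(exp_inst, mediator_stats,
                         palindrome_policy = palindrome_policy,
                         eaf_threshold = eaf_threshold))
  b1 <- step("step1: IVW", mr_ivw(h_xm))

  h_xy <- step("total: harmonize exposure-outcome",
               harmonize(exp_inst, outcome_stats,
                         palindrome_policy = palindrome_policy,
                         eaf_threshold = eaf_threshold))
  total <- step("total: IVW", mr_ivw(h_xy))

  med_inst <- step("step2: mediator instruments", {
    inst <- select_instruments(mediator_stats, p_threshold)
    if (!is.null(ld_matrix)) inst <- clump(inst, ld_matrix, r2_threshold,
                                           window_kb)
    inst
  })
  if (beta2_method == "mvmr") {
    ds <- step("step2: MVMR dataset",
               make_mvmr_dataset(
                 exposures = list(mediator = mediator_stats,
                                  exposure = exposure_stats),
                 outcome = outcome_stats, instruments = med_inst$snp,
                 palindrome_policy = palindrome_policy,
                 eaf_threshold = eaf_threshold))
    mv <- step("step2: MVMR IVW", mvmr_ivw(ds, warn_weak = FALSE))
    b2 <- mv$estimates$mediator
    n2 <- mv$n_snps
    cond_f <- mv$conditional_f
  } else {
    h_my <- step("step2: harmonize mediator-outcome",
                 harmonize(med_inst, outcome_stats,
                           palindrome_policy = palindrome_policy,
                           eaf_threshold = eaf_threshold))
    b2 <- step("step2: IVW", mr_ivw(h_my))
    n2 <- b2$n_snps
    cond_f <- NULL
  }
  res <- two_step_mediation(b1$beta, b1$se, b2$beta, b2$se,
                            total$beta, total$se, level = level)
  attr(res, "provenance") <- list(
    n_snps_step1 = b1$n_snps, n_snps_step2 = n2,
    n_snps_total = total$n_snps, beta2_method = beta2_method,
    p_threshold = p_threshold, conditional_f = cond_f
  )
  res
}
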