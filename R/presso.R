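# Core MR-PRESSO machinery. The observed statistic is the weighted residual
# sum of squares RSS = sum_j w_j (b_Yj - theta_{-j} b_Xj)^2 with
# w_j = 1 / se_Yj^2 and theta_{-j} the IVW estimate excluding SNP j. The
# null distribution is built from n_sim parametric draws of both beta
# vectors; each draw's RSS is recomputed with its own leave-one-out
# estimates. Everything is computed on a snp-id-sorted copy so the result
# is invariant to input row order.
presso_core <- function(harmonized, n_sim, seed, exposure_uncertainty = TRUE) {
  ord <- order(harmonized$snp)
  h <- harmonized[ord, , drop = FALSE]
  j <- nrow(h)
  bx <- h$beta_exposure; by <- h$beta_outcome
  sex <- h$se_exposure; sey <- h$se_outcome
  w <- 1 / sey^2

  loo_theta <- function(bx, by) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  th <- loo_theta(bx, by)
  resid_obs <- w * (by - th * bx)^2
  rss_obs <- sum(resid_obs)

  sims <- with_seed(seed, {
    bx_star <- if (exposure_uncertainty) {
      matrix(stats::rnorm(j * n_sim, bx, sex), nrow = j)
    } else matrix(bx, nrow = j, ncol = n_sim)
    by_star <- matrix(stats::rnorm(j * n_sim, th * bx, sey), nrow = j)
    sxy <- colSums(w * bx_star * by_star)
    sxx <- colSums(w * bx_star^2)
    th_star <- (rep(sxy, each = j) - w * bx_star * by_star) /
      (rep(sxx, each = j) - w * bx_star^2)
    resid_star <- w * (by_star - th_star * bx_star)^2
    list(resid = resid_star, rss = colSums(resid_star))
  })

  global_pval <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_pvals <- rowMeans(sims$resid >= resid_obs)
  back <- order(ord)
  list(rss_obs = rss_obs, global_pval = global_pval, n_sim = n_sim,
       outlier_pvals = stats::setNames(outlier_pvals[back],
                                       harmonized$snp),
       resid_obs = stats::setNames(resid_obs[back], harmonized$snp))
}

#' MR-PRESSO global pleiotropy test
#'
#' Tests for horizontal pleiotropy as excess residual heterogeneity: the
#' observed leave-one-out weighted residual sum of squares is compared with
#' a null distribution built from `n_sim` parametric draws of the summary
#' statistics. The p-value uses the add-one estimator
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`, so it is never below
#' `1 / (n_sim + 1)`.
#'
#' @param harmonized An `mr_harmonized` dataset (>= 4 SNPs).
#' @param n_sim Number of null draws (>= 1000, default 1000).
#' @param seed Integer seed; with the input it fully determines the result.
#' @param exposure_uncertainty Also redraw exposure betas in the null
#'   (default `TRUE`, following the method's parametric bootstrap design).
#' @return An object of class `mr_presso` with `rss_obs`, `global_pval`,
#'   `n_sim` and per-SNP `outlier_pvals` (empirical proportions; see
#'   [presso_outliers()]).
#' @export
presso_global <- function(harmonized, n_sim = 1000, seed,
                          exposure_uncertainty = TRUE) {
  if (nrow(harmonized) < 4) {
    stop_mrlink("MR-PRESSO needs at least 4 SNPs", "mrlink_estimation_error")
  }
  if (missing(seed)) {
    stop_mrlink("a simulation seed is required", "mrlink_config_error")
  }
  stopifnot(n_sim >= 1000)
  core <- presso_core(harmonized, n_sim, seed, exposure_uncertainty)
  structure(c(core, list(outliers = NULL, corrected_estimate = NULL,
                         alpha = NULL)),
            class = "mr_presso")
}

#' MR-PRESSO per-SNP outlier test
#'
#' Compares each SNP's observed leave-one-out residual with its simulated
#' null residuals from the same draws as the global test. Per-SNP p-values
#' are the empirical proportions `#\{resid* >= resid_obs\} / n_sim` and are
#' Bonferroni-adjusted over the J SNPs before flagging at `alpha`. The test
#' is meant to be run when the global test is significant; set
#' `force = TRUE` to run it regardless.
#'
#' @inheritParams presso_global
#' @param alpha Flagging level after Bonferroni adjustment, default 0.05.
#' @param global_gate Significance gate on the global p-value
#'   (default 0.05).
#' @param force Run the outlier test even when the global test is not
#'   significant.
#' @return An `mr_presso` object with `outliers` (flagged SNP ids) and, when
#'   any SNP is flagged, the outlier-corrected IVW `corrected_estimate`.
#' @export
presso_outliers <- function(harmonized, n_sim = 1000, seed, alpha = 0.05,
                            global_gate = 0.05, force = FALSE,
                            exposure_uncertainty = TRUE) {
  res <- presso_global(harmonized, n_sim = n_sim, seed = seed,
                       exposure_uncertainty = exposure_uncertainty)
  res$alpha <- alpha
  if (res$global_pval >= global_gate && !force) {
    stop_mrlink(sprintf(
      "global test not significant (p = %.3g >= %.3g); use force = TRUE to override",
      res$global_pval, global_gate), "mrlink_estimation_error")
  }
  # pmin takes attributes from its first argument: keep the SNP names
  p_adj <- pmin(res$outlier_pvals * length(res$outlier_pvals), 1)
  res$outliers <- names(p_adj)[p_adj < alpha]
  if (length(res$outliers) > 0) {
    res$corrected_estimate <- presso_corrected(harmonized, res$outliers)
  }
  res
}

#' Outlier-corrected IVW estimate
#'
#' Re-estimates the IVW causal effect after removing flagged outlier SNPs.
#'
#' @param harmonized An `mr_harmonized` dataset.
#' @param outliers Character vector of SNP ids to remove (must be a subset
#'   of the dataset; at least 2 SNPs must remain).
#' @return An `mr_estimate` with attribute `removed_snps`.
#' @export
presso_corrected <- function(harmonized, outliers) {
  stopifnot(all(outliers %in% harmonized$snp))
  keep <- !(harmonized$snp %in% outliers)
  if (sum(keep) < 2) {
    stop_mrlink("fewer than 2 SNPs remain after outlier removal",
                "mrlink_estimation_error")
  }
  est <- mr_ivw(harmonized[keep, , drop = FALSE])
  est$removed_snps <- outliers
  est
}

#' Full MR-PRESSO analysis
#'
#' Convenience wrapper: global test always; per-SNP outlier test and
#' outlier-corrected re-estimation when the global test is significant at
#' `global_gate`.
#'
#' @inheritParams presso_outliers
#' @return An `mr_presso` object.
#' @export
mr_presso <- function(harmonized, n_sim = 1000, seed, alpha = 0.05,
                      global_gate = 0.05, exposure_uncertainty = TRUE) {
  res <- presso_global(harmonized, n_sim = n_sim, seed = seed,
                       exposure_uncertainty = exposure_uncertainty)
  res$alpha <- alpha
  if (res$global_pval < global_gate) {
    res <- presso_outliers(harmonized, n_sim = n_sim, seed = seed,
                           alpha = alpha, global_gate = global_gate,
                           exposure_uncertainty = exposure_uncertainty)
  }
  res
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (n_sim = %d)\n", x$n_sim))
  cat(sprintf("  global RSS = %.6g, global p = %.4g\n", x$rss_obs,
              x$global_pval))
  if (!is.null(x$outliers)) {
    cat(sprintf("  outliers flagged: %s\n",
                if (length(x$outliers)) paste(x$outliers, collapse = ", ")
                else "none"))
  }
  if (!is.null(x$corrected_estimate)) {
    cat(sprintf("  corrected IVW beta = %.6g (p = %.3g)\n",
                x$corrected_estimate$beta, x$corrected_estimate$pval))
  }
  invisible(x)
}
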