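new_mr_estimate <- function(method, beta, se, pval, n_snps, level = 0.95,
                            extra = list()) {
  or <- to_odds_ratio(beta, se, level)
  structure(c(list(method = method, beta = beta, se = se, pval = pval,
                   n_snps = n_snps, or = or$or, or_ci_low = or$ci_low,
                   or_ci_high = or$ci_high, level = level), extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.6g (SE %.6g), p = %.3g\n", x$beta, x$se, x$pval))
  cat(sprintf("  OR = %.4g (%d%% CI %.4g-%.4g)\n", x$or,
              round(100 * x$level), x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' Computes the per-SNP causal-effect estimate `beta_outcome /
#' beta_exposure` with the first-order standard error
#' `se_outcome / |beta_exposure|` (exposure uncertainty ignored; the
#' second-order form adding `beta_outcome^2 se_exposure^2 /
#' beta_exposure^4` is available via `second_order = TRUE`). SNPs with a
#' zero exposure beta are dropped with a warning.
#'
#' @param harmonized An `mr_harmonized` dataset.
#' @param second_order Use the second-order delta SE. Default `FALSE`.
#' @return Data.frame with `snp`, `ratio`, `se` and `weight` (`1 / se^2`).
#' @export
wald_ratios <- function(harmonized, second_order = FALSE) {
  bx <- harmonized$beta_exposure
  nonzero <- bx != 0
  if (!any(nonzero)) {
    stop_mrlink("all exposure betas are zero; Wald ratios undefined",
                "mrlink_estimation_error")
  }
  if (!all(nonzero)) {
    warning(sprintf("%d SNP(s) with zero exposure beta dropped",
                    sum(!nonzero)))
  }
  h <- harmonized[nonzero, , drop = FALSE]
  ratio <- h$beta_outcome / h$beta_exposure
  var1 <- h$se_outcome^2 / h$beta_exposure^2
  se <- if (second_order) {
    sqrt(var1 + h$beta_outcome^2 * h$se_exposure^2 / h$beta_exposure^4)
  } else sqrt(var1)
  data.frame(snp = h$snp, ratio = ratio, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - theta)^2` over Wald ratios with inverse-variance
#' weights, compared with a chi-squared distribution on J - 1 degrees of
#' freedom.
#'
#' @param harmonized An `mr_harmonized` dataset (>= 2 SNPs).
#' @param theta Causal effect the ratios are compared against (typically
#'   the IVW estimate).
#' @return List with `q_stat`, `df` and `pval`.
#' @export
cochrans_q <- function(harmonized, theta) {
  wr <- wald_ratios(harmonized)
  stopifnot(nrow(wr) >= 2)
  q <- sum(wr$weight * (wr$ratio - theta)^2)
  df <- nrow(wr) - 1
  list(q_stat = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted MR estimate
#'
#' The IVW estimator: `theta = sum(w b_X b_Y) / sum(w b_X^2)` with
#' `w = 1 / se_Y^2`, identical to the inverse-variance-weighted mean of the
#' Wald ratios and to a weighted regression of outcome on exposure betas
#' through the origin. The default multiplicative random-effects model
#' inflates the fixed-effect standard error by `sqrt(Q / (J - 1))` when
#' heterogeneity exceeds its expectation and leaves it untouched otherwise;
#' `"fixed"` never inflates, `"additive"` uses a DerSimonian-Laird
#' between-SNP variance. P-values are two-sided normal.
#'
#' @param harmonized An `mr_harmonized` dataset (>= 2 SNPs).
#' @param model `"random"` (default, multiplicative), `"fixed"` or
#'   `"additive"`.
#' @return An `mr_estimate` with fields `q_stat`, `q_df`, `q_pval` and
#'   `se_fixed` alongside the usual estimate slots.
#' @export
mr_ivw <- function(harmonized, model = c("random", "fixed", "additive")) {
  model <- match.arg(model)
  if (nrow(harmonized) < 2) {
    stop_mrlink("IVW needs at least 2 SNPs", "mrlink_estimation_error")
  }
  bx <- harmonized$beta_exposure
  by <- harmonized$beta_outcome
  w <- 1 / harmonized$se_outcome^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- 1 / sqrt(sxx)
  q <- cochrans_q(harmonized, beta)
  j <- nrow(harmonized)
  if (model == "additive") {
    wr <- wald_ratios(harmonized)
    tau2 <- max(0, (q$q_stat - (j - 1)) /
                  (sum(wr$weight) - sum(wr$weight^2) / sum(wr$weight)))
    w_star <- 1 / (wr$se^2 + tau2)
    beta <- sum(w_star * wr$ratio) / sum(w_star)
    se <- 1 / sqrt(sum(w_star))
  } else {
    scale <- if (model == "random") max(1, sqrt(q$q_stat / (j - 1))) else 1
    se <- se_fixed * scale
  }
  new_mr_estimate("ivw", beta, se, two_sided_p(beta / se), j,
                  extra = list(model = model, se_fixed = se_fixed,
                               q_stat = q$q_stat, q_df = q$df,
                               q_pval = q$pval))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an
#' intercept, weights `1 / se_Y^2`, after orienting every SNP so the
#' exposure beta is non-negative. The slope estimates the causal effect
#' under the weaker InSIDE assumption; the intercept estimates average
#' directional pleiotropy and its test is the Egger intercept test.
#' Standard errors use multiplicative overdispersion floored at 1 (the
#' fixed-effect SE is never deflated by an under-dispersed fit); p-values
#' use the t distribution on J - 2 degrees of freedom.
#'
#' @param harmonized An `mr_harmonized` dataset (>= 3 SNPs).
#' @return An `mr_estimate` (slope) carrying `intercept`, `intercept_se`,
#'   `intercept_pval` and the residual overdispersion `sigma`.
#' @export
mr_egger <- function(harmonized) {
  j <- nrow(harmonized)
  if (j < 3) {
    stop_mrlink("MR-Egger needs at least 3 SNPs", "mrlink_estimation_error")
  }
  flip <- sign(harmonized$beta_exposure)
  flip[flip == 0] <- 1
  bx <- harmonized$beta_exposure * flip
  by <- harmonized$beta_outcome * flip
  w <- 1 / harmonized$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  # summary.lm warns on an exactly collinear (perfect-fit) configuration;
  # that degenerate case is legitimate input for noiseless oracles
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  sigma <- sm$sigma
  # lm SEs already carry sigma; floor the multiplicative scaling at 1
  # (a perfect fit, sigma = 0, keeps its zero SEs)
  adj <- if (sigma > 0) 1 / min(1, sigma) else 1
  se_slope <- cf["bx", "Std. Error"] * adj
  se_int <- cf["(Intercept)", "Std. Error"] * adj
  slope <- cf["bx", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  p_slope <- if (se_slope == 0) as.numeric(slope == 0) else
    2 * stats::pt(-abs(slope / se_slope), df = j - 2)
  p_int <- if (se_int == 0) as.numeric(intercept == 0) else
    2 * stats::pt(-abs(intercept / se_int), df = j - 2)
  new_mr_estimate("mr_egger", slope, se_slope, p_slope, j,
                  extra = list(intercept = intercept, intercept_se = se_int,
                               intercept_pval = p_int, sigma = sigma))
}

# Interpolated weighted median of `x` with weights `w`: the standardized
# cumulative weight s_j = (cumsum(w) - w/2) / sum(w) is linearly
# interpolated at 1/2.
weighted_median_estimate <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Inverse-variance weighted median of the per-SNP Wald ratios, consistent
#' when SNPs carrying more than half of the weight are valid instruments.
#' The standard error comes from a parametric bootstrap: exposure and
#' outcome betas are redrawn from their normal sampling distributions, the
#' weighted median recomputed, and the SD over draws taken.
#'
#' @param harmonized An `mr_harmonized` dataset (>= 3 SNPs).
#' @param n_boot Bootstrap draws (>= 100, default 1000).
#' @param seed Integer seed for the bootstrap; required for
#'   reproducibility.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(harmonized, n_boot = 1000, seed) {
  j <- nrow(harmonized)
  if (j < 3) {
    stop_mrlink("weighted median needs at least 3 SNPs",
                "mrlink_estimation_error")
  }
  if (missing(seed)) {
    stop_mrlink("a bootstrap seed is required", "mrlink_config_error")
  }
  stopifnot(n_boot >= 100)
  wr <- wald_ratios(harmonized)
  est <- weighted_median_estimate(wr$ratio, wr$weight)
  h <- harmonized[harmonized$snp %in% wr$snp, , drop = FALSE]
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(h), h$beta_exposure, h$se_exposure)
      by <- stats::rnorm(nrow(h), h$beta_outcome, h$se_outcome)
      ok <- bx != 0
      r <- by[ok] / bx[ok]
      w <- bx[ok]^2 / h$se_outcome[ok]^2
      weighted_median_estimate(r, w)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pval <- if (se == 0) as.numeric(est == 0) else two_sided_p(est / se)
  new_mr_estimate("weighted_median", est, se, pval, j,
                  extra = list(n_boot = n_boot, seed = seed))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect J times, omitting one SNP at a time, to
#' check whether the pooled estimate is dominated by any single variant. An
#' omission is flagged when it changes the sign of the estimate or moves it
#' outside the full-set confidence interval.
#'
#' @param harmonized An `mr_harmonized` dataset (>= 3 SNPs).
#' @param model IVW variant passed through to [mr_ivw()].
#' @return Data.frame with one row per omitted SNP (`snp`, `beta`, `se`,
#'   `pval`, `flagged`), with the full-set estimate in attribute `full`.
#' @export
mr_leave_one_out <- function(harmonized, model = "random") {
  j <- nrow(harmonized)
  if (j < 3) {
    stop_mrlink("leave-one-out needs at least 3 SNPs",
                "mrlink_estimation_error")
  }
  full <- mr_ivw(harmonized, model = model)
  z <- z_crit(full$level)
  ci <- c(full$beta - z * full$se, full$beta + z * full$se)
  rows <- lapply(seq_len(j), function(i) {
    e <- mr_ivw(harmonized[-i, , drop = FALSE], model = model)
    data.frame(snp = harmonized$snp[i], beta = e$beta, se = e$se,
               pval = e$pval,
               flagged = sign(e$beta) != sign(full$beta) ||
                 e$beta < ci[1] || e$beta > ci[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "full") <- full
  res
}

#' Tidy table of univariable MR estimates
#'
#' Runs IVW, weighted median and MR-Egger on one harmonized dataset and
#' returns a tidy table (method, nsnp, beta, se, pval, OR and CI bounds),
#' the layout in which two-sample MR results are conventionally reported.
#'
#' @param harmonized An `mr_harmonized` dataset.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return Data.frame with one row per method; the full estimate objects
#'   are kept in attribute `estimates`.
#' @export
mr_all_methods <- function(harmonized, n_boot = 1000, seed) {
  ests <- list(
    ivw = mr_ivw(harmonized),
    weighted_median = mr_weighted_median(harmonized, n_boot = n_boot,
                                         seed = seed),
    mr_egger = mr_egger(harmonized)
  )
  tab <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, nsnp = e$n_snps, beta = e$beta, se = e$se,
               pval = e$pval, or = e$or, or_ci_low = e$or_ci_low,
               or_ci_high = e$or_ci_high, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  attr(tab, "estimates") <- ests
  tab
}
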