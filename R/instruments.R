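#' Select genome-wide significant instruments
#'
#' Subsets a summary table to SNPs whose association p-value is strictly
#' below the threshold (default genome-wide significance, 5e-8), preserving
#' input order.
#'
#' @param records Summary-statistics data.frame with a `pval` column.
#' @param p_threshold Strict upper bound on the p-value; default `5e-8`.
#' @return The subset of `records`; errors (class
#'   `mrlink_instrument_error`) if no SNP passes, so a pipeline can never
#'   silently continue without instruments.
#' @export
select_instruments <- function(records, p_threshold = 5e-8) {
  keep <- records$pval < p_threshold
  if (!any(keep)) {
    stop_mrlink(sprintf("no SNP reaches p < %g; cannot build an instrument set",
                        p_threshold), "mrlink_instrument_error")
  }
  res <- records[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Greedy LD clumping
#'
#' Identifies independent index SNPs by the standard greedy procedure:
#' records are ranked by ascending p-value (ties broken by lexical SNP id
#' for determinism); the best remaining SNP becomes an index SNP and every
#' remaining SNP on the same chromosome whose squared correlation with it is
#' at or above `r2_threshold` *and* whose position lies within `window_kb`
#' of it is removed. SNPs on different chromosomes are never clumped
#' together.
#'
#' @param records Summary table with `snp`, `pval` and (optionally) `chrom`
#'   and `pos` columns. When positions are absent all pairs are treated as
#'   within-window.
#' @param ld_matrix Square correlation matrix with SNP ids as dimnames. A
#'   missing entry for an in-window pair is an error: independence is never
#'   silently assumed. Pass `NULL` only to assert that all SNPs are
#'   uncorrelated.
#' @param r2_threshold Squared-correlation cutoff, default 0.001.
#' @param window_kb Clumping window in kilobases, default 10,000.
#' @return The index-SNP rows of `records`, in selection order.
#' @export
clump <- function(records, ld_matrix = NULL, r2_threshold = 0.001,
                  window_kb = 10000) {
  if (nrow(records) == 0) return(records)
  if (is.null(ld_matrix)) {
    return(records)                     # caller asserts pairwise independence
  }
  snp <- records$snp
  has_pos <- all(c("chrom", "pos") %in% names(records)) &&
    !anyNA(records$pos)
  chrom <- if (has_pos) as.character(records$chrom) else rep("1", nrow(records))
  pos <- if (has_pos) records$pos else rep(0, nrow(records))
  window_bp <- window_kb * 1000

  ord <- order(records$pval, snp)
  alive <- rep(TRUE, nrow(records))
  picked <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    picked <- c(picked, i)
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) == 0) break
    same_chr <- chrom[cand] == chrom[i]
    in_window <- same_chr & abs(pos[cand] - pos[i]) <= window_bp
    if (!any(in_window)) next
    idx_i <- match(snp[i], rownames(ld_matrix))
    idx_c <- match(snp[cand[in_window]], colnames(ld_matrix))
    if (is.na(idx_i) || anyNA(idx_c)) {
      stop_mrlink(sprintf(
        "LD matrix has no entry for an in-window pair involving '%s'", snp[i]),
        "mrlink_ld_error")
    }
    r2 <- ld_matrix[idx_i, idx_c]^2
    if (anyNA(r2)) {
      stop_mrlink(sprintf(
        "LD matrix has missing correlations for SNPs near '%s'", snp[i]),
        "mrlink_ld_error")
    }
    drop <- cand[in_window][r2 >= r2_threshold]
    alive[drop] <- FALSE
  }
  res <- records[picked, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-SNP variance explained
#'
#' Approximates the proportion of exposure variance explained by one SNP.
#' The default needs no allele frequency:
#' `r2 = beta^2 / (beta^2 + se^2 * n)`, the standardized approximation that
#' follows from the identity `t^2 = (n - 2) r2 / (1 - r2)`. The alternative
#' `method = "eaf"` uses `2 p (1 - p) beta^2` for a standardized trait.
#'
#' @param beta,se Per-SNP effect and standard error (`se > 0`).
#' @param n Exposure-study sample size (`n > 2`).
#' @param eaf Effect-allele frequency, required for `method = "eaf"`.
#' @param method `"tstat"` (default) or `"eaf"`.
#' @return Vector of per-SNP r-squared values.
#' @export
per_snp_r2 <- function(beta, se, n, eaf = NULL, method = c("tstat", "eaf")) {
  method <- match.arg(method)
  stopifnot(all(se > 0), all(n > 2))
  if (method == "tstat") {
    beta^2 / (beta^2 + se^2 * n)
  } else {
    if (is.null(eaf)) {
      stop_mrlink("method = 'eaf' needs effect-allele frequencies",
                  "mrlink_config_error")
    }
    2 * eaf * (1 - eaf) * beta^2
  }
}

#' Instrument-strength F statistic
#'
#' Joint F statistic of an instrument set,
#' `F = ((n - k - 1) / k) * (r2 / (1 - r2))`, with the conventional weak
#' instrument flag at `F <= 10`.
#'
#' @param n Exposure sample size (`n > k + 1`).
#' @param k Number of SNPs in the instrument set.
#' @param r2_total Total variance explained, in `[0, 1)`.
#' @return List with `f_stat` and logical `weak`.
#' @export
f_statistic <- function(n, k, r2_total) {
  if (r2_total >= 1 || r2_total < 0) {
    stop_mrlink("r2_total must lie in [0, 1)", "mrlink_domain_error")
  }
  stopifnot(k >= 1, n > k + 1)
  f <- ((n - k - 1) / k) * (r2_total / (1 - r2_total))
  list(f_stat = f, weak = f <= 10)
}

#' Summarize instrument strength for a harmonized dataset
#'
#' Computes the total variance explained by the instrument set (sum of
#' per-SNP r-squared, capped below 1), the joint F statistic, and the mean
#' per-SNP F (`mean(beta^2 / se^2)`), which is also in common use; the
#' joint formula is the primary measure.
#'
#' @param harmonized An `mr_harmonized` dataset.
#' @param n Exposure sample size; defaults to the per-SNP median of
#'   `samplesize_exposure` when present.
#' @return List of class `mr_instrument_strength` with `n`, `k`,
#'   `r2_total`, `f_stat`, `f_mean` and `weak`.
#' @export
instrument_strength <- function(harmonized, n = NULL) {
  if (is.null(n)) {
    if (!"samplesize_exposure" %in% names(harmonized) ||
        anyNA(harmonized$samplesize_exposure)) {
      stop_mrlink("exposure sample size unavailable; supply n",
                  "mrlink_config_error")
    }
    n <- stats::median(harmonized$samplesize_exposure)
  }
  k <- nrow(harmonized)
  r2 <- sum(per_snp_r2(harmonized$beta_exposure, harmonized$se_exposure, n))
  r2 <- min(r2, 1 - 1e-12)
  fs <- f_statistic(n, k, r2)
  structure(list(n = n, k = k, r2_total = r2, f_stat = fs$f_stat,
                 f_mean = mean(harmonized$beta_exposure^2 /
                                 harmonized$se_exposure^2),
                 weak = fs$weak),
            class = "mr_instrument_strength")
}
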