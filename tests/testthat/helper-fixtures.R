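# Small builders shared across the suite.

# A well-formed summary table with deterministic values.
make_records <- function(n = 5, seed = 1) {
  set.seed(seed)
  maf <- runif(n, 0.1, 0.4)
  se <- 1 / sqrt(2 * maf * (1 - maf) * 100000)
  beta <- rnorm(n, 0.05, 0.01)
  data.frame(
    snp = sprintf("rs%d", seq_len(n)), chrom = "1", pos = seq_len(n) * 1e6,
    effect_allele = rep(c("A", "G", "C", "T", "A"), length.out = n),
    other_allele = rep(c("G", "A", "T", "C", "C"), length.out = n),
    eaf = maf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), samplesize = 100000,
    stringsAsFactors = FALSE
  )
}

# Random harmonized dataset for estimator property tests.
random_harmonized <- function(j, seed) {
  set.seed(seed)
  harmonized_dataset(
    beta_exposure = rnorm(j, 0, 0.3) + sample(c(-1, 1), j, TRUE) * 0.2,
    se_exposure = runif(j, 0.01, 0.1),
    beta_outcome = rnorm(j, 0, 0.2),
    se_outcome = runif(j, 0.02, 0.2)
  )
}

# Independent greedy clumping oracle: direct transcription of the rule,
# O(n^2), no shared code with clump().
clump_oracle <- function(records, ld, r2_threshold = 0.001,
                         window_kb = 10000) {
  remaining <- records[order(records$pval, records$snp), , drop = FALSE]
  picked <- character(0)
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    picked <- c(picked, lead$snp)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      same_chr <- remaining$chrom[i] == lead$chrom
      close <- abs(remaining$pos[i] - lead$pos) <= window_kb * 1000
      r2 <- ld[lead$snp, remaining$snp[i]]^2
      drop[i] <- same_chr && close && r2 >= r2_threshold
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  picked
}

# Weighted absolute-deviation objective used as the weighted-median oracle.
wad_grid_minimizer <- function(x, w, step = 1e-4) {
  grid <- seq(min(x), max(x), by = step)
  obj <- vapply(grid, function(g) sum(w * abs(x - g)), numeric(1))
  grid[which.min(obj)]
}
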