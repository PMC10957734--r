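CANONICAL_COLS <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "samplesize")
MANDATORY_COLS <- c("snp", "effect_allele", "other_allele", "beta", "se",
                    "pval")

DEFAULT_COLUMN_MAP <- c(
  snp = "SNP", chrom = "chr", pos = "pos",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "eaf", beta = "beta", se = "se", pval = "pval",
  samplesize = "samplesize"
)

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table of per-SNP association summaries and
#' validates each row against the invariants the MR estimators rely on
#' (positive standard error, p-value in (0, 1], distinct biallelic
#' single-base alleles, effect-allele frequency in \[0, 1\]). Rows failing a
#' check are dropped, not fixed, and the drop reasons are tallied in the
#' `load_report` attribute. Alleles are upper-cased on input. Column names
#' are matched case-insensitively through `column_map`.
#'
#' @param source Path to a delimited file (or a connection).
#' @param column_map Named character vector mapping canonical field names
#'   (`snp`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `samplesize`) to source column names. Defaults to the
#'   common `SNP/effect_allele/other_allele/eaf/beta/se/pval/samplesize`
#'   dialect.
#' @param sep Field separator, default tab.
#' @param allow_indels If `FALSE` (default) rows whose alleles are not a
#'   single A/C/G/T base are dropped.
#' @return A data.frame of validated records in canonical column order,
#'   with attribute `load_report` (a list with `n_read`, `n_kept`,
#'   `drop_count` and a `reasons` table).
#' @export
read_summary_table <- function(source, column_map = NULL, sep = "\t",
                               allow_indels = FALSE) {
  map <- DEFAULT_COLUMN_MAP
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0) {
    stop_mrlink("summary table is empty", "mrlink_format_error")
  }
  lower <- tolower(names(raw))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in CANONICAL_COLS) {
    hit <- match(tolower(map[[field]]), lower)
    if (is.na(hit)) hit <- match(field, lower)  # canonical name fallback
    if (!is.na(hit)) {
      out[[field]] <- raw[[hit]]
    } else if (field %in% MANDATORY_COLS) {
      stop_mrlink(sprintf("missing mandatory column '%s' (looked for '%s')",
                          field, map[[field]]), "mrlink_format_error")
    } else {
      out[[field]] <- NA
    }
  }
  out$snp <- as.character(out$snp)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  for (f in c("eaf", "beta", "se", "pval", "pos", "samplesize")) {
    out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  }
  out$chrom <- as.character(out$chrom)

  valid_allele <- function(a) {
    if (allow_indels) grepl("^[ACGT]+$", a) else a %in% names(COMPLEMENT)
  }
  reasons <- c(
    bad_allele = sum(!(valid_allele(out$effect_allele) &
                         valid_allele(out$other_allele))),
    same_alleles = 0, bad_se = 0, bad_pval = 0, bad_eaf = 0, bad_beta = 0
  )
  keep <- valid_allele(out$effect_allele) & valid_allele(out$other_allele)
  chk <- function(ok, reason) {
    reasons[reason] <<- reasons[reason] + sum(keep & !ok)
    keep <<- keep & ok
  }
  chk(out$effect_allele != out$other_allele, "same_alleles")
  chk(is.finite(out$se) & out$se > 0, "bad_se")
  chk(is.finite(out$pval) & out$pval > 0 & out$pval <= 1, "bad_pval")
  chk(is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1), "bad_eaf")
  chk(is.finite(out$beta), "bad_beta")

  res <- out[keep, CANONICAL_COLS, drop = FALSE]
  rownames(res) <- NULL
  attr(res, "load_report") <- list(
    n_read = nrow(out), n_kept = nrow(res),
    drop_count = nrow(out) - nrow(res), reasons = reasons
  )
  res
}

#' Write a GWAS summary-statistics table
#'
#' Writes records in the canonical tab-separated dialect with all floats
#' formatted to 10 significant digits, so read -> write -> read round-trips
#' losslessly at that precision.
#'
#' @param records Data.frame of summary records (canonical columns; missing
#'   optional columns are written as NA).
#' @param sink Output path or connection.
#' @export
write_summary_table <- function(records, sink) {
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (field in CANONICAL_COLS) {
    x <- if (field %in% names(records)) records[[field]] else
      rep(NA, nrow(records))
    out[[field]] <- if (is.numeric(x)) format_num(x) else as.character(x)
  }
  names(out)[names(out) == "snp"] <- "SNP"
  utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(NULL)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations of every SNP shared between the two
#' tables to the exposure's effect allele. Records with identical allele
#' orientation are kept as-is; swapped alleles have the outcome beta negated
#' and frequency mirrored; non-palindromic strand flips are resolved through
#' allele complements. Palindromic (A/T, G/C) SNPs cannot be oriented from
#' alleles alone: under `palindrome_policy = "conservative"` they are kept
#' only when both allele frequencies fall on the same side of 0.5 and both
#' are outside `[eaf_threshold, 1 - eaf_threshold]` (informative
#' frequencies); under `"drop"` they are always removed. Irreconcilable
#' allele sets are dropped. Every decision is logged per SNP in the `audit`
#' attribute.
#'
#' @param exposure_records,outcome_records Summary tables as returned by
#'   [read_summary_table()] or the simulators; matched on `snp`.
#' @param palindrome_policy `"conservative"` (default) or `"drop"`.
#' @param eaf_threshold Ambiguity band half-width for palindromic SNPs,
#'   default 0.42: frequencies in \[0.42, 0.58\] are considered
#'   uninformative.
#' @return A data.frame of class `mr_harmonized` with columns `snp`,
#'   `chrom`, `pos`, `eaf`, `beta_exposure`, `se_exposure`, `pval_exposure`,
#'   `samplesize_exposure`, `beta_outcome`, `se_outcome`, `pval_outcome`,
#'   `samplesize_outcome`; attribute `audit` is a data.frame of per-SNP
#'   actions in `{kept, allele_flipped, palindromic_kept,
#'   palindromic_dropped, incompatible_dropped}`.
#' @export
harmonize <- function(exposure_records, outcome_records,
                      palindrome_policy = c("conservative", "drop"),
                      eaf_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure_records$snp, outcome_records$snp)
  if (length(shared) == 0) {
    stop_mrlink("no SNPs shared between exposure and outcome tables",
                "mrlink_harmonize_error")
  }
  ex <- exposure_records[match(shared, exposure_records$snp), ]
  ou <- outcome_records[match(shared, outcome_records$snp), ]

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, n)
  eaf_ex <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, n)

  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    pal <- is_palindromic(e1, e2)
    if (pal) {
      if (!is_palindromic(o1, o2) || !all(c(o1, o2) %in% c(e1, e2))) {
        action[i] <- "incompatible_dropped"
        next
      }
      # label-align first (palindromic strand state is decided by frequency)
      if (o1 == e2) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      }
      if (palindrome_policy == "drop") {
        action[i] <- "palindromic_dropped"
        next
      }
      informative <- !is.na(eaf_ex[i]) && !is.na(eaf_out[i]) &&
        sign(eaf_ex[i] - 0.5) == sign(eaf_out[i] - 0.5) &&
        pmin(eaf_ex[i], 1 - eaf_ex[i]) < eaf_threshold &&
        pmin(eaf_out[i], 1 - eaf_out[i]) < eaf_threshold
      action[i] <- if (informative) "palindromic_kept" else
        "palindromic_dropped"
      next
    }
    c1 <- COMPLEMENT[[o1]]; c2 <- COMPLEMENT[[o2]]
    if (o1 == e1 && o2 == e2) {
      action[i] <- "kept"
    } else if (o1 == e2 && o2 == e1) {
      action[i] <- "allele_flipped"
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    } else if (c1 == e1 && c2 == e2) {
      action[i] <- "kept"               # strand-corrected, same orientation
    } else if (c1 == e2 && c2 == e1) {
      action[i] <- "allele_flipped"     # strand-corrected, swapped
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
    } else {
      action[i] <- "incompatible_dropped"
    }
  }

  keep <- action %in% c("kept", "allele_flipped", "palindromic_kept")
  opt <- function(df, col) if (col %in% names(df)) df[[col]] else
    rep(NA_real_, n)
  res <- data.frame(
    snp = shared,
    chrom = if ("chrom" %in% names(ex)) as.character(ex$chrom) else
      rep(NA_character_, n),
    pos = opt(ex, "pos"),
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    eaf = eaf_ex,
    beta_exposure = ex$beta, se_exposure = ex$se, pval_exposure = ex$pval,
    samplesize_exposure = opt(ex, "samplesize"),
    beta_outcome = beta_out, se_outcome = ou$se, pval_outcome = ou$pval,
    samplesize_outcome = opt(ou, "samplesize"),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "audit") <- data.frame(snp = shared, action = action,
                                   stringsAsFactors = FALSE)
  attr(res, "palindrome_policy") <- palindrome_policy
  attr(res, "eaf_threshold") <- eaf_threshold
  class(res) <- c("mr_harmonized", "data.frame")
  res
}

#' Construct a harmonized dataset from aligned effect vectors
#'
#' Convenience constructor for estimator input when per-SNP exposure and
#' outcome effects are already aligned to a common effect allele (e.g. in
#' simulations or worked examples).
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors
#'   of equal length; standard errors must be positive.
#' @param snp Optional SNP identifiers (default `snp1..snpJ`).
#' @return An `mr_harmonized` data.frame.
#' @export
harmonized_dataset <- function(beta_exposure, se_exposure, beta_outcome,
                               se_outcome,
                               snp = sprintf("snp%d", seq_along(beta_exposure))) {
  stopifnot(length(beta_exposure) == length(beta_outcome),
            length(se_exposure) == length(beta_exposure),
            length(se_outcome) == length(beta_exposure),
            all(se_exposure > 0), all(se_outcome > 0))
  res <- data.frame(snp = snp,
                    beta_exposure = beta_exposure, se_exposure = se_exposure,
                    pval_exposure = two_sided_p(beta_exposure / se_exposure),
                    beta_outcome = beta_outcome, se_outcome = se_outcome,
                    pval_outcome = two_sided_p(beta_outcome / se_outcome),
                    stringsAsFactors = FALSE)
  class(res) <- c("mr_harmonized", "data.frame")
  res
}

#' Harmonized view of a synthetic study
#'
#' Convenience wrapper: harmonizes a simulated exposure table with the
#' study's outcome (or mediator) table. Simulator tables are already
#' allele-aligned, so apart from ambiguous palindromic SNPs this is a
#' column join on SNP id.
#'
#' @param study An `mr_synthetic_study`.
#' @param outcome `"outcome"` (default) or `"mediator"`.
#' @return An `mr_harmonized` dataset.
#' @export
harmonize_synthetic <- function(study, outcome = c("outcome", "mediator")) {
  outcome <- match.arg(outcome)
  tab <- if (outcome == "outcome") study$outcome_stats else
    study$mediator_stats
  harmonize(study$exposure_stats, tab, palindrome_policy = "conservative")
}

#' Odds ratio with confidence interval from a log-odds estimate
#'
#' @param beta Log-odds effect estimate(s).
#' @param se Standard error(s), `>= 0`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Data.frame with columns `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se, level = 0.95) {
  stopifnot(all(se >= 0), level > 0, level < 1)
  z <- z_crit(level)
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}
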