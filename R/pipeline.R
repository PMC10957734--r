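#' Triple significance verdict for a univariable MR result
#'
#' A causal claim is labelled significant only when (a) the IVW p-value
#' beats the Bonferroni threshold `0.05 / n_outcomes` (strict), (b) the
#' IVW, weighted-median and MR-Egger estimates agree in sign, and (c)
#' neither pleiotropy test fires: Egger intercept p and MR-PRESSO global p
#' both above 0.05. Each criterion's pass/fail is stored separately so the
#' verdict can be re-derived from a saved report.
#'
#' @param ivw_p IVW p-value.
#' @param estimate_betas Numeric vector of the three estimators' betas.
#' @param egger_intercept_p Egger intercept test p-value.
#' @param presso_global_p MR-PRESSO global test p-value.
#' @param n_outcomes Bonferroni denominator (number of outcome traits).
#' @return List with logicals `criterion_a`, `criterion_b`, `criterion_c`
#'   and `significant`.
#' @export
assess_significance <- function(ivw_p, estimate_betas, egger_intercept_p,
                                presso_global_p, n_outcomes = 1) {
  a <- ivw_p < 0.05 / n_outcomes
  signs <- sign(estimate_betas)
  b <- length(signs) > 0 && all(signs == signs[1]) && signs[1] != 0
  c_ <- egger_intercept_p > 0.05 && presso_global_p > 0.05
  list(criterion_a = a, criterion_b = b, criterion_c = c_,
       significant = a && b && c_,
       bonferroni_threshold = 0.05 / n_outcomes)
}

default_pipeline_config <- function(config = list()) {
  defaults <- list(
    p_threshold = 5e-8, r2_threshold = 0.001, window_kb = 10000,
    n_boot = 1000, n_sim = 1000, palindrome_policy = "conservative",
    eaf_threshold = 0.42, n_outcomes = 1, presso_gate = 0.05,
    seed = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) {
    stop_mrlink("a seed is required for the analysis pipeline",
                "mrlink_config_error")
  }
  cfg
}

#' Univariable MR analysis of one exposure-outcome direction
#'
#' Runs the complete univariable workflow: instrument selection, LD
#' clumping, harmonization, instrument-strength F statistics, the three
#' causal estimators, Cochran's Q, the Egger intercept test, MR-PRESSO
#' (with outlier removal and re-estimation when the global test fires),
#' leave-one-out diagnostics and the triple significance verdict. Every
#' SNP-count change between stages is logged.
#'
#' @param exposure_table,outcome_table Summary-statistics data.frames.
#' @param ld_matrix Optional LD correlation matrix for clumping (`NULL`
#'   asserts independent SNPs).
#' @param config Named list overriding the defaults: `p_threshold` (5e-8),
#'   `r2_threshold` (0.001), `window_kb` (10,000), `n_boot` (1000),
#'   `n_sim` (1000), `palindrome_policy` ("conservative"), `eaf_threshold`
#'   (0.42), `n_outcomes` (Bonferroni denominator, 1), `presso_gate`
#'   (0.05) and `seed` (required).
#' @return Object of class `mr_univariable_report`.
#' @export
run_univariable <- function(exposure_table, outcome_table, ld_matrix = NULL,
                            config = list()) {
  cfg <- default_pipeline_config(config)
  log <- list()
  note <- function(stage, n, extra = "") {
    log[[length(log) + 1]] <<- data.frame(stage = stage, n_snps = n,
                                          note = extra,
                                          stringsAsFactors = FALSE)
  }
  note("input", nrow(exposure_table))
  inst <- select_instruments(exposure_table, cfg$p_threshold)
  note("select", nrow(inst), sprintf("p < %g", cfg$p_threshold))
  inst <- clump(inst, ld_matrix, cfg$r2_threshold, cfg$window_kb)
  note("clump", nrow(inst),
       if (is.null(ld_matrix)) "no LD matrix: SNPs assumed independent"
       else sprintf("r2 < %g in %g kb", cfg$r2_threshold, cfg$window_kb))
  h <- harmonize(inst, outcome_table,
                 palindrome_policy = cfg$palindrome_policy,
                 eaf_threshold = cfg$eaf_threshold)
  audit <- attr(h, "audit")
  note("harmonize", nrow(h),
       paste(names(table(audit$action)), table(audit$action),
             sep = "=", collapse = ", "))

  strength <- instrument_strength(h)
  estimates <- mr_all_methods(h, n_boot = cfg$n_boot, seed = cfg$seed)
  ests <- attr(estimates, "estimates")
  presso <- mr_presso(h, n_sim = cfg$n_sim, seed = cfg$seed + 1L,
                      alpha = 0.05, global_gate = cfg$presso_gate)
  if (!is.null(presso$corrected_estimate)) {
    note("presso_corrected", presso$corrected_estimate$n_snps,
         paste("removed:", paste(presso$outliers, collapse = ", ")))
  }
  loo <- mr_leave_one_out(h)
  verdict <- assess_significance(
    ivw_p = ests$ivw$pval,
    estimate_betas = c(ests$ivw$beta, ests$weighted_median$beta,
                       ests$mr_egger$beta),
    egger_intercept_p = ests$mr_egger$intercept_pval,
    presso_global_p = presso$global_pval,
    n_outcomes = cfg$n_outcomes
  )
  structure(list(
    config = cfg,
    estimates = estimates,
    heterogeneity = list(q_stat = ests$ivw$q_stat, q_df = ests$ivw$q_df,
                         q_pval = ests$ivw$q_pval,
                         egger_intercept = ests$mr_egger$intercept,
                         egger_intercept_se = ests$mr_egger$intercept_se,
                         egger_intercept_pval = ests$mr_egger$intercept_pval),
    strength = unclass(strength),
    presso = list(rss_obs = presso$rss_obs, global_pval = presso$global_pval,
                  n_sim = presso$n_sim,
                  outliers = as.list(presso$outliers),
                  corrected_beta = presso$corrected_estimate$beta,
                  corrected_se = presso$corrected_estimate$se,
                  corrected_pval = presso$corrected_estimate$pval),
    leave_one_out = loo,
    verdict = verdict,
    harmonization_audit = audit,
    log = do.call(rbind, log)
  ), class = "mr_univariable_report")
}

resolve_table <- function(x, what) {
  if (is.character(x) && length(x) == 1) {
    read_summary_table(x)
  } else if (is.data.frame(x)) {
    x
  } else {
    stop_mrlink(sprintf("manifest entry '%s' must be a path or data.frame",
                        what), "mrlink_config_error")
  }
}

#' Read a square LD matrix from TSV
#'
#' Expects a tab-separated table whose header and first column hold SNP
#' ids.
#'
#' @param path File path.
#' @return Numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE, row.names = 1))
  storage.mode(m) <- "double"
  m
}

#' Write a square LD matrix as TSV
#' @param ld_matrix Matrix with SNP-id dimnames.
#' @param path File path.
#' @export
write_ld_matrix <- function(ld_matrix, path) {
  df <- data.frame(snp = rownames(ld_matrix),
                   apply(ld_matrix, 2, format_num), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Run the complete bidirectional MR study
#'
#' Orchestrates the full design over a manifest: for every outcome a
#' forward and a reverse univariable analysis with the full sensitivity
#' suite; for outcomes with a significant forward verdict, multivariable
#' MR with each covariate one at a time (direct effect of the exposure
#' adjusted for that covariate) and a two-step mediation screen over every
#' covariate. The Bonferroni denominator is the number of outcomes in the
#' manifest.
#'
#' @param manifest A named list (or path to a YAML file) with entries
#'   `exposure` (path or data.frame), `outcomes` (named list),
#'   `covariates` (named list, optional), `ld_matrix` (path or matrix,
#'   optional), `seed` (required), and any [run_univariable()] config
#'   overrides (`p_threshold`, `r2_threshold`, `window_kb`, `n_boot`,
#'   `n_sim`, `palindrome_policy`, `eaf_threshold`).
#' @param out_dir Optional directory; when given, `report.json`,
#'   `table1.tsv`, `table2.tsv`, `table3.tsv` and `audit.log` are written
#'   there via [write_study_report()].
#' @return Object of class `mr_study_report`.
#' @export
run_full_study <- function(manifest, out_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- yaml::read_yaml(manifest)
  }
  for (required in c("exposure", "outcomes", "seed")) {
    if (is.null(manifest[[required]])) {
      stop_mrlink(sprintf("manifest entry '%s' is missing", required),
                  "mrlink_config_error")
    }
  }
  exposure <- resolve_table(manifest$exposure, "exposure")
  outcomes <- lapply(names(manifest$outcomes), function(nm)
    resolve_table(manifest$outcomes[[nm]], nm))
  names(outcomes) <- names(manifest$outcomes)
  covariates <- list()
  if (!is.null(manifest$covariates)) {
    covariates <- lapply(names(manifest$covariates), function(nm)
      resolve_table(manifest$covariates[[nm]], nm))
    names(covariates) <- names(manifest$covariates)
  }
  ld <- manifest$ld_matrix
  if (is.character(ld)) ld <- read_ld_matrix(ld)

  cfg_keys <- c("p_threshold", "r2_threshold", "window_kb", "n_boot",
                "n_sim", "palindrome_policy", "eaf_threshold", "presso_gate")
  base_cfg <- manifest[intersect(cfg_keys, names(manifest))]
  base_cfg$n_outcomes <- length(outcomes)
  seed <- as.integer(manifest$seed)

  univariable <- list()
  for (i in seq_along(outcomes)) {
    nm <- names(outcomes)[i]
    fwd_cfg <- c(base_cfg, list(seed = seed + 10L * i))
    forward <- run_univariable(exposure, outcomes[[i]], ld, fwd_cfg)
    reverse <- tryCatch(
      run_univariable(outcomes[[i]], exposure, ld,
                      c(base_cfg, list(seed = seed + 10L * i + 5L))),
      mrlink_error = function(e) {
        list(status = "failed", message = conditionMessage(e),
             verdict = list(significant = FALSE))
      })
    univariable[[nm]] <- list(forward = forward, reverse = reverse)
  }

  mvmr <- list()
  mediation <- list()
  for (nm in names(univariable)) {
    if (!isTRUE(univariable[[nm]]$forward$verdict$significant)) next
    for (cv in names(covariates)) {
      ds <- make_mvmr_dataset(
        exposures = stats::setNames(list(exposure, covariates[[cv]]),
                                    c("exposure", cv)),
        outcome = outcomes[[nm]],
        p_threshold = base_cfg$p_threshold %||% 5e-8, ld_matrix = ld)
      fit <- mvmr_ivw(ds)
      e <- fit$estimates$exposure
      mvmr[[nm]][[cv]] <- list(
        adjustment = cv, n_snps = fit$n_snps, beta = e$beta, se = e$se,
        pval = e$pval, or = e$or, or_ci_low = e$or_ci_low,
        or_ci_high = e$or_ci_high,
        conditional_f = as.list(fit$conditional_f))
      med <- run_mediation(exposure, covariates[[cv]], outcomes[[nm]],
                           p_threshold = base_cfg$p_threshold %||% 5e-8,
                           ld_matrix = ld)
      mediation[[nm]][[cv]] <- list(
        mediator = cv,
        beta1 = med$beta1, beta2 = med$beta2, total = med$total,
        indirect = med$indirect, proportion = med$proportion,
        provenance = attr(med, "provenance"))
    }
  }

  report <- structure(list(
    provenance = list(
      package = "mrlink",
      version = as.character(utils::packageVersion("mrlink")),
      seed = seed,
      n_outcomes = length(outcomes),
      bonferroni_denominator = length(outcomes),
      config = c(base_cfg),
      inputs = list(
        exposure = if (is.character(manifest$exposure)) manifest$exposure
          else "<in-memory>",
        outcomes = lapply(manifest$outcomes, function(x)
          if (is.character(x)) x else "<in-memory>"),
        covariates = lapply(manifest$covariates %||% list(), function(x)
          if (is.character(x)) x else "<in-memory>")
      )
    ),
    univariable = univariable,
    mvmr = mvmr,
    mediation = mediation
  ), class = "mr_study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

strip_classes <- function(x) {
  if (is.data.frame(x)) {
    attr(x, "full") <- NULL
    attr(x, "estimates") <- NULL
    return(as.data.frame(x))
  }
  if (is.matrix(x)) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    attributes(x) <- attributes(x)["names"]
    return(lapply(x, strip_classes))
  }
  x
}

#' Write a study report to disk
#'
#' Serializes an `mr_study_report` to `report.json` (10-significant-digit
#' floats, deterministic for a fixed manifest and seed) plus flat TSV
#' tables: `table1.tsv` (univariable estimates and sensitivity statistics
#' per direction), `table2.tsv` (MVMR adjustments), `table3.tsv`
#' (mediation screen) and `audit.log` (per-stage SNP counts).
#'
#' @param report An `mr_study_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the path to `report.json`.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(strip_classes(report), json_path, digits = 10,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")

  t1 <- list()
  for (nm in names(report$univariable)) {
    for (dir in c("forward", "reverse")) {
      frag <- report$univariable[[nm]][[dir]]
      if (!is.null(frag$status) && frag$status == "failed") next
      est <- frag$estimates
      t1[[length(t1) + 1]] <- data.frame(
        outcome = nm, direction = dir, method = est$method,
        nsnp = est$nsnp, f_stat = frag$strength$f_stat,
        beta = est$beta, se = est$se, pval = est$pval, or = est$or,
        or_ci_low = est$or_ci_low, or_ci_high = est$or_ci_high,
        heterogeneity_p = frag$heterogeneity$q_pval,
        egger_intercept_p = frag$heterogeneity$egger_intercept_pval,
        presso_global_p = frag$presso$global_pval,
        significant = frag$verdict$significant,
        stringsAsFactors = FALSE)
    }
  }
  write_tsv_formatted(do.call(rbind, t1), file.path(out_dir, "table1.tsv"))

  t2 <- list()
  for (nm in names(report$mvmr)) {
    for (cv in names(report$mvmr[[nm]])) {
      r <- report$mvmr[[nm]][[cv]]
      t2[[length(t2) + 1]] <- data.frame(
        outcome = nm, adjustment = cv, nsnp = r$n_snps, or = r$or,
        or_ci_low = r$or_ci_low, or_ci_high = r$or_ci_high, pval = r$pval,
        stringsAsFactors = FALSE)
    }
  }
  if (length(t2)) {
    write_tsv_formatted(do.call(rbind, t2), file.path(out_dir, "table2.tsv"))
  }

  t3 <- list()
  for (nm in names(report$mediation)) {
    for (cv in names(report$mediation[[nm]])) {
      r <- report$mediation[[nm]][[cv]]
      t3[[length(t3) + 1]] <- data.frame(
        outcome = nm, mediator = cv,
        proportion_pct = 100 * r$proportion$estimate,
        ci_low_pct = 100 * r$proportion$ci_low,
        ci_high_pct = 100 * r$proportion$ci_high,
        pval = r$proportion$pval, indirect = r$indirect$beta,
        indirect_p = r$indirect$pval, stringsAsFactors = FALSE)
    }
  }
  if (length(t3)) {
    write_tsv_formatted(do.call(rbind, t3), file.path(out_dir, "table3.tsv"))
  }

  lines <- character(0)
  for (nm in names(report$univariable)) {
    for (dir in c("forward", "reverse")) {
      frag <- report$univariable[[nm]][[dir]]
      if (!is.null(frag$status) && frag$status == "failed") {
        lines <- c(lines, sprintf("%s/%s\tfailed\t%s", nm, dir,
                                  frag$message))
        next
      }
      lines <- c(lines, sprintf("%s/%s\t%s\tn=%d\t%s", nm, dir,
                                frag$log$stage, frag$log$n_snps,
                                frag$log$note))
    }
  }
  writeLines(lines, file.path(out_dir, "audit.log"))
  invisible(json_path)
}

write_tsv_formatted <- function(df, path) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- format_num(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
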