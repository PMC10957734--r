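#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulation helpers never perturb global
# reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Canonical float formatting used everywhere a table or report is written:
# 10 significant digits, plain (non-scientific where possible) representation.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

stop_mrlink <- function(message, class) {
  stop(structure(
    class = c(class, "mrlink_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mrlink(sprintf("configuration field '%s' must be a finite number", field),
                "mrlink_config_error")
  }
  invisible(x)
}

z_crit <- function(level) stats::qnorm((1 + level) / 2)

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))
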