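# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic sub-seed derivation: one root seed, fixed offsets per
# subject / session / purpose, so adding subjects never perturbs the
# streams of existing ones. Offsets are spaced so purposes cannot collide
# for subject_index <= 20000 and session_index <= 12.
derive_seed <- function(seed, subject_index = 0L, session_index = 0L, purpose = 0L) {
  (as.double(seed) + 104729 * subject_index + 7919 * session_index + purpose) %% 2147483647
}

#' Format an estimate with its 95\% confidence interval
#'
#' Renders `"2.420 (95\% CI 2.161-2.628)"`-style strings (en dash between
#' bounds) used throughout pipeline reports.
#'
#' @param estimate point estimate.
#' @param lower,upper interval bounds.
#' @param digits decimal places (default 3).
#' @return character scalar.
#' @export
format_ci <- function(estimate, lower, upper, digits = 3) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (95%% CI ", fmt, "–", fmt, ")"), estimate, lower, upper)
}

# mean with two-sided t-based 95% CI
mean_ci <- function(x, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(list(mean = m, lower = NA_real_, upper = NA_real_, n = n))
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
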