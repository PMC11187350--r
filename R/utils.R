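#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published ratio tables round half up
#' (e.g. 19/32 of 100 prints as 59.38). Operates on non-negative values.
#'
#' @param x numeric vector, non-negative.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 2L) {
  scale <- 10^digits
  # nudge by a relative epsilon so binary representations of exact halves
  # (e.g. 59.375) land on the correct side of floor()
  floor(x * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) `.Random.seed` afterwards so generators never leak
#' global random state.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Uppercase, trim, drop empties -- the only gene-symbol normalization applied
# anywhere (exact string matching; no alias or ortholog resolution).
normalize_symbols <- function(x) {
  x <- toupper(trimws(x))
  x[nzchar(x)]
}

# Lowercase, trim -- cohort symptom terms are free strings compared
# case-insensitively.
normalize_terms <- function(x) {
  x <- tolower(trimws(x))
  x[nzchar(x)]
}

stop_input <- function(...) stop(..., call. = FALSE)
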