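# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. All generator functions route their randomness through this
# so that a given seed is reproducible regardless of surrounding code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-stage seed from a master seed, kept within 32-bit range.
# Doubles hold the intermediate product exactly (< 2^53), so chained
# derivations cannot overflow.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483587)
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# The study's four treatment groups and the four prespecified post hoc pairs.
#' Treatment group labels and post hoc pairs
#'
#' The four treatment groups of the crossed early-life (STD vs LBN) by adult
#' (CON vs ALPS) design, and the four prespecified post hoc comparisons:
#' within-rearing stress effects (STD-CON vs STD-ALPS, LBN-CON vs LBN-ALPS)
#' and within-adult-treatment rearing effects (STD-CON vs LBN-CON,
#' STD-ALPS vs LBN-ALPS).
#'
#' @return `psc_groups()` returns a character vector of the four labels;
#'   `psc_posthoc_pairs()` a list of four length-2 character vectors.
#' @export
#' @examples
#' psc_groups()
#' psc_posthoc_pairs()
psc_groups <- function() {
  c("STD-CON", "STD-ALPS", "LBN-CON", "LBN-ALPS")
}

#' @rdname psc_groups
#' @export
psc_posthoc_pairs <- function() {
  list(
    c("STD-CON", "STD-ALPS"),
    c("LBN-CON", "LBN-ALPS"),
    c("STD-CON", "LBN-CON"),
    c("STD-ALPS", "LBN-ALPS")
  )
}
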