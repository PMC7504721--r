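#' Round half away from zero
#'
#' Base `round()` rounds half to even, which would report a hit rate of
#' 95/2000 as 4.8 or 4.7 depending on representation. Screening bookkeeping
#' uses conventional half-up rounding so printed rates match what a bench
#' scientist computes by hand.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(4.75, 1) # 4.8
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared argument checks -----------------------------------------------------

check_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (non_negative && x < 0) abort(sprintf("`%s` must be non-negative.", name))
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Derive a stream-specific RNG seed from a base seed. Keeps derived seeds
# inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
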