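# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores whatever state existed before, so seeded package functions do
#' not disturb a user's random stream. With `seed = NULL` the code runs
#' against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Commercial rounding used for display values (R's `round()` rounds half
#' to even, which turns 0.00625 into 0.0062 rather than the conventional
#' 0.0063).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.05 / 8, 4)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded for display
#'
#' @param n Count in the category.
#' @param total Stratum size.
#' @param digits Decimal places (default 1, the usual table convention).
#' @return `100 * n / total`, rounded half away from zero.
#' @export
pct <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

# two-sided normal p from an estimate and its SE
z_pval <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# 95% normal CI
z_ci <- function(est, se, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(est - q * se, est + q * se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
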