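#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used by
#' most sequencing-facility reports), unlike [base::round()]'s banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)       # 3, not 2
#' round_half_up(97.045, 2) # 97.05
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a total
#'
#' `100 * numerator / denominator`, rounded half-up. Used for base-retention
#' percentages after read filtering and annotation-coverage shares.
#'
#' @param numerator,denominator Non-negative numerics; `denominator` must be
#'   positive.
#' @param digits Decimal places to report (2 for retention tables, 1 for
#'   annotation shares).
#' @return Percentage on the 0-100 scale.
#' @export
#' @examples
#' percent_of(30147, 52474, digits = 1)
percent_of <- function(numerator, denominator, digits = 2) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) {
    stop("percent_of(): denominator must be positive")
  }
  if (any(numerator < 0)) {
    stop("percent_of(): numerator must be non-negative")
  }
  round_half_up(100 * numerator / denominator, digits)
}

#' Average contig length of an assembly
#'
#' Total assembled characters divided by the number of contigs, reported to
#' 2 decimals as in standard assembly summary tables.
#'
#' @param total_characters Total bases across contigs.
#' @param n_contigs Number of contigs (positive).
#' @return Mean contig length in bp.
#' @export
average_contig_length <- function(total_characters, n_contigs) {
  stopifnot(is.numeric(total_characters), is.numeric(n_contigs))
  if (any(n_contigs <= 0)) stop("average_contig_length(): n_contigs must be positive")
  round_half_up(total_characters / n_contigs, 2)
}

# internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: stop unless x is a single finite number
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
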