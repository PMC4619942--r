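#' The 1.4.3.-2 minifloat count codec
#'
#' An 8-bit IEEE-754-inspired float used as a saturating approximate
#' counter: 1 sign bit (the strand flag; the pattern negative zero is
#' reserved as the hash-collision flag), 4 exponent bits, 3 mantissa bits,
#' exponent bias -2. Subnormal values (`e = 0`) decode to `t`; normalized
#' values to `(1 + t/8) * 2^(e+2)`. Every integer 1..15 (and 16) is exactly
#' representable; the largest finite value is 122,880 at `e = 1110`,
#' `t = 111`. The top exponent `e = 1111` is reserved and never produced.
#'
#' `mf_decode` accepts bit patterns 0..255 and returns the decoded count
#' (`NA` for the reserved band), the sign/strand bit, whether the pattern is
#' the collision flag -0, and whether it is finite.
#'
#' @param b integer vector of bit patterns in 0..255.
#' @return `mf_decode`: a data.frame with columns `value`, `strand`,
#'   `collision`, `finite`.
#' @examples
#' mf_decode(mf_encode_exact(15))$value  # 15
#' mf_decode(0x77)$value                 # 122880 / 2^... see mf_table()
#' @export
mf_decode <- function(b) {
  res <- cpp_mf_decode(as.integer(b))
  data.frame(value = res$value, strand = res$strand,
             collision = res$collision, finite = res$finite)
}

#' @rdname mf_decode
#' @param c non-negative integer counts.
#' @return `mf_encode_exact`: integer bit patterns, `NA` where the count is
#'   not exactly representable (e.g. 17).
#' @export
mf_encode_exact <- function(c) cpp_mf_encode_exact(as.numeric(c))

#' @rdname mf_decode
#' @return `mf_successor`: the bit pattern of the smallest representable
#'   value greater than `decode(b)`, `NA` when `b` is maximal (saturation).
#'   In exponent band `e >= 2` the gap to the successor is `2^(e-1)`.
#' @export
mf_successor <- function(b) cpp_mf_successor(as.integer(b))

#' Probabilistic (Morris-style) increment
#'
#' Advances the counter to its successor with probability `1/gap`, where
#' `gap` is the distance to the next representable value; advances
#' deterministically while the gap is 1 (counts through 16) and saturates
#' at 122,880. The expected advance is exactly 1 at every state, so the
#' decoded value is an unbiased estimate of the true count. Uses the R RNG
#' (`set.seed()` applies).
#'
#' @param b integer vector of bit patterns (sign bit preserved).
#' @return Integer vector of updated bit patterns.
#' @export
mf_prob_increment <- function(b) cpp_mf_increment(as.integer(b))

#' Stream n increments into fresh counters
#'
#' Applies `n` true increments to a zero-initialised counter, `reps`
#' independent times, and returns each replicate's final decoded value.
#' Distributionally identical to `n` calls of [mf_prob_increment()] per
#' replicate, but uses geometric skip-ahead so large-count concordance
#' experiments (10,000 replicates per logarithmic bin) run in milliseconds.
#'
#' @param n true count (number of increments).
#' @param reps number of independent replicates.
#' @return Numeric vector of `reps` decoded final values.
#' @export
mf_count_stream <- function(n, reps) {
  stopifnot(n >= 0, reps >= 0)
  cpp_mf_count_stream(as.numeric(n), as.integer(reps))
}

#' Full decode table of the 256 bit patterns
#'
#' @return A data.frame with `pattern` (0..255), `sign`, `exponent`,
#'   `mantissa` and the [mf_decode()] columns; convenient for inspecting
#'   the codec against its defining formulas.
#' @export
mf_table <- function() {
  b <- 0:255
  cbind(
    data.frame(pattern = b,
               sign = bitwAnd(bitwShiftR(b, 7L), 1L),
               exponent = bitwAnd(bitwShiftR(b, 3L), 15L),
               mantissa = bitwAnd(b, 7L)),
    mf_decode(b)
  )
}
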