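#' 2-bit DNA encoding
#'
#' Encodes a DNA string over `{A,C,G,T}` into a packed 2-bit representation
#' with `A=00, C=01, G=10, T=11`, most-significant bits first within each
#' byte. Under this code table the complement of a base is the bitwise NOT of
#' its 2-bit code (`A<->T`, `C<->G`), which is what makes the XOR fold of
#' [xor_fold()] strand-invariant.
#'
#' @param s a DNA string (case-insensitive). Characters outside `A,C,G,T`
#'   are an error; ambiguous bases are handled upstream by
#'   [extract_seeds()], which skips affected windows.
#' @return An `encoded_seq`: a list with `length` (bases) and `payload`
#'   (raw vector of packed codes).
#' @examples
#' x <- encode_dna("ACGT")
#' decode_dna(x)
#' @export
encode_dna <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  structure(
    list(length = nchar(s), payload = cpp_pack(s)),
    class = "encoded_seq"
  )
}

#' @rdname encode_dna
#' @param x an `encoded_seq`.
#' @export
decode_dna <- function(x) {
  stopifnot(inherits(x, "encoded_seq"))
  cpp_unpack(x$payload, x$length)
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat("<encoded_seq> ", x$length, " bases: ", decode_dna(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.encoded_seq <- function(x) x$length

as_dna_string <- function(x) {
  if (inherits(x, "encoded_seq")) decode_dna(x) else {
    stopifnot(is.character(x), length(x) == 1L)
    toupper(x)
  }
}

#' Reverse complement
#'
#' Reverses the sequence and complements each base via the 2-bit bitwise NOT.
#' An involution: `revcomp(revcomp(x))` equals `x`.
#'
#' @param x a DNA string or an `encoded_seq`.
#' @return Same type as the input.
#' @export
revcomp <- function(x) UseMethod("revcomp")

#' @export
revcomp.character <- function(x) {
  vapply(x, cpp_revcomp_str, character(1), USE.NAMES = FALSE)
}

#' @export
revcomp.encoded_seq <- function(x) encode_dna(cpp_revcomp_str(decode_dna(x)))

#' Canonical form of a sequence
#'
#' The lexicographically smaller of a sequence and its reverse complement
#' under the 2-bit code order (which coincides with `A<C<G<T`). Collapses
#' the two strands: `canonical(x) == canonical(revcomp(x))`.
#'
#' @inheritParams revcomp
#' @return Same type as the input.
#' @export
canonical <- function(x) UseMethod("canonical")

#' @export
canonical.character <- function(x) {
  vapply(x, cpp_canonical_str, character(1), USE.NAMES = FALSE)
}

#' @export
canonical.encoded_seq <- function(x) encode_dna(cpp_canonical_str(decode_dna(x)))

#' Strided substring with index origin 1
#'
#' Returns the bases at positions `a, a+b, a+2b, ... <= c` (1-based,
#' inclusive). This is the one interface in the package that keeps 1-based
#' coordinates, so that the left/right/odd/even subsequences used by
#' [seed_hashes()] read off directly: left `= (1:1:k)`, right
#' `= (k+1:1:2k)`, odd `= (1:2:2k-1)`, even `= (2:2:2k)`.
#'
#' @param x a DNA string or `encoded_seq`.
#' @param a,c 1-based start and end positions, `1 <= a <= c <= length`.
#' @param b stride, `>= 1`.
#' @return Same type as the input.
#' @examples
#' substride("ACGTACGT", 1, 2, 7)  # "AGAG"
#' @export
substride <- function(x, a, b, c) {
  s <- as_dna_string(x)
  n <- nchar(s)
  if (!(a >= 1 && a <= c && c <= n)) stop("substride indices out of range")
  if (b < 1) stop("stride must be >= 1")
  out <- paste(strsplit(s, "", fixed = TRUE)[[1]][seq(a, c, by = b)],
               collapse = "")
  if (inherits(x, "encoded_seq")) encode_dna(out) else out
}

#' Spaced-seed template
#'
#' A spaced seed is two k-mers `[k:k]` separated by a fixed gap of `delta`
#' bases; the template spans `2k + delta` bases and a read of length `L`
#' yields `max(0, L - (2k + delta) + 1)` seeds. Odd `k` is recommended: no
#' odd-length k-mer equals its own reverse complement, so the XOR fold of a
#' seed half can never degenerate to all-zero bits.
#'
#' @param k seed (k-mer) length in bases, `>= 1`.
#' @param delta gap length in bases, `>= 0`.
#' @return A `seed_template` with fields `k`, `delta`, `span`.
#' @export
seed_template <- function(k, delta) {
  stopifnot(k >= 1, delta >= 0)
  k <- as.integer(k); delta <- as.integer(delta)
  structure(list(k = k, delta = delta, span = 2L * k + delta),
            class = "seed_template")
}

#' @export
print.seed_template <- function(x, ...) {
  cat("<seed_template> [", x$k, ":", x$k, "] gap ", x$delta,
      " (span ", x$span, " bp)\n", sep = "")
  invisible(x)
}

#' Extract spaced seeds from a read
#'
#' Slides the template across the read and emits one seed per window. The
#' gap bases are not stored; windows whose *seed* positions contain a
#' non-ACGT base are skipped (a gap base may contain anything, since errors
#' and ambiguity there cannot affect the stored sequence).
#'
#' @param read a DNA string.
#' @param template a [seed_template()].
#' @return A data.frame with `origin` (0-based offset of the left k-mer's
#'   first base, strictly increasing) and `s2k` (the concatenated `[k:k]`
#'   seed content, length `2k`).
#' @export
extract_seeds <- function(read, template) {
  stopifnot(inherits(template, "seed_template"))
  res <- cpp_extract_seeds(toupper(read), template$k, template$delta)
  data.frame(origin = res$origin, s2k = res$s2k, stringsAsFactors = FALSE)
}
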