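#' Salted 64-bit base hash
#'
#' The hash function `H` underlying all filter coordinates: FNV-1a style
#' byte accumulation followed by a multiply-XOR avalanche finalizer, salted.
#' Deterministic and identical across platforms for identical input bytes
#' and salt. 64-bit values are returned as 16-character lower-case hex
#' strings so they survive R's numeric types exactly.
#'
#' @param data a raw vector, or a character string (hashed as its bytes).
#' @param salt a non-negative integer salt (default 0).
#' @return A 16-character hex string.
#' @export
base_hash <- function(data, salt = 0) {
  if (is.character(data)) data <- charToRaw(data)
  stopifnot(is.raw(data))
  cpp_base_hash(data, as.numeric(salt))
}

#' XOR fold of a sequence with its reverse complement
#'
#' XORs the 2-bit packing of `x` with the 2-bit packing of `revcomp(x)`.
#' Because XOR commutes, `xor_fold(x) == xor_fold(revcomp(x))`: hashing the
#' fold makes every downstream coordinate strand-invariant without an
#' explicit canonicalisation step. The price is that any reverse-complement
#' palindrome folds to all-zero bits; with odd `k` no k-mer is such a
#' palindrome, which is why odd `k` is the recommended default.
#'
#' @param x a DNA string or `encoded_seq`.
#' @return A raw vector of folded packed bytes.
#' @export
xor_fold <- function(x) cpp_fold(as_dna_string(x))

#' The four strand-folded hash values of a spaced seed
#'
#' For a concatenated seed `S` of length 2k, computes
#' `xL = H{fold(S(1:1:k))}`, `xR = H{fold(S(k+1:1:2k))}`,
#' `xO = H{fold(S(1:2:2k-1))}`, `xE = H{fold(S(2:2:2k))}` — the left,
#' right, odd and even hash values, with the substring taken before reverse
#' complementation. These four values are used directly as the Bloom
#' filter's h = 4 hash functions. Under reverse complementation the (L,R)
#' pair and the (O,E) pair each swap, so inserting a seed and querying its
#' reverse complement touch the same four bits.
#'
#' @param s2k the concatenated seed (string or `encoded_seq`) of length 2k.
#' @param k the seed length; defaults to half the sequence length.
#' @return Named character vector of four 64-bit hex values
#'   (`xL`, `xR`, `xO`, `xE`).
#' @export
seed_hashes <- function(s2k, k = NULL) {
  s <- as_dna_string(s2k)
  if (is.null(k)) {
    if (nchar(s) %% 2 != 0) stop("s2k must have even length")
    k <- nchar(s) %/% 2
  }
  cpp_seed_hashes(s, as.integer(k))
}

#' Strand-sensitive hash pair
#'
#' `hF` hashes the un-folded 2-bit packing of `s2k`; `hR` hashes that of its
#' reverse complement, under a salt distinct from [seed_hashes()]. Unlike
#' the folded quadruple these distinguish the two strands:
#' `strand_hash_pair(revcomp(S))` is `(hR, hF)`. The cascade counter uses
#' them as the byte-array coordinates `x` and `x'`, whose asymmetry carries
#' the strand information recorded in the minifloat sign bit.
#'
#' @inheritParams seed_hashes
#' @return Named character vector (`hF`, `hR`) of 64-bit hex values.
#' @export
strand_hash_pair <- function(s2k) cpp_strand_hash_pair(as_dna_string(s2k))
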