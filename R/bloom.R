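#' Bloom filter false positive rate
#'
#' The approximate false positive rate of a Bloom filter with `h` hash
#' functions holding `n` sequences in `m` bits:
#' `f = (1 - exp(-h n / m))^h`. At the optimal load `h n / m = ln 2` with
#' `h = 4` this gives `f = 0.5^4 = 6.25%`.
#'
#' @param h number of hash functions, `>= 1`.
#' @param n number of stored sequences, `>= 0`.
#' @param m filter size in bits, `> 0`.
#' @return The false positive probability in `[0, 1)`.
#' @export
bloom_fpr <- function(h, n, m) {
  stopifnot(h >= 1, n >= 0)
  if (any(m <= 0)) stop("m must be positive")
  (1 - exp(-h * n / m))^h
}

#' Optimal number of hash functions
#'
#' `h* = (m / n) ln 2`, the hash count minimising the false positive rate
#' at fixed `m` and `n`.
#'
#' @inheritParams bloom_fpr
#' @return The (real-valued) optimal hash count.
#' @export
bloom_optimal_h <- function(m, n) {
  if (any(n <= 0)) stop("n must be positive")
  (m / n) * log(2)
}

#' Filter size for a target false positive rate
#'
#' Smallest `m` (in bits) with `bloom_fpr(h, n, m) <= target_fpr`. Obtained
#' by inverting the FPR formula: `m = ceiling(-h n / log(1 - f^{1/h}))`.
#'
#' @inheritParams bloom_fpr
#' @param target_fpr target false positive probability in (0, 1).
#' @return Filter size in bits (numeric; may exceed `.Machine$integer.max`).
#' @export
bloom_size_for <- function(n, h, target_fpr) {
  stopifnot(target_fpr > 0, target_fpr < 1, h >= 1)
  if (n == 0) return(1)
  m <- ceiling(-h * n / log(1 - target_fpr^(1 / h)))
  m <- max(m, 1)
  # ceiling in floating point can land one off the true minimum
  while (m > 1 && bloom_fpr(h, n, m - 1) <= target_fpr) m <- m - 1
  while (bloom_fpr(h, n, m) > target_fpr) m <- m + 1
  m
}

#' Spaced-seed Bloom filter
#'
#' A bit array of `m` bits addressed by the four strand-folded hash values
#' of [seed_hashes()] (`h = 4`, position `= hash mod m`). Membership is
#' automatically strand-canonical: inserting a seed and querying its
#' reverse complement hit the same four bits. There are never false
#' negatives.
#'
#' The returned object has reference semantics (the bit array lives in an
#' external pointer): [bloom_insert()] mutates it in place.
#'
#' @param m filter size in bits.
#' @param template a [seed_template()].
#' @return A `seed_bloom` object.
#' @export
seed_bloom <- function(m, template) {
  stopifnot(inherits(template, "seed_template"))
  structure(
    list(ptr = cpp_bloom_new(as.numeric(m), template$k, template$delta),
         template = template),
    class = "seed_bloom"
  )
}

#' @export
print.seed_bloom <- function(x, ...) {
  p <- cpp_bloom_params(x$ptr)
  cat(sprintf(
    "<seed_bloom> m = %s bits, k = %d, delta = %d, %s inserts, load %.3f\n",
    format(p$m, big.mark = ","), p$k, p$delta,
    format(p$n_inserted, big.mark = ","), p$bits_set / p$m))
  invisible(x)
}

#' Filter bookkeeping
#'
#' @param bf a [seed_bloom()].
#' @return A list with `m`, `k`, `delta`, `n_inserted` (insert calls) and
#'   `bits_set`.
#' @export
bloom_params <- function(bf) cpp_bloom_params(bf$ptr)

check_seeds <- function(seeds) {
  if (is.data.frame(seeds)) seeds <- seeds$s2k
  if (inherits(seeds, "encoded_seq")) seeds <- decode_dna(seeds)
  as.character(seeds)
}

#' Insert spaced seeds
#'
#' Sets the four bits of each seed and reports, per seed, which bits were
#' already set *before* the insertion (the hit pattern, in order
#' `xL, xR, xO, xE`). An all-`TRUE` row means the seed — or its reverse
#' complement — had been observed before (modulo false positives); the
#' cascade counter uses exactly this signal to engage its second stage.
#'
#' @param bf a [seed_bloom()] (mutated in place).
#' @param seeds character vector of 2k-length seed sequences, or the
#'   data.frame returned by [extract_seeds()].
#' @return Logical matrix (seeds x 4) of pre-insert hits, invisibly.
#' @export
bloom_insert <- function(bf, seeds) {
  invisible(cpp_bloom_insert(bf$ptr, check_seeds(seeds)))
}

#' Query spaced seeds
#'
#' Per-hash-value bit membership; does not mutate the filter.
#'
#' @inheritParams bloom_insert
#' @return Logical matrix (seeds x 4), columns `xL, xR, xO, xE`.
#' @export
bloom_query <- function(bf, seeds) cpp_bloom_query(bf$ptr, check_seeds(seeds))

#' Full membership (all four bits set)
#'
#' @inheritParams bloom_insert
#' @return Logical vector.
#' @export
bloom_contains <- function(bf, seeds) {
  rowSums(bloom_query(bf, seeds)) == 4L
}

#' Insert / query every seed window of a read
#'
#' Batch versions of [bloom_insert()] / [bloom_query()] that extract the
#' windows internally (skipping windows with non-ACGT seed bases).
#'
#' @param bf a [seed_bloom()].
#' @param read a DNA string.
#' @return A list with `origin` (0-based window offsets) and `pre`
#'   (resp. `hits`): logical matrix of per-window hit patterns.
#' @export
bloom_insert_read <- function(bf, read) {
  invisible(cpp_bloom_insert_read(bf$ptr, toupper(read)))
}

#' @rdname bloom_insert_read
#' @export
bloom_query_read <- function(bf, read) cpp_bloom_query_read(bf$ptr, toupper(read))

#' Probe the four 1-base extensions of an assembled tail
#'
#' `tail` is the last `span - 1` bases of a growing contig; for each base
#' `b` in `A,C,G,T` the spaced seed of `paste0(tail, b)` is tested for full
#' membership. Because the seed's left k-mer comes from already-assembled
#' sequence, a hit simultaneously validates the lagging wave front.
#'
#' @param bf a [seed_bloom()].
#' @param tail a DNA string of length `span - 1`.
#' @return Named logical vector over `A, C, G, T`.
#' @export
bloom_next_bases <- function(bf, tail) cpp_bloom_next(bf$ptr, tail)

#' Single-scale k-mer sub-query
#'
#' Probes a lone k-mer's folded hash against the same bit array. This is
#' the small length scale of the structure (scale `k` as opposed to
#' `2k + delta`); with only one hash value its false positive rate is
#' `1 - (1 - load)^1`, far above the four-hash rate, so it is used only as
#' a fallback.
#'
#' @param bf a [seed_bloom()].
#' @param kmer a DNA string of length `k`.
#' @return Logical scalar.
#' @export
bloom_kmer_contains <- function(bf, kmer) cpp_bloom_kmer_query(bf$ptr, toupper(kmer))

# Binary serialization. Header (little-endian): magic "SSBF", version int32,
# k int32, delta int32, m double, n_inserted double, then the raw bit array
# (LSB-first within bytes).
#' Serialize / restore a seed Bloom filter
#'
#' @param bf a [seed_bloom()].
#' @param path file path.
#' @return `bloom_save` returns `path` invisibly; `bloom_load` a
#'   [seed_bloom()].
#' @export
bloom_save <- function(bf, path) {
  p <- cpp_bloom_params(bf$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SSBF"), con)
  writeBin(c(1L, p$k, p$delta), con, size = 4L, endian = "little")
  writeBin(c(p$m, p$n_inserted), con, size = 8L, endian = "little")
  writeBin(cpp_bloom_bits(bf$ptr), con)
  invisible(path)
}

#' @rdname bloom_save
#' @export
bloom_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "SSBF") stop("not a seed_bloom file")
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stop("unsupported version ", hdr[1])
  nums <- readBin(con, "double", 2L, size = 8L, endian = "little")
  bits <- readBin(con, "raw", ceiling(nums[1] / 8))
  structure(
    list(ptr = cpp_bloom_from_bits(nums[1], hdr[2], hdr[3], nums[2], bits),
         template = seed_template(hdr[2], hdr[3])),
    class = "seed_bloom"
  )
}
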