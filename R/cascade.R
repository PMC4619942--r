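#' Cascading counting Bloom filter
#'
#' A two-stage counting structure for spaced seeds. Stage 1 is a
#' [seed_bloom()]: it records every first observation. When an insert finds
#' all four bits already set — the seed has been observed at least twice —
#' the seed *cascades* to stage 2, a byte array of `m2` minifloat counters
#' ([mf_decode()]). The strand-sensitive hash pair ([strand_hash_pair()])
#' yields two byte coordinates, `x = hF mod m2` for the seed as presented
#' and `x' = hR mod m2` for its reverse complement; the update rules of
#' [cascade_update_rule()] decide which byte to set, increment, or flag.
#' The minifloat sign bit records observation on both strands; the reserved
#' pattern negative zero flags a coordinate-pair collision.
#'
#' Reference semantics: [cascade_add()] mutates the counter in place.
#'
#' @param m stage-1 size in bits.
#' @param template a [seed_template()].
#' @param m2 stage-2 size in bytes; default `m / 8` (same memory as
#'   stage 1).
#' @return A `cascade_counter` object.
#' @export
cascade_counter <- function(m, template, m2 = ceiling(m / 8)) {
  stopifnot(inherits(template, "seed_template"))
  structure(
    list(ptr = cpp_cascade_new(as.numeric(m), as.numeric(m2),
                               template$k, template$delta),
         template = template),
    class = "cascade_counter"
  )
}

#' @export
print.cascade_counter <- function(x, ...) {
  p <- cpp_cascade_params(x$ptr)
  cat(sprintf(
    "<cascade_counter> stage1 %s bits + stage2 %s bytes, k = %d, delta = %d, %s inserts\n",
    format(p$m, big.mark = ","), format(p$m2, big.mark = ","),
    p$k, p$delta, format(p$n_inserted, big.mark = ",")))
  invisible(x)
}

#' Add spaced seeds to the cascade
#'
#' @param counter a [cascade_counter()] (mutated in place).
#' @param seeds character vector of 2k-length seeds, or an
#'   [extract_seeds()] data.frame.
#' @return Integer vector of the stage reached per seed (1 = recorded in
#'   the stage-1 filter only; 2 = cascaded to the byte array), invisibly.
#' @export
cascade_add <- function(counter, seeds) {
  invisible(cpp_cascade_add(counter$ptr, check_seeds(seeds)))
}

#' @rdname cascade_add
#' @param read a DNA string; all its seed windows are added in order.
#' @export
cascade_add_read <- function(counter, read) {
  invisible(cpp_cascade_add_read(counter$ptr, toupper(read)))
}

#' Query cascade counts
#'
#' Reads the byte pair `(x, x')` of each seed. A negative zero at either
#' coordinate means the count was lost to a collision (`collided`).
#' Otherwise the estimate is the decoded minifloat at whichever byte is
#' nonzero; 1 if both bytes are zero but the stage-1 filter holds the seed;
#' 0 if the seed was never observed.
#'
#' @inheritParams cascade_add
#' @return A data.frame with `estimate` (`NA` when collided),
#'   `both_strands` (minifloat sign of the counting byte) and `collided`.
#' @export
cascade_count <- function(counter, seeds) {
  res <- cpp_cascade_count(counter$ptr, check_seeds(seeds))
  data.frame(estimate = res$estimate, both_strands = res$both_strands,
             collided = res$collided)
}

#' Stage-2 update rule
#'
#' The total 9-case mapping on byte-state classes (zero `+0`, negative zero
#' `-0`, nonzero) applied when a seed cascades, exposed for direct
#' inspection:
#' \itemize{
#'   \item `(0, 0 | -0)` set `x` to count 2, sign 0;
#'   \item `(nonzero, 0 | -0)` increment `x`, sign unchanged;
#'   \item `(0 | -0, nonzero)` increment `x'`, set its sign to 1 (observed
#'     on both strands);
#'   \item `(nonzero, nonzero)` and `(-0, -0)` collision: truncate both to
#'     `-0` (negative zero counts as nonzero here, guarding against
#'     secondary collisions);
#'   \item `(-0, 0)` set `x'` to count 2, sign 1.
#' }
#' "Increment" is the probabilistic minifloat increment
#' ([mf_prob_increment()]).
#'
#' @param vx,vxp byte values (0..255) at coordinates `x` and `x'`.
#' @param same_coord set when `x == x'` (reverse-complement-palindromic
#'   seed or a modulus collision of the pair): the single byte is then
#'   set/incremented and the sign is never raised.
#' @return A list with the updated `vx`, `vxp` and an `action` label
#'   (`set_x`, `increment_x`, `increment_xp`, `set_xp`, `flag_collision`,
#'   `none`).
#' @export
cascade_update_rule <- function(vx, vxp, same_coord = FALSE) {
  cpp_update_rule(as.integer(vx), as.integer(vxp), isTRUE(same_coord))
}

#' Byte-array coordinates of a seed
#'
#' The unordered coordinate pair is strand-symmetric:
#' `cascade_coords(counter, S)` and `cascade_coords(counter, revcomp(S))`
#' are each other's swaps.
#'
#' @inheritParams cascade_add
#' @param s2k a single seed sequence.
#' @return Named numeric vector `(x, xp)`.
#' @export
cascade_coords <- function(counter, s2k) {
  cpp_cascade_coords(counter$ptr, as_dna_string(s2k))
}

#' Cascade bookkeeping
#'
#' @param counter a [cascade_counter()].
#' @return A list with `m`, `m2`, `k`, `delta`, `n_inserted`.
#' @export
cascade_params <- function(counter) cpp_cascade_params(counter$ptr)

#' Serialize / restore a cascade counter
#'
#' Shares the [bloom_save()] header (magic "SSCC"), followed by the
#' stage-1 bit array and the stage-2 byte array.
#'
#' @param counter a [cascade_counter()].
#' @param path file path.
#' @export
cascade_save <- function(counter, path) {
  p <- cpp_cascade_params(counter$ptr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SSCC"), con)
  writeBin(c(1L, p$k, p$delta), con, size = 4L, endian = "little")
  writeBin(c(p$m, p$m2, p$n_inserted), con, size = 8L, endian = "little")
  writeBin(cpp_cascade_stage1_bits(counter$ptr), con)
  writeBin(cpp_cascade_bytes(counter$ptr), con)
  invisible(path)
}

#' @rdname cascade_save
#' @export
cascade_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "SSCC") stop("not a cascade_counter file")
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stop("unsupported version ", hdr[1])
  nums <- readBin(con, "double", 3L, size = 8L, endian = "little")
  bits <- readBin(con, "raw", ceiling(nums[1] / 8))
  bytes <- readBin(con, "raw", nums[2])
  structure(
    list(ptr = cpp_cascade_from_state(nums[1], nums[2], hdr[2], hdr[3],
                                      nums[3], bits, bytes),
         template = seed_template(hdr[2], hdr[3])),
    class = "cascade_counter"
  )
}
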