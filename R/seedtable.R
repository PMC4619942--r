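#' ABySS-style spaced-seed hash table
#'
#' A deterministic hash-table record per canonical spaced seed, carrying:
#' (1) the concatenated `[k:k]` sequence content of the first observation
#' (4k bits — constant in `delta`, because the gap is never stored);
#' (2) forward and reverse-complement observation counts, each saturating
#' at `2^15 - 1`; (3) presence bits for all four one-base extensions of
#' *either* seed in *either* direction (16 bits); (4) 16 bookkeeping flag
#' bits for error-removal algorithms.
#'
#' Implemented as an R environment keyed by the canonical seed — exact and
#' deterministic, the reference structure against which the probabilistic
#' filters are checked.
#'
#' @param template a [seed_template()].
#' @return A `seed_table` object (reference semantics).
#' @export
seed_table <- function(template) {
  stopifnot(inherits(template, "seed_template"))
  structure(list(env = new.env(parent = emptyenv(), hash = TRUE),
                 template = template),
            class = "seed_table")
}

#' @export
print.seed_table <- function(x, ...) {
  cat("<seed_table> ", length(ls(x$env)), " canonical seeds, k = ",
      x$template$k, ", delta = ", x$template$delta, "\n", sep = "")
  invisible(x)
}

#' @export
length.seed_table <- function(x) length(ls(x$env))

COUNT_CAP <- 32767L  # 15-bit saturating counters

new_record <- function(seq) {
  list(seq = seq, fwd = 0L, rev = 0L, ext = 0L, flags = 0L)
}

#' Insert or update a seed record
#'
#' Records are keyed by the canonical seed; the stored sequence is the
#' canonical form of the first observation. The strand-appropriate counter
#' (forward if the presented orientation is canonical, reverse-complement
#' otherwise) is incremented, saturating at `2^15 - 1`.
#'
#' @param table a [seed_table()] (mutated in place).
#' @param s2k a 2k-length seed sequence as observed.
#' @param n number of observations to add at once (default 1).
#' @return The updated record, invisibly.
#' @export
st_upsert <- function(table, s2k, n = 1L) {
  s2k <- as_dna_string(s2k)
  if (nchar(s2k) != 2L * table$template$k)
    stop("seed length must be 2k")
  key <- cpp_canonical_str(s2k)
  rec <- get0(key, envir = table$env, inherits = FALSE)
  if (is.null(rec)) rec <- new_record(key)
  if (s2k == key) {
    rec$fwd <- min(rec$fwd + as.integer(n), COUNT_CAP)
  } else {
    rec$rev <- min(rec$rev + as.integer(n), COUNT_CAP)
  }
  assign(key, rec, envir = table$env)
  invisible(rec)
}

#' Look up a seed record
#'
#' @inheritParams st_upsert
#' @return The record (a list with `seq`, `fwd`, `rev`, `ext`, `flags`) or
#'   `NULL` if absent. Lookup is strand-insensitive.
#' @export
st_get <- function(table, s2k) {
  get0(cpp_canonical_str(as_dna_string(s2k)), envir = table$env,
       inherits = FALSE)
}

# extension bit index, 0..15: seed (1|2) x direction (5p|3p) x base
ext_bit <- function(seed_index, direction, base) {
  code <- match(toupper(base), c("A", "C", "G", "T"))
  if (is.na(code)) stop("extension base must be one of A, C, G, T")
  d <- match(direction, c("5p", "3p"))
  if (is.na(d)) stop("direction must be '5p' or '3p'")
  (seed_index - 1L) * 8L + (d - 1L) * 4L + (code - 1L)
}

#' Record a one-base extension
#'
#' Sets the presence bit for an observed extension of seed 1 or seed 2, on
#' its 5' or 3' side, by one of the four bases. Idempotent. The
#' (`seed_index`, `direction`, `base`) triple refers to the *presented*
#' orientation; when the stored canonical orientation is the reverse
#' complement, the bit is mapped accordingly (seeds swap, directions flip,
#' the base is complemented).
#'
#' @inheritParams st_upsert
#' @param seed_index 1 (left seed) or 2 (right seed).
#' @param direction `"5p"` or `"3p"`.
#' @param base one of `A, C, G, T`.
#' @return The updated record, invisibly.
#' @export
st_set_extension <- function(table, s2k, seed_index, direction, base) {
  s2k <- as_dna_string(s2k)
  stopifnot(seed_index %in% c(1L, 2L))
  key <- cpp_canonical_str(s2k)
  rec <- get0(key, envir = table$env, inherits = FALSE)
  if (is.null(rec)) rec <- new_record(key)
  if (s2k != key) {  # map to the stored orientation
    seed_index <- 3L - seed_index
    direction <- if (direction == "5p") "3p" else "5p"
    base <- chartr("ACGTacgt", "TGCATGCA", base)
  }
  rec$ext <- bitwOr(rec$ext, bitwShiftL(1L, ext_bit(as.integer(seed_index),
                                                    direction, base)))
  assign(key, rec, envir = table$env)
  invisible(rec)
}

#' Populate a table from a read
#'
#' Upserts every seed window of the read and sets the extension bits that
#' the read context implies (the base preceding/following each of the two
#' seeds, where the read provides one).
#'
#' @param table a [seed_table()].
#' @param read a DNA string.
#' @param quiet unused, reserved.
#' @return The table, invisibly.
#' @export
st_add_read <- function(table, read, quiet = TRUE) {
  tpl <- table$template
  read <- toupper(read)
  w <- extract_seeds(read, tpl)
  if (nrow(w) == 0L) return(invisible(table))
  chars <- strsplit(read, "", fixed = TRUE)[[1]]
  k <- tpl$k; delta <- tpl$delta; span <- tpl$span
  for (i in seq_len(nrow(w))) {
    o <- w$origin[i]  # 0-based
    s <- w$s2k[i]
    st_upsert(table, s)
    # seed 1 occupies read positions o+1 .. o+k (1-based); seed 2
    # occupies o+k+delta+1 .. o+span
    ctx <- list(
      list(1L, "5p", o), list(1L, "3p", o + k + 1L),
      list(2L, "5p", o + k + delta), list(2L, "3p", o + span + 1L)
    )
    for (cx in ctx) {
      p <- cx[[3]]
      if (p >= 1L && p <= length(chars) && chars[p] %in% c("A", "C", "G", "T"))
        st_set_extension(table, s, cx[[1]], cx[[2]], chars[p])
    }
  }
  invisible(table)
}

#' Dump table contents
#'
#' @param table a [seed_table()].
#' @return A data.frame with one row per canonical seed: `seed`, `fwd_count`,
#'   `rev_count`, `ext_mask` (hex), `flags` (hex), sorted by seed.
#' @export
st_dump <- function(table) {
  keys <- sort(ls(table$env))
  recs <- lapply(keys, get, envir = table$env)
  data.frame(
    seed = keys,
    fwd_count = vapply(recs, `[[`, integer(1), "fwd"),
    rev_count = vapply(recs, `[[`, integer(1), "rev"),
    ext_mask = sprintf("%04x", vapply(recs, `[[`, integer(1), "ext")),
    flags = sprintf("%04x", vapply(recs, `[[`, integer(1), "flags")),
    stringsAsFactors = FALSE
  )
}

#' Record memory accounting
#'
#' A full record costs `4k` bits of sequence content + 32 bits of strand
#' counters + 16 extension bits + 16 flag bits, independent of `delta`.
#' Storing the full `(2k + delta)`-base sequence content instead would cost
#' `2(2k + delta)` bits; since counters and flags are identical in both
#' layouts, the spaced-seed layout (content 4k + 16 extension bits, versus
#' content `4k + 2 delta`) is strictly smaller exactly when `delta > 8`,
#' and ties at `delta = 8`.
#'
#' @param k seed length.
#' @param delta gap length.
#' @return `bits_per_record`: total record size in bits.
#' @export
bits_per_record <- function(k, delta) {
  stopifnot(k >= 1)
  4 * k + 32 + 16 + 16
}

#' @rdname bits_per_record
#' @return `seed_memory_costs`: a list with the two content+extension costs
#'   (`spaced`, `full`) in bits.
#' @export
seed_memory_costs <- function(k, delta) {
  list(spaced = 4 * k + 16, full = 2 * (2 * k + delta))
}

#' @rdname bits_per_record
#' @return `savings_threshold`: the smallest bound on `delta` above which
#'   the spaced-seed layout is strictly smaller (8, for every `k`).
#' @export
savings_threshold <- function(k) {
  stopifnot(k >= 1)
  # solve 2(2k + delta) > 4k + 16  <=>  delta > 8, independent of k
  delta <- 0
  while (seed_memory_costs(k, delta + 1)$full <=
         seed_memory_costs(k, delta + 1)$spaced) {
    delta <- delta + 1
  }
  delta
}
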