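#' Classify a four-hash hit pattern
#'
#' A single base error in a queried seed is confined to the left *or* right
#' k-mer and to the odd *or* even positions, so if the error-free seed is
#' in the filter exactly two of the four hash values still hit, in one of
#' the four patterns `{L|R} x {O|E}`. Classification:
#' \itemize{
#'   \item `(1,1,1,1)` — `present`;
#'   \item exactly two hits forming `{L|R} x {O|E}` — `single-correctable`;
#'   \item exactly one hit — `double-flagged` (there may be a two-base
#'     correction; no default action);
#'   \item everything else (0 hits, >= 3 hits, or the non-localising pairs
#'     `L+R` and `O+E`) — `absent`.
#' }
#'
#' @param hits logical vector of length 4 (order `xL, xR, xO, xE`) or a
#'   logical matrix with those columns.
#' @return Character vector of classes.
#' @export
classify_pattern <- function(hits) {
  if (is.matrix(hits)) return(apply(hits, 1L, classify_pattern))
  stopifnot(length(hits) == 4L)
  nh <- sum(hits)
  if (nh == 4L) return("present")
  if (nh == 1L) return("double-flagged")
  if (nh == 2L && xor(hits[1], hits[2]) && xor(hits[3], hits[4]))
    return("single-correctable")
  "absent"
}

#' Candidate error positions for a single-correctable pattern
#'
#' The error must lie in the *missed* half and at the *missed* parity, so
#' the candidates are their intersection: e.g. pattern `(1,0,1,0)` (left
#' and odd hit) confines the error to the even positions of the right
#' k-mer. Candidates always lie inside the stored 2k seed bases, never in
#' the gap.
#'
#' @inheritParams classify_pattern
#' @param k the seed length.
#' @return Integer vector of candidate positions, 1-based within the
#'   2k-length seed.
#' @export
locate_candidates <- function(hits, k) {
  if (classify_pattern(hits) != "single-correctable")
    stop("pattern is not single-correctable")
  half <- if (hits[1]) (k + 1L):(2L * k) else 1L:k   # missed half
  parity <- if (hits[3]) 0L else 1L                  # missed parity (odd = 1)
  half[half %% 2L == parity]
}

BASES <- c("A", "C", "G", "T")

substitute_base <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

#' Attempt a single-base correction of one seed
#'
#' Applies the error-correction rules to a single seed against a filter
#' (and optionally a cascade counter):
#' \itemize{
#'   \item pattern `present`: update the counter (when given), no change;
#'   \item pattern `absent` or `double-flagged`: insert the seed;
#'   \item pattern `single-correctable`: try all candidate positions times
#'     three alternative bases; keep substitutions whose pattern becomes
#'     `(1,1,1,1)` and (when a counter is given) whose count is nonzero.
#'     The correction is applied only if exactly *one* substitution
#'     survives — an ambiguous fix is treated as absent and inserted
#'     (precision over recall).
#' }
#'
#' @param s2k the seed as observed (2k-length string).
#' @param filter a [seed_bloom()] (mutated when an insert occurs).
#' @param counter optional [cascade_counter()] used both to update counts
#'   of present seeds and to validate candidate corrections.
#' @param insert_missing insert absent seeds into the filter (default TRUE,
#'   the streaming build-and-correct behaviour).
#' @return A list: `status` (`present`, `corrected`, `inserted`,
#'   `ambiguous`, `no-change`), and for corrections `pos` (1-based in s2k),
#'   `from`, `to`, `s2k` (the corrected seed).
#' @export
try_correct <- function(s2k, filter, counter = NULL, insert_missing = TRUE) {
  hits <- bloom_query(filter, s2k)[1L, ]
  class <- classify_pattern(hits)
  if (class == "present") {
    if (!is.null(counter)) cascade_add(counter, s2k)
    return(list(status = "present", s2k = s2k))
  }
  if (class == "single-correctable") {
    k <- filter$template$k
    cand <- locate_candidates(hits, k)
    trials <- expand.grid(pos = cand, base = BASES, stringsAsFactors = FALSE)
    trials <- trials[substring(s2k, trials$pos, trials$pos) != trials$base, ]
    fixed <- mapply(function(p, b) substitute_base(s2k, p, b),
                    trials$pos, trials$base)
    ok <- bloom_contains(filter, fixed)
    if (!is.null(counter) && any(ok)) {
      cnt <- cascade_count(counter, fixed[ok])
      ok[ok] <- !is.na(cnt$estimate) & cnt$estimate > 0
    }
    if (sum(ok) == 1L) {
      i <- which(ok)
      return(list(status = "corrected", pos = trials$pos[i],
                  from = substring(s2k, trials$pos[i], trials$pos[i]),
                  to = trials$base[i], s2k = fixed[i]))
    }
    if (sum(ok) > 1L) class <- "ambiguous"
  }
  if (insert_missing) {
    bloom_insert(filter, s2k)
    if (!is.null(counter)) cascade_add(counter, s2k)
    return(list(status = if (class == "ambiguous") "ambiguous" else "inserted",
                s2k = s2k))
  }
  list(status = if (class == "ambiguous") "ambiguous" else "no-change",
       s2k = s2k)
}

# map a 1-based position within s2k to a 1-based read position
s2k_pos_to_read <- function(pos, origin, k, delta) {
  ifelse(pos <= k, origin + pos, origin + delta + pos)
}

#' Correct a read against a spaced-seed filter
#'
#' Slides the template over the read left to right. Windows found present
#' update the counter (when given); single-correctable windows propose a
#' substitution via [try_correct()], which is committed to the read only if
#' it is unique and (when qualities are given) the base's quality is below
#' `quality_threshold`. Committed changes take effect immediately, so
#' subsequent windows are evaluated against the corrected read. Errors in
#' a window's gap do not disturb that window at all — the gap is never
#' stored.
#'
#' @param read a DNA string.
#' @param template a [seed_template()].
#' @param filter a [seed_bloom()] built from the data (mutated: absent
#'   windows are inserted unless `insert_missing = FALSE`).
#' @param counter optional [cascade_counter()].
#' @param quality optional integer vector of per-base Phred qualities (same
#'   length as the read); gating is applied only when provided.
#' @param quality_threshold corrections are committed only at bases with
#'   quality strictly below this (default 20, i.e. Q20).
#' @param insert_missing see [try_correct()].
#' @return A list with `read` (corrected sequence) and `changes`, a
#'   data.frame of committed substitutions: `pos` (0-based read position),
#'   `from`, `to`, `window` (0-based origin of the deciding window).
#' @export
correct_read <- function(read, template, filter, counter = NULL,
                         quality = NULL, quality_threshold = 20,
                         insert_missing = TRUE) {
  read <- toupper(read)
  k <- template$k; delta <- template$delta; span <- template$span
  changes <- list()
  if (nchar(read) < span)
    return(list(read = read,
                changes = data.frame(pos = integer(), from = character(),
                                     to = character(), window = integer())))
  # fast path: classify all windows at once, then revisit the imperfect ones
  scan <- bloom_query_read(filter, read)
  pending <- scan$origin[rowSums(scan$hits) < 4L]
  if (!is.null(counter)) {
    for (o in scan$origin[rowSums(scan$hits) == 4L])
      cascade_add(counter, substr_seed(read, o, k, delta))
  }
  for (o in sort(pending)) {
    s2k <- substr_seed(read, o, k, delta)
    if (is.na(s2k)) next
    res <- try_correct(s2k, filter, counter, insert_missing)
    if (res$status == "corrected") {
      rpos <- s2k_pos_to_read(res$pos, o, k, delta)
      if (!is.null(quality) && quality[rpos] >= quality_threshold) next
      substr(read, rpos, rpos) <- res$to
      changes[[length(changes) + 1L]] <-
        data.frame(pos = rpos - 1L, from = res$from, to = res$to, window = o)
    }
  }
  list(read = read,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(pos = integer(), from = character(),
                                 to = character(), window = integer()))
}

# seed content of the window at 0-based origin o, NA if any seed base is
# ambiguous
substr_seed <- function(read, o, k, delta) {
  left <- substr(read, o + 1L, o + k)
  right <- substr(read, o + k + delta + 1L, o + 2L * k + delta)
  s <- paste0(left, right)
  if (grepl("[^ACGT]", s)) NA_character_ else s
}

#' Correct a set of reads
#'
#' Applies [correct_read()] to each read of a FASTQ-style data.frame
#' (columns `id`, `seq`, optionally `qual`) and returns the corrected
#' reads plus a combined change log.
#'
#' @param reads a data.frame as returned by [read_fastq()] or
#'   [sim_reads()].
#' @inheritParams correct_read
#' @return A list with `reads` (same data.frame, `seq` corrected) and
#'   `changes` (read id, 0-based position, from, to, window origin).
#' @export
correct_reads <- function(reads, template, filter, counter = NULL,
                          quality_threshold = 20, insert_missing = TRUE) {
  logs <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    qual <- if ("qual" %in% names(reads) && !is.na(reads$qual[i]))
      utf8ToInt(reads$qual[i]) - 33L else NULL
    res <- correct_read(reads$seq[i], template, filter, counter,
                        quality = qual,
                        quality_threshold = quality_threshold,
                        insert_missing = insert_missing)
    reads$seq[i] <- res$read
    if (nrow(res$changes))
      logs[[i]] <- cbind(id = reads$id[i], res$changes)
  }
  changes <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  if (is.null(changes))
    changes <- data.frame(id = character(), pos = integer(),
                          from = character(), to = character(),
                          window = integer())
  list(reads = reads, changes = changes)
}
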