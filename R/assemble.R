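#' Build the spaced-seed graph structure from reads
#'
#' Inserts every seed window of every read into a [seed_bloom()] and
#' captures auxiliary seeds along the way:
#' \itemize{
#'   \item *blunt* candidates — the first and last window of each read
#'     (initially every read contributes two blunt edges; most are pruned
#'     later by [garbage_collect()]);
#'   \item *branch* representatives — when a read moves between
#'     already-observed and new territory, the boundary window is probed
#'     for multiple observed 1-base extensions; if it has two or more it is
#'     a junction, caught by the second sequence to cross it.
#' }
#'
#' @param reads character vector of read sequences, or a data.frame with a
#'   `seq` column.
#' @param template a [seed_template()].
#' @param m filter size in bits; default sized via [bloom_size_for()] for
#'   the *distinct* canonical seed count at `target_fpr`.
#' @param target_fpr four-hash sizing target for the default `m` (default
#'   `1e-14`, i.e. a per-bit load near `3e-4`). The target is deliberately
#'   aggressive: a 1-base extension probe shares its left k-mer and its
#'   odd positions with a true seed, so only two of the four hash values
#'   discriminate it and the per-probe false-extension rate scales as the
#'   *square* of the per-bit load, not its fourth power.
#' @return A list with `filter` (the populated [seed_bloom()]) and `aux`
#'   (data.frame: `seq` — the full span-length window, `type` — `blunt` or
#'   `branch`, `side` — the direction of bluntness / branching).
#' @export
build_graph <- function(reads, template, m = NULL, target_fpr = 1e-14) {
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- toupper(reads)
  span <- template$span
  if (is.null(m)) {
    n_distinct <- length(unique(unlist(lapply(
      reads, function(r) cpp_canonical_seeds(r, template$k,
                                             template$delta)$seed))))
    m <- bloom_size_for(max(n_distinct, 1), 4, target_fpr)
  }
  bf <- seed_bloom(m, template)
  aux <- list()
  for (r in reads) {
    ins <- bloom_insert_read(bf, r)
    n <- length(ins$origin)
    if (n == 0L) next
    allhit <- rowSums(ins$pre) == 4L
    win <- function(i) substr(r, ins$origin[i] + 1L, ins$origin[i] + span)
    aux[[length(aux) + 1L]] <-
      data.frame(seq = c(win(1L), win(n)), type = "blunt",
                 side = c("left", "right"))
    if (n > 1L) {
      contig_pair <- ins$origin[-1L] == ins$origin[-n] + 1L
      # known -> new: the known window may have gained a second right
      # extension; new -> known: the known window a second left extension
      for (i in which(allhit[-n] & !allhit[-1L] & contig_pair)) {
        if (sum(bloom_next_bases(bf, substr(r, ins$origin[i] + 2L,
                                            ins$origin[i] + span))) >= 2L)
          aux[[length(aux) + 1L]] <-
            data.frame(seq = win(i), type = "branch", side = "right")
      }
      for (i in which(!allhit[-n] & allhit[-1L] & contig_pair)) {
        w <- win(i + 1L)
        if (sum(bloom_next_bases(bf, substr(cpp_revcomp_str(w), 2L, span))) >= 2L)
          aux[[length(aux) + 1L]] <-
            data.frame(seq = w, type = "branch", side = "left")
      }
    }
  }
  aux <- if (length(aux)) unique(do.call(rbind, aux))
         else data.frame(seq = character(), type = character(),
                         side = character())
  rownames(aux) <- NULL
  list(filter = bf, aux = aux)
}

has_extension <- function(bf, window, side) {
  span <- bf$template$span
  tail <- if (side == "right") substr(window, 2L, span)
          else substr(cpp_revcomp_str(window), 2L, span)
  any(bloom_next_bases(bf, tail))
}

#' Prune the auxiliary blunt-edge list
#'
#' Re-interrogates each blunt entry against the (now fully populated)
#' filter and removes those that have acquired an extension on their
#' recorded side — the periodic garbage collection of the transitory
#' blunt-edge list. On a fully tiled linear target exactly the two true
#' sequence ends survive (none for a circular target). Branch entries are
#' kept untouched. Idempotent when no reads were added since capture.
#'
#' @param aux the `aux` data.frame from [build_graph()].
#' @param filter the populated [seed_bloom()].
#' @return The pruned data.frame.
#' @export
garbage_collect <- function(aux, filter) {
  if (nrow(aux) == 0L) return(aux)
  keep <- vapply(seq_len(nrow(aux)), function(i) {
    if (aux$type[i] != "blunt") return(TRUE)
    !has_extension(filter, aux$seq[i], aux$side[i])
  }, logical(1))
  out <- aux[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# extend to the right; contig given as a character vector of bases
extend_right <- function(chars, bf, visited, max_length, two_scale) {
  span <- bf$template$span
  k <- bf$template$k
  n_added <- 0L
  repeat {
    if (length(chars) >= max_length)
      return(list(chars = chars, term = "length-limit", n = n_added))
    tail <- paste(chars[(length(chars) - span + 2L):length(chars)],
                  collapse = "")
    hits <- bloom_next_bases(bf, tail)
    nh <- sum(hits)
    if (nh == 0L && two_scale) {
      # low-coverage fallback at scale k: probe the lone trailing k-mer
      ktail <- substr(tail, span - k + 1L, span - 1L)
      hits <- vapply(BASES, function(b)
        bloom_kmer_contains(bf, paste0(ktail, b)), logical(1))
      nh <- sum(hits)
    }
    if (nh == 0L) return(list(chars = chars, term = "blunt-end", n = n_added))
    if (nh >= 2L) return(list(chars = chars, term = "branch", n = n_added))
    b <- BASES[which(hits)]
    key <- cpp_canonical_str(paste0(tail, b))
    if (!is.null(visited[[key]]))
      return(list(chars = chars, term = "circular", n = n_added))
    visited[[key]] <- TRUE
    chars <- c(chars, b)
    n_added <- n_added + 1L
  }
}

#' Extend a contig from a starting seed window
#'
#' Grows a contig in both directions from a full span-length window (an
#' auxiliary blunt/branch seed, whose gap bases come from its read of
#' origin). Each rightward step probes the four 1-base extensions of the
#' current tail for full spaced-seed membership: the leading wave front
#' advances one base, while the lagging k-mer — drawn from sequence
#' assembled span bases earlier — must simultaneously agree, which is what
#' eliminates false branches after the transient gap-length phase.
#' Extension stops at a blunt end (no candidate), an unresolvable branch
#' (two or more candidates), or when a window repeats (circular).
#'
#' @param start a span-length DNA string present in the structure.
#' @param filter the populated [seed_bloom()].
#' @param max_length safety cap on contig length (default 1e6).
#' @param two_scale enable the scale-k fallback at zero-candidate steps
#'   (single-hash membership, elevated FPR; off by default).
#' @return A list: `seq`, `length`, `terminated_by` (`blunt-end`, `branch`
#'   or `circular`), `n_extended` (bases added beyond the start window),
#'   and the per-direction terminations `term_right`, `term_left`.
#' @export
extend_contig <- function(start, filter, max_length = 1e6,
                          two_scale = FALSE) {
  span <- filter$template$span
  start <- toupper(start)
  if (nchar(start) != span) stop("start must be a span-length window")
  if (!bloom_contains(filter, substr_seed(start, 0L, filter$template$k,
                                          filter$template$delta)))
    stop("start window is not present in the filter")
  visited <- new.env(parent = emptyenv())
  visited[[cpp_canonical_str(start)]] <- TRUE
  chars <- strsplit(start, "", fixed = TRUE)[[1]]
  right <- extend_right(chars, filter, visited, max_length, two_scale)
  if (right$term == "circular") {
    left <- list(chars = strsplit(cpp_revcomp_str(
      paste(right$chars, collapse = "")), "", fixed = TRUE)[[1]],
      term = "circular", n = 0L)
  } else {
    left <- extend_right(
      strsplit(cpp_revcomp_str(paste(right$chars, collapse = "")), "",
               fixed = TRUE)[[1]],
      filter, visited, max_length, two_scale)
  }
  seq <- cpp_revcomp_str(paste(left$chars, collapse = ""))
  term <- if ("circular" %in% c(right$term, left$term)) "circular"
          else if ("branch" %in% c(right$term, left$term)) "branch"
          else "blunt-end"
  list(seq = seq, length = nchar(seq), terminated_by = term,
       n_extended = right$n + left$n,
       term_right = right$term, term_left = left$term)
}

#' Trim short dead-end branches
#'
#' Removes contigs that look like false-positive spurs: started from a
#' *branch* seed, ended blunt, and extended fewer than `min_len` bases
#' beyond their starting window (default `2k - 1`, the conventional branch
#' trimming length). A false branch survives `l` membership probes with
#' probability `f^l`, so at `f = 6.25%` even 3e9 Bonferroni-corrected
#' tests leave a false branch of length 10 below 0.3% probability — see
#' [false_branch_prob()].
#'
#' @param contigs a data.frame of contigs (from [assemble_reads()]) with
#'   columns `start_type`, `terminated_by`, `n_extended`.
#' @param template a [seed_template()].
#' @param min_len trimming threshold override (default `2k - 1`).
#' @return The pruned data.frame.
#' @export
trim_branches <- function(contigs, template, min_len = NULL) {
  if (is.null(min_len)) min_len <- 2L * template$k - 1L
  if (nrow(contigs) == 0L) return(contigs)
  spur <- contigs$start_type == "branch" &
    contigs$terminated_by == "blunt-end" &
    contigs$n_extended < min_len
  out <- contigs[!spur, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' False-branch survival probability
#'
#' The probability that a chain of Bloom false positives sustains a false
#' branch of length `len` is `f^len`; `n_tests` applies a Bonferroni
#' factor for the number of extension hypotheses tested.
#'
#' @param f false positive rate per membership probe.
#' @param len branch length in bases.
#' @param n_tests Bonferroni correction factor (default 1).
#' @return Upper bound on the corrected probability.
#' @export
false_branch_prob <- function(f, len, n_tests = 1) {
  pmin(1, f^len * n_tests)
}

#' Assemble reads into contigs
#'
#' The toy end-to-end pipeline: [build_graph()], [garbage_collect()],
#' [extend_contig()] from every surviving auxiliary seed (in sorted order,
#' for reproducibility), [trim_branches()], then deduplication of
#' reverse-complement-equivalent and contained contigs.
#'
#' @inheritParams build_graph
#' @param trim_len branch trimming override (default `2k - 1`).
#' @param two_scale enable the scale-k fallback (off by default).
#' @param max_length safety cap per contig.
#' @return A data.frame of contigs: `id`, `seq`, `length`,
#'   `terminated_by`, `start_type`, `n_extended`; zero rows for empty
#'   input.
#' @export
assemble_reads <- function(reads, template, m = NULL, target_fpr = 1e-14,
                           trim_len = NULL, two_scale = FALSE,
                           max_length = 1e6) {
  empty <- data.frame(id = character(), seq = character(),
                      length = integer(), terminated_by = character(),
                      start_type = character(), n_extended = integer())
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 0L) return(empty)
  g <- build_graph(reads, template, m = m, target_fpr = target_fpr)
  aux <- garbage_collect(g$aux, g$filter)
  if (nrow(aux) == 0L) return(empty)
  aux <- aux[order(aux$seq, aux$type), , drop = FALSE]
  contigs <- list()
  for (i in seq_len(nrow(aux))) {
    ct <- extend_contig(aux$seq[i], g$filter, max_length = max_length,
                        two_scale = two_scale)
    contigs[[i]] <- data.frame(seq = ct$seq, length = ct$length,
                               terminated_by = ct$terminated_by,
                               start_type = aux$type[i],
                               n_extended = ct$n_extended)
  }
  contigs <- do.call(rbind, contigs)
  contigs <- trim_branches(contigs, template, min_len = trim_len)
  if (nrow(contigs) == 0L) return(empty)
  # collapse strand duplicates, keep the canonical representative
  contigs$canon <- vapply(contigs$seq, cpp_canonical_str, character(1),
                          USE.NAMES = FALSE)
  contigs <- contigs[!duplicated(contigs$canon), , drop = FALSE]
  # drop contigs contained in a longer contig (either strand)
  ord <- order(-contigs$length)
  contigs <- contigs[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && (grepl(contigs$seq[i], contigs$seq[j], fixed = TRUE) ||
                      grepl(cpp_revcomp_str(contigs$seq[i]), contigs$seq[j],
                            fixed = TRUE))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  contigs <- contigs[keep, , drop = FALSE]
  contigs$canon <- NULL
  contigs <- cbind(id = sprintf("contig%03d", seq_len(nrow(contigs))),
                   contigs)
  rownames(contigs) <- NULL
  contigs
}

#' Write contigs as FASTA
#'
#' Headers carry `id`, `length` and `terminated_by` as space-separated
#' fields.
#'
#' @param contigs output of [assemble_reads()].
#' @param path output path.
#' @export
write_contigs <- function(contigs, path) {
  ids <- sprintf("%s length=%d terminated_by=%s", contigs$id,
                 contigs$length, contigs$terminated_by)
  write_fasta(setNames(contigs$seq, ids), path)
}
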