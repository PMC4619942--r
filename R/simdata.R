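#' Simulate a genome with planted repeat families
#'
#' Generates an i.i.d. uniform random genome (GC fraction 0.5) and plants
#' repeat families into it: each family consists of `count` copies of one
#' random `length`-base unit, placed at non-overlapping positions and
#' independently mutated at the per-base `divergence` rate. All randomness
#' flows through the R RNG; a fixed `seed` gives byte-identical output.
#'
#' @param genome_length total genome length in bases.
#' @param repeat_spec optional data.frame with columns `count`, `length`,
#'   `divergence` (one row per family), or `NULL` for a repeat-free genome.
#' @param seed optional RNG seed applied via `set.seed()`.
#' @return A character string of length `genome_length`, with attribute
#'   `repeats`: a data.frame of planted copies (`family`, `start` 0-based,
#'   `length`).
#' @export
sim_genome <- function(genome_length, repeat_spec = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- sample(BASES, genome_length, replace = TRUE)
  planted <- data.frame(family = integer(), start = integer(),
                        length = integer())
  if (!is.null(repeat_spec) && nrow(repeat_spec) > 0) {
    if (sum(repeat_spec$count * repeat_spec$length) > genome_length)
      stop("repeat copies do not fit in the genome")
    taken <- rep(FALSE, genome_length)
    for (f in seq_len(nrow(repeat_spec))) {
      unit <- sample(BASES, repeat_spec$length[f], replace = TRUE)
      len <- repeat_spec$length[f]
      for (cp in seq_len(repeat_spec$count[f])) {
        # rejection-sample a non-overlapping placement
        for (try in 1:1000) {
          s <- sample.int(genome_length - len + 1L, 1L)
          if (!any(taken[s:(s + len - 1L)])) break
          if (try == 1000) stop("could not place repeat copy without overlap")
        }
        copy <- unit
        mut <- runif(len) < repeat_spec$divergence[f]
        if (any(mut))
          copy[mut] <- vapply(copy[mut], function(b)
            sample(setdiff(BASES, b), 1L), character(1))
        g[s:(s + len - 1L)] <- copy
        taken[s:(s + len - 1L)] <- TRUE
        planted <- rbind(planted,
                         data.frame(family = f, start = s - 1L, length = len))
      }
    }
  }
  structure(paste(g, collapse = ""), repeats = planted)
}

#' Simulate reads with substitution errors
#'
#' Uniform start positions, random strand, i.i.d. substitutions at
#' `error_rate` per base. The error model is substitution-only (no indels),
#' matching the correction logic, and the quality string is constant at the
#' Phred encoding of the configured error rate.
#'
#' @param genome a DNA string (e.g. from [sim_genome()]).
#' @param read_length read length in bases.
#' @param coverage fold coverage; the number of reads is
#'   `round(coverage * genome_length / read_length)`.
#' @param error_rate per-base substitution probability.
#' @param seed optional RNG seed.
#' @return A data.frame with `id`, `seq`, `qual`, plus the truth columns
#'   `start` (0-based on the forward strand), `strand` (`+`/`-`) and
#'   `errors` (comma-separated 0-based read positions of planted errors).
#' @export
sim_reads <- function(genome, read_length, coverage, error_rate = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- nchar(genome)
  if (read_length > G) stop("read_length exceeds genome length")
  n_reads <- round(coverage * G / read_length)
  starts <- sample.int(G - read_length + 1L, n_reads, replace = TRUE)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  q <- if (error_rate > 0) min(41L, round(-10 * log10(error_rate))) else 41L
  qual <- strrep(intToUtf8(q + 33L), read_length)
  seqs <- character(n_reads)
  errs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- substr(genome, starts[i], starts[i] + read_length - 1L)
    if (strands[i] == "-") s <- cpp_revcomp_str(s)
    if (error_rate > 0) {
      pos <- which(runif(read_length) < error_rate)
      if (length(pos)) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(BASES, b), 1L), character(1))
        s <- paste(ch, collapse = "")
      }
      errs[i] <- paste(pos - 1L, collapse = ",")
    }
    seqs[i] <- s
  }
  data.frame(id = sprintf("read%06d", seq_len(n_reads)), seq = seqs,
             qual = qual, start = starts - 1L, strand = strands,
             errors = errs, stringsAsFactors = FALSE)
}

#' Count fixture over logarithmic bins
#'
#' Defines the replication layout for minifloat concordance experiments:
#' each logarithmic bin's true count is replicated `reps` times (default
#' 10,000 replicates per bin). Feed the rows to [mf_count_stream()].
#'
#' @param bins integer vector of true counts (default powers of two up to
#'   8192 plus 10,000).
#' @param reps replicates per bin (default 10,000).
#' @return A data.frame with `true_count` and `reps`.
#' @export
sim_counts <- function(bins = c(2^(0:13), 10000), reps = 10000) {
  if (reps == 0 || length(bins) == 0)
    return(data.frame(true_count = numeric(), reps = integer()))
  data.frame(true_count = as.numeric(bins), reps = as.integer(reps))
}
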