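# Independent oracles, deliberately implemented without the package's
# compiled code paths.

ORACLE_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(ORACLE_BASES, n, replace = TRUE),
                              collapse = "")

# pure-R reverse complement
r_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

r_canonical <- function(s) {
  rc <- r_revcomp(s)
  if (rc < s) rc else s
}

# brute-force census of canonical spaced seeds at every position (pure R)
brute_canonical_seeds <- function(genome, k, delta) {
  span <- 2 * k + delta
  n <- nchar(genome) - span + 1
  if (n < 1) return(character())
  vapply(seq_len(n), function(o) {
    r_canonical(paste0(substr(genome, o, o + k - 1),
                       substr(genome, o + k + delta, o + span - 1)))
  }, character(1))
}

brute_uniqueness <- function(genome, k, delta) {
  seeds <- brute_canonical_seeds(genome, k, delta)
  counts <- table(seeds)
  sum(counts[seeds] == 1) / length(seeds)
}

# brute-force 1.4.3.-2 decode table straight from the defining formulas
brute_mf_table <- function() {
  do.call(rbind, lapply(0:255, function(b) {
    s <- b %/% 128L
    e <- (b %/% 8L) %% 16L
    t <- b %% 8L
    value <- if (e == 0) t
             else if (e == 15) NA_real_
             else (1 + t / 8) * 2^(e + 2)
    data.frame(pattern = b, sign = s, exponent = e, mantissa = t,
               value = value, collision = (b == 128), finite = (e != 15))
  }))
}

# plain contiguous n-mer de Bruijn assembler over an exact k-mer set:
# the comparison oracle for the repeat-resolution property
plain_dbg_contigs <- function(reads, n) {
  env <- new.env(parent = emptyenv())
  for (r in reads) {
    L <- nchar(r)
    if (L < n) next
    for (o in seq_len(L - n + 1))
      assign(r_canonical(substr(r, o, o + n - 1)), TRUE, envir = env)
  }
  has <- function(s) !is.null(get0(r_canonical(s), envir = env,
                                   inherits = FALSE))
  exts <- function(tail) ORACLE_BASES[vapply(ORACLE_BASES, function(b)
    has(paste0(tail, b)), logical(1))]
  contigs <- character()
  for (km in ls(env)) {
    for (s in unique(c(km, r_revcomp(km)))) {
      # start only at k-mers with no left extension (blunt on the left)
      if (length(exts(substr(r_revcomp(s), 2, n))) > 0) next
      ctg <- s
      repeat {
        e <- exts(substr(ctg, nchar(ctg) - n + 2, nchar(ctg)))
        if (length(e) != 1) break
        ctg <- paste0(ctg, e)
        if (nchar(ctg) > 1e6) break
      }
      contigs <- c(contigs, ctg)
    }
  }
  unique(vapply(contigs, r_canonical, character(1), USE.NAMES = FALSE))
}

# does `sub` occur exactly in `full` on either strand?
is_exact_substring <- function(sub, full) {
  grepl(sub, full, fixed = TRUE) || grepl(r_revcomp(sub), full, fixed = TRUE)
}
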