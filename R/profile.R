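#' Spaced-seed uniqueness of a genome
#'
#' The fraction of genomic seed positions whose canonical spaced seed
#' occurs exactly once genome-wide (an exact census over a sorted canonical
#' seed multiset; the genome is treated as linear and both strands are
#' collapsed through the canonical form). Uniqueness is the
#' assembly-relevant quantity: a unique seed admits unambiguous extension.
#' At `delta = 0` it reduces to the uniqueness of canonical 2k-mers.
#'
#' @param genome a DNA string of length at least `2k + delta`.
#' @param k seed length.
#' @param delta gap length.
#' @return One-row data.frame: `k`, `delta`, `n_positions`, `n_unique`,
#'   `uniqueness`.
#' @export
seed_uniqueness <- function(genome, k, delta) {
  if (nchar(genome) < 2 * k + delta)
    stop("genome shorter than the seed span 2k + delta")
  census <- cpp_canonical_seeds(toupper(genome), as.integer(k),
                                as.integer(delta))
  counts <- table(census$seed)
  n_pos <- length(census$seed)
  n_unique <- sum(counts[census$seed] == 1L)
  data.frame(k = k, delta = delta, n_positions = n_pos,
             n_unique = n_unique,
             uniqueness = if (n_pos > 0) n_unique / n_pos else NA_real_)
}

#' Uniqueness-versus-gap curves
#'
#' Computes [seed_uniqueness()] over a grid of seed lengths and gap
#' lengths. On repetitive genomes uniqueness typically increases with the
#' gap: a wider template spans more of each repeat copy's flanking
#' context. Grid points whose span exceeds the genome are skipped.
#'
#' @param genome a DNA string.
#' @param k seed lengths (default `c(8, 16, 32)`).
#' @param delta gap grid (default `seq(0, 400, by = 25)`).
#' @return A data.frame with one row per (k, delta), columns as in
#'   [seed_uniqueness()]; empty for an empty grid.
#' @export
uniqueness_curve <- function(genome, k = c(8, 16, 32),
                             delta = seq(0, 400, by = 25)) {
  grid <- expand.grid(k = k, delta = delta)
  grid <- grid[2 * grid$k + grid$delta <= nchar(genome), ]
  if (nrow(grid) == 0)
    return(data.frame(k = numeric(), delta = numeric(),
                      n_positions = integer(), n_unique = integer(),
                      uniqueness = numeric()))
  out <- do.call(rbind, Map(function(kk, dd) seed_uniqueness(genome, kk, dd),
                            grid$k, grid$delta))
  out[order(out$k, out$delta), , drop = FALSE]
}

#' Write a uniqueness curve as TSV
#'
#' @param curve output of [uniqueness_curve()].
#' @param path output path.
#' @export
write_uniqueness_tsv <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
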