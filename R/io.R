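#' Read a FASTA file
#'
#' Tolerant of multi-line records; sequences are uppercased on ingest.
#' Paths ending in `.gz` are decompressed transparently.
#'
#' @param path file path (plain or gzip).
#' @return Named character vector of sequences (names from the header up
#'   to the first whitespace).
#' @export
read_fasta <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), ids[as.integer(names(seqs))])
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path (gzip if it ends in `.gz`).
#' @param width line wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a (4-line) FASTQ file
#'
#' @param path file path (plain or gzip).
#' @return A data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  i <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("\\s.*$", "", sub("^@", "", lines[i])),
             seq = toupper(lines[i + 1L]),
             qual = lines[i + 3L],
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads a data.frame with `id`, `seq` and optionally `qual` (a
#'   constant "I" quality is written when absent).
#' @param path output path (gzip if it ends in `.gz`).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- if ("qual" %in% names(reads)) reads$qual
          else strrep("I", nchar(reads$seq))
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), con)
  invisible(path)
}
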