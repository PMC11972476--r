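#' Per-position genomic k-mer occurrence counts
#'
#' For every valid start position `i` of every fragment, counts the number
#' of positions (over all fragments and both strands) whose k-mer equals the
#' k-mer starting at `i` (`mismatches = 0`), or lies within the given
#' Hamming distance of it (`mismatches` up to 2). A k-mer always matches
#' itself, so every defined count is at least 1. Positions whose window
#' contains `N` carry `NA` ("poison"): assembly gaps must not masquerade as
#' unique sequence, and downstream window sums treat them as infinite.
#'
#' Counting is performed by exact Hamming-ball enumeration over a hash table
#' of the genome's k-mers of both strands; no seeding heuristics.
#'
#' @param g a [genome()].
#' @param k k-mer size in nt, `1 <= k <= 31`; must not exceed the longest
#'   fragment.
#' @param mismatches allowed Hamming distance, 0, 1 or 2.
#' @return a `kmer_count_track`: list with `genome_id`, `k`, `mismatches`
#'   and `counts`, a named list of integer vectors (one per fragment, length
#'   `max(0, fragment_length - k + 1)`, `NA` = poison).
#' @export
count_kmers <- function(g, k, mismatches = 0L) {
  stopifnot(inherits(g, "genome"))
  k <- as.integer(k); mismatches <- as.integer(mismatches)
  if (k < 1L) stop("k must be >= 1")
  if (mismatches < 0L || mismatches > 2L)
    stop("mismatches must be 0, 1 or 2")
  if (mismatches >= k) stop("mismatch allowance must be smaller than k")
  if (k > max(nchar(g$fragments)))
    stop("k = ", k, " exceeds the longest fragment (",
         max(nchar(g$fragments)), " nt)")
  counts <- cpp_kmer_counts(g$fragments, k, mismatches)
  names(counts) <- names(g$fragments)
  structure(list(genome_id = g$genome_id, k = k, mismatches = mismatches,
                 counts = counts),
            class = "kmer_count_track")
}

#' @export
print.kmer_count_track <- function(x, ...) {
  np <- sum(lengths(x$counts))
  cat(sprintf(
    "<kmer_count_track '%s'>: k=%d, mismatches=%d, %d position(s)\n",
    x$genome_id, x$k, x$mismatches, np))
  invisible(x)
}

#' Suggested k for a genome of length n
#'
#' `k = round(log4(n))`, so that a random k-mer is expected roughly once in
#' the genome; slightly larger values keep roughly unique k-mers informative
#' without being unique with near certainty.
#'
#' @param n genome length in nt.
#' @return integer k.
#' @export
suggest_k <- function(n) {
  if (n < 4) stop("genome too short")
  as.integer(round(log(n, base = 4)))
}

#' Export mappability (1/h_k) as bedGraph
#'
#' Inverse occurrence counts: 1 marks k-mers unique in the genome (both
#' strands). Poison positions are skipped.
#'
#' @param track a [count_kmers()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mappability_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "kmer_count_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=mappability_k%d_m%d",
                     track$k, track$mismatches), con)
  for (nm in names(track$counts)) {
    v <- track$counts[[nm]]
    ok <- which(!is.na(v))
    if (length(ok) == 0) next
    writeLines(sprintf("%s\t%d\t%d\t%.6g", nm, ok - 1L, ok,
                       1 / v[ok]), con)
  }
  invisible(path)
}

#' Ingest externally computed per-position k-mer frequencies
#'
#' Adapter for cross-validation against an external mappability tool. The
#' expected format is plain text: one `>fragment` header line per fragment
#' followed by whitespace-separated integer frequencies, one value per valid
#' k-mer start position (non-positive or missing values are read as poison).
#'
#' @param path input path.
#' @param genome_id,k,mismatches metadata to attach.
#' @return a `kmer_count_track`.
#' @export
read_frequency_track <- function(path, genome_id, k, mismatches = 0L) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no fragment headers in ", path)
  counts <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    nm <- sub("^>\\s*", "", lines[hdr[i]])
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    tok <- unlist(strsplit(paste(body, collapse = " "), "\\s+"))
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.integer(tok)) # non-numeric tokens become poison
    v[!is.na(v) & v < 1L] <- NA_integer_
    counts[[nm]] <- v
  }
  structure(list(genome_id = genome_id, k = as.integer(k),
                 mismatches = as.integer(mismatches), counts = counts),
            class = "kmer_count_track")
}
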