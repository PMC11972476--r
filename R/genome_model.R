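#' Construct a genome object
#'
#' A genome is an ordered collection of assembly fragments (chromosomes,
#' scaffolds or contigs) over the alphabet `{A,C,G,T,N}`. Fragment ends act
#' as hard breaks: no window, k-mer or alignment ever crosses a fragment
#' boundary. Coordinates are 0-based half-open throughout the package.
#'
#' @param fragments named character vector of fragment sequences. Names must
#'   be unique; sequences are uppercased on input.
#' @param genome_id identifier for the genome.
#' @return an object of class `genome` with elements `genome_id`,
#'   `fragments` (named character vector), and optionally `offsets` /
#'   `source` bookkeeping set by [excise()].
#' @export
genome <- function(fragments, genome_id = "genome") {
  if (length(fragments) < 1) stop("a genome needs at least one fragment")
  nm <- names(fragments)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    stop("all fragments must be named")
  if (anyDuplicated(nm))
    stop("duplicate fragment name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  fragments <- toupper(fragments)
  for (i in seq_along(fragments)) {
    bad <- regexpr("[^ACGTN]", fragments[[i]])
    if (bad > 0L)
      stop(sprintf("illegal character '%s' in fragment '%s' at offset %d",
                   substr(fragments[[i]], bad, bad), nm[i], bad - 1L))
  }
  structure(
    list(genome_id = genome_id, fragments = fragments),
    class = "genome")
}

#' Read a genome from a FASTA file
#'
#' One fragment per record, record order preserved, sequences uppercased.
#' Lowercase (soft-masked) bases are uppercased and not treated as masked:
#' the k-mer rareness filter is the package's own masking mechanism.
#'
#' @param path path to a FASTA file with at least one record.
#' @param genome_id identifier; defaults to the file name without extension.
#' @return a [genome()] object.
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0) stop("FASTA file contains no records: ", path)
  seqs <- as.character(dss)
  # readBStringSet keeps full headers; fragment name = first token
  names(seqs) <- vapply(strsplit(names(dss), "[ \t]"), `[`, "", 1)
  genome(seqs, genome_id = genome_id)
}

#' Write a genome to a FASTA file
#' @param g a [genome()].
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(g$fragments)) {
    writeLines(paste0(">", nm), con)
    s <- g$fragments[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Total genome length in nucleotides
#' @param g a [genome()].
#' @return integer, sum of fragment lengths.
#' @export
genome_length <- function(g) {
  stopifnot(inherits(g, "genome"))
  sum(nchar(g$fragments))
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome '%s'>: %d fragment(s), %s nt total\n",
              x$genome_id, length(x$fragments),
              format(genome_length(x), big.mark = ",")))
  invisible(x)
}

#' Genomic interval
#'
#' 0-based half-open interval `[start, end)` on one fragment.
#'
#' @param fragment fragment name.
#' @param start,end integer bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return a list of class `genomic_interval`.
#' @export
genomic_interval <- function(fragment, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: require 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(fragment = fragment, start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised.
#'
#' @param seq character vector over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
reverse_complement <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L))
    stop("illegal character in sequence at offset ",
         min(bad[bad > 0L]) - 1L)
  vapply(seq, function(s) as.character(cpp_revcomp(s)), "",
         USE.NAMES = FALSE)
}

#' Excise an interval from a genome
#'
#' Returns the genome with the locus removed: the host fragment is split
#' into the prefix before `locus$start` and the suffix from `locus$end`,
#' each becoming its own fragment (empty pieces are dropped). This realises
#' the "replace by fragment breaks" semantics used for within-genome
#' uniqueness: no alignment against the excised genome can cross the cut.
#' Coordinate bookkeeping (`offsets`, `source`) is attached so hits against
#' the excised genome can be reported in original coordinates.
#'
#' @param g a [genome()].
#' @param locus a [genomic_interval()] lying within one fragment of `g`.
#' @return a `genome` with `offsets` (named integer, offset of each fragment
#'   in its source fragment) and `source` (named character, source fragment
#'   name) elements.
#' @export
excise <- function(g, locus) {
  stopifnot(inherits(g, "genome"), inherits(locus, "genomic_interval"))
  host <- locus$fragment
  if (!host %in% names(g$fragments)) stop("unknown fragment: ", host)
  len <- nchar(g$fragments[[host]])
  if (locus$end > len) stop("locus out of bounds on fragment ", host)

  frs <- character(0); offs <- integer(0); srcs <- character(0)
  for (nm in names(g$fragments)) {
    s <- g$fragments[[nm]]
    if (!identical(nm, host)) {
      frs[nm] <- s; offs[nm] <- 0L; srcs[nm] <- nm
      next
    }
    if (locus$start > 0L) {
      pn <- paste0(nm, ":0")
      frs[pn] <- substr(s, 1L, locus$start)
      offs[pn] <- 0L; srcs[pn] <- nm
    }
    if (locus$end < len) {
      sn <- paste0(nm, ":", locus$end)
      frs[sn] <- substr(s, locus$end + 1L, len)
      offs[sn] <- locus$end; srcs[sn] <- nm
    }
  }
  if (length(frs) == 0)
    stop("excision removed the entire genome")
  out <- genome(frs, genome_id = g$genome_id)
  out$offsets <- offs
  out$source <- srcs
  out
}

#' Extract the sequence of an interval
#' @param g a [genome()].
#' @param fragment fragment name.
#' @param start,end 0-based half-open bounds.
#' @return character scalar.
#' @export
fragment_seq <- function(g, fragment, start, end) {
  s <- g$fragments[[fragment]]
  if (is.null(s)) stop("unknown fragment: ", fragment)
  if (start < 0L || end > nchar(s) || start >= end)
    stop("interval out of bounds on fragment ", fragment)
  substr(s, start + 1L, end)
}

#' Echo fragment extents as BED3
#' @param g a [genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(g, path) {
  df <- data.frame(chrom = names(g$fragments), start = 0L,
                   end = nchar(g$fragments))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
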