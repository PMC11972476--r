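#' Alignment score model
#'
#' Raw-score parameters mirror blastn defaults (match +2, mismatch -3, gap
#' open 5, gap extend 2; a gap of length L costs `open + L * extend`), with
#' the matching gapped Karlin-Altschul parameters `lambda` and `K`, so bit
#' scores live on the familiar blastn scale and the 40-bit floor used
#' downstream keeps its usual meaning. `alpha` is the idealised
#' per-nucleotide self-comparison information (2 bits for uniformly
#' distributed nucleotides) used only in the distance form
#' `d = alpha * l - s` and the anchor-match guarantee flag.
#'
#' @param match,mismatch,gap_open,gap_extend raw alignment scores/penalties.
#' @param lambda,K Karlin-Altschul parameters for this scoring scheme.
#' @param alpha per-position self-score in bits (default 2).
#' @param word_size exact seed word length (default 11).
#' @param evalue_cutoff maximum E-value of emitted fragments (default 1e-3).
#' @param band half-width of the banded gapped extension (default 64 nt).
#' @param x_drop raw-score drop at which extension terminates (default 100).
#' @return an object of class `score_model`.
#' @export
score_model <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                        gap_extend = 2L, lambda = 0.625, K = 0.41,
                        alpha = 2, word_size = 11L, evalue_cutoff = 1e-3,
                        band = 64L, x_drop = 100L) {
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  if (match <= 0 || mismatch >= 0) stop("need match > 0 and mismatch < 0")
  if (gap_open < 0 || gap_extend <= 0) stop("invalid gap penalties")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, alpha = alpha,
                 word_size = as.integer(word_size),
                 evalue_cutoff = evalue_cutoff,
                 band = as.integer(band), x_drop = as.integer(x_drop)),
            class = "score_model")
}

#' Convert raw alignment scores to bit scores
#' @param raw raw score(s).
#' @param model a [score_model()].
#' @return numeric bit score(s), `(lambda * raw - log(K)) / log(2)`.
#' @export
bit_score <- function(raw, model = score_model()) {
  (model$lambda * raw - log(model$K)) / log(2)
}

#' E-value of a raw score in a given search space
#' @param raw raw score(s).
#' @param m,n query and subject lengths (search space `m * n`).
#' @param model a [score_model()].
#' @return expected number of chance hits scoring at least `raw`.
#' @export
evalue <- function(raw, m, n, model = score_model()) {
  model$K * as.numeric(m) * as.numeric(n) * exp(-model$lambda * raw)
}

subject_fragments <- function(subject) {
  if (inherits(subject, "genome")) subject$fragments
  else if (is.character(subject)) {
    if (length(subject) > 0 && is.null(names(subject)))
      stop("subject sequences must be named")
    subject
  } else stop("subject must be a genome or a named character vector")
}

#' Local alignment of queries against a subject
#'
#' Seed-and-extend local alignment: exact seeding at `word_size`, banded
#' gapped extension with affine gaps and x-drop termination, on both
#' strands. Fragments are scored with the Karlin-Altschul model over the
#' search space `|query| x total subject length` and those with E-value
#' above the cutoff are suppressed. Deterministic for fixed inputs.
#'
#' @param queries character vector of query sequences (each at least
#'   `word_size` long).
#' @param subject a [genome()] or a named character vector of sequences.
#' @param model a [score_model()].
#' @return data.frame with one row per alignment fragment: `query` (index
#'   into `queries`), `qstart`, `qend` (forward query coords), `sfrag`
#'   (subject fragment name), `sstart`, `send` (forward subject coords),
#'   `strand`, `raw`, `bits`, `evalue`. Coordinates 0-based half-open.
#' @export
align_sequences <- function(queries, subject, model = score_model()) {
  frs <- subject_fragments(subject)
  empty <- data.frame(query = integer(0), qstart = integer(0),
                      qend = integer(0), sfrag = character(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), raw = integer(0),
                      bits = numeric(0), evalue = numeric(0))
  if (length(frs) == 0 || length(queries) == 0) return(empty)
  if (any(nchar(queries) < model$word_size))
    stop("all queries must be at least word_size (", model$word_size,
         ") nt long")
  hits <- cpp_align_multi(queries, frs, model$match, model$mismatch,
                          model$gap_open, model$gap_extend,
                          model$word_size, model$band, model$x_drop)
  if (nrow(hits) == 0) return(empty)
  hits$sfrag <- names(frs)[hits$sfrag]
  n_subject <- sum(nchar(frs))
  hits$bits <- bit_score(hits$raw, model)
  hits$evalue <- evalue(hits$raw, nchar(queries)[hits$query], n_subject,
                        model)
  hits <- hits[hits$evalue <= model$evalue_cutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Parse a 12-column tabular alignment report
#'
#' Adapter for blastn `-outfmt 6` reports (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). 1-based
#' inclusive coordinates are converted to the package's 0-based half-open
#' convention; `sstart > send` encodes a minus-strand hit.
#'
#' @param path path to the report, or a character vector of its lines.
#' @return data.frame with `query` (query id as given), `qstart`, `qend`,
#'   `sfrag`, `sstart`, `send`, `strand`, `bits`, `evalue`.
#' @export
parse_blast_tabular <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(query = character(0), qstart = integer(0),
                      qend = integer(0), sfrag = character(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), bits = numeric(0),
                      evalue = numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12))
    stop("malformed tabular report: expected 12 columns, got ",
         nc[which(nc != 12)[1]], " at line ", which(nc != 12)[1])
  m <- do.call(rbind, parts)
  qs <- as.integer(m[, 7]); qe <- as.integer(m[, 8])
  ss <- as.integer(m[, 9]); se <- as.integer(m[, 10])
  if (anyNA(qs) || anyNA(qe) || anyNA(ss) || anyNA(se))
    stop("malformed tabular report: non-integer coordinate at line ",
         which(is.na(qs) | is.na(qe) | is.na(ss) | is.na(se))[1])
  minus <- ss > se
  data.frame(query = m[, 1],
             qstart = qs - 1L, qend = qe,
             sfrag = m[, 2],
             sstart = ifelse(minus, se - 1L, ss - 1L),
             send = ifelse(minus, ss, se),
             strand = ifelse(minus, "-", "+"),
             bits = as.numeric(m[, 12]),
             evalue = as.numeric(m[, 11]),
             stringsAsFactors = FALSE)
}

#' Exact local alignment score (reference scorer)
#'
#' Full-matrix Smith-Waterman optimum raw score with affine gaps under the
#' model's scoring scheme. Quadratic time and intended for short sequences:
#' used by the consistency audits on extracted subsequences and as an exact
#' reference for the seed-and-extend engine.
#'
#' @param a,b DNA strings.
#' @param model a [score_model()].
#' @return integer optimal local raw score.
#' @export
sw_score <- function(a, b, model = score_model()) {
  cpp_sw_score(a, b, model$match, model$mismatch, model$gap_open,
               model$gap_extend)
}

#' Vectorised [sw_score()] of one query against many subjects
#' @param a DNA string.
#' @param bs character vector of subjects.
#' @param model a [score_model()].
#' @return integer vector of optimal raw scores.
#' @export
sw_score_many <- function(a, bs, model = score_model()) {
  cpp_sw_score_many(a, bs, model$match, model$mismatch, model$gap_open,
                    model$gap_extend)
}
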