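#' Collinear chaining of alignment fragments
#'
#' Groups fragments of one query by (subject fragment, strand) and, per
#' group, finds the chain of non-overlapping fragments consecutive on both
#' query and subject that maximises the summed bit score. "Consecutive"
#' means strictly increasing and non-overlapping on both axes (decreasing
#' subject coordinates for minus-strand groups); zero-gap adjacency is
#' allowed and no gap cost is charged between chained fragments. Ties are
#' broken toward fewer fragments, then toward the smaller first query
#' start. Singleton fragments are valid chains.
#'
#' @param frags data.frame of alignment fragments of a single query, as
#'   produced by [align_sequences()] (columns `qstart`, `qend`, `sfrag`,
#'   `sstart`, `send`, `strand`, `bits`).
#' @return data.frame with one row per (subject fragment, strand) group:
#'   `sfrag`, `strand`, `score` (summed bits), `n_frags`, and the chain
#'   span `qstart`, `qend`, `sstart`, `send`; the list column `members`
#'   holds the member fragment rows in chain order. Zero rows for empty
#'   input.
#' @export
chain_fragments <- function(frags) {
  empty <- data.frame(sfrag = character(0), strand = character(0),
                      score = numeric(0), n_frags = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0))
  empty$members <- list()
  if (is.null(frags) || nrow(frags) == 0) return(empty)
  if (length(unique(frags$query)) > 1)
    stop("chain_fragments expects fragments of a single query")

  out <- list()
  for (key in unique(paste(frags$sfrag, frags$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    gf <- frags[frags$sfrag == parts[1] & frags$strand == parts[2], ,
                drop = FALSE]
    # orient subject axis so that collinear always means increasing
    if (parts[2] == "+") { ts <- gf$sstart; te <- gf$send }
    else { ts <- -gf$send; te <- -gf$sstart }
    o <- order(gf$qstart, ts)
    gf <- gf[o, , drop = FALSE]; ts <- ts[o]; te <- te[o]
    n <- nrow(gf)
    score <- gf$bits; nfr <- rep(1L, n); firstq <- gf$qstart
    parent <- rep(0L, n)
    for (j in seq_len(n)) {
      for (i in seq_len(j - 1L)) {
        if (gf$qend[i] <= gf$qstart[j] && te[i] <= ts[j]) {
          cs <- score[i] + gf$bits[j]
          cn <- nfr[i] + 1L
          cq <- firstq[i]
          better <- cs > score[j] ||
            (cs == score[j] && (cn < nfr[j] ||
                                (cn == nfr[j] && cq < firstq[j])))
          if (better) {
            score[j] <- cs; nfr[j] <- cn; firstq[j] <- cq; parent[j] <- i
          }
        }
      }
    }
    best <- 1L
    for (j in seq_len(n)) {
      better <- score[j] > score[best] ||
        (score[j] == score[best] && (nfr[j] < nfr[best] ||
          (nfr[j] == nfr[best] && firstq[j] < firstq[best])))
      if (better) best <- j
    }
    chain_idx <- integer(0); j <- best
    while (j > 0L) { chain_idx <- c(j, chain_idx); j <- parent[j] }
    mem <- gf[chain_idx, , drop = FALSE]
    row <- data.frame(sfrag = parts[1], strand = parts[2],
                      score = score[best], n_frags = nfr[best],
                      qstart = min(mem$qstart), qend = max(mem$qend),
                      sstart = min(mem$sstart), send = max(mem$send),
                      stringsAsFactors = FALSE)
    row$members <- list(mem)
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-nucleotide maximum-score track of a query
#'
#' Position `p` of the query carries the maximum bit score over all
#' fragments whose query interval covers `p`; uncovered positions carry 0.
#'
#' @param frags data.frame of alignment fragments of one query (possibly
#'   after exclusion filtering); may have zero rows.
#' @param query_length length of the query in nt.
#' @return numeric vector of length `query_length`.
#' @export
score_track <- function(frags, query_length) {
  track <- numeric(query_length)
  if (is.null(frags) || nrow(frags) == 0) return(track)
  if (any(frags$qstart < 0L) || any(frags$qend > query_length))
    stop("fragment query interval outside [0, query_length)")
  o <- order(frags$bits) # ascending: later (higher) wins
  for (i in o) {
    track[(frags$qstart[i] + 1L):frags$qend[i]] <-
      pmax(track[(frags$qstart[i] + 1L):frags$qend[i]], frags$bits[i])
  }
  track
}
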