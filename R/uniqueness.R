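#' Convert a bit score to the alignment distance form
#'
#' `d = alpha * l - s`: the distance of two length-`l` sequences implied by
#' their similarity bit score `s`, with `alpha` the per-position
#' self-comparison information (2 bits for uniform nucleotide composition).
#' Used for reporting and for the anchor-match guarantee diagnostics.
#'
#' @param s bit score(s).
#' @param l sequence length in nt.
#' @param alpha bits per position (default 2).
#' @return numeric distance(s).
#' @export
score_to_distance <- function(s, l, alpha = 2) {
  if (any(s < 0)) stop("bit scores must be non-negative")
  alpha * l - s
}

#' Within-genome uniqueness of one candidate interval
#'
#' Aligns the candidate sequence against the genome with the candidate's
#' own locus excised (so the trivial self-hit and anything crossing the cut
#' cannot contribute), maps hits back to original genome coordinates,
#' discards fragments and chains whose target interval still overlaps the
#' origin locus by more than `overlap_tol` of the hit's target length, and
#' summarises the survivors: the per-nucleotide maximum-score track, its
#' maximum `s0` (floored at `floor` bits so weak noise never certifies
#' spurious uniqueness), and the best surviving chain for diagnostics.
#'
#' @param g a [genome()].
#' @param fragment,start,end the candidate locus (0-based half-open).
#' @param model a [score_model()].
#' @param overlap_tol maximal tolerated origin overlap as a fraction of a
#'   hit's target length (default 0.25).
#' @param floor minimum `s0` in bits (default 40).
#' @return list with `s0` (bits), `track` (numeric, one value per candidate
#'   nucleotide), `best_chain_score`, `n_hits` (surviving fragments), and
#'   `d0 = alpha * l - s0`.
#' @export
self_uniqueness <- function(g, fragment, start, end, model = score_model(),
                            overlap_tol = 0.25, floor = 40) {
  qseq <- fragment_seq(g, fragment, start, end)
  qlen <- end - start
  ex <- excise(g, genomic_interval(fragment, start, end))
  hits <- align_sequences(qseq, ex, model)
  if (nrow(hits) > 0) {
    # back to original coordinates
    hits$sstart <- hits$sstart + ex$offsets[hits$sfrag]
    hits$send <- hits$send + ex$offsets[hits$sfrag]
    hits$sfrag <- unname(ex$source[hits$sfrag])
    # origin-overlap exclusion (vacuous after excision, but kept for hits
    # imported from engines that search the full genome)
    ov <- pmin(hits$send, end) - pmax(hits$sstart, start)
    ov[hits$sfrag != fragment] <- 0L
    hits <- hits[pmax(ov, 0L) / (hits$send - hits$sstart) <= overlap_tol, ,
                 drop = FALSE]
  }
  chains <- chain_fragments(hits)
  if (nrow(chains) > 0) {
    cov <- pmin(chains$send, end) - pmax(chains$sstart, start)
    cov[chains$sfrag != fragment] <- 0L
    chains <- chains[pmax(cov, 0L) / (chains$send - chains$sstart) <=
                       overlap_tol, , drop = FALSE]
  }
  track <- score_track(hits, qlen)
  s0 <- max(c(track, floor))
  list(s0 = s0,
       track = track,
       best_chain_score = if (nrow(chains)) max(chains$score) else NA_real_,
       n_hits = nrow(hits),
       d0 = score_to_distance(s0, qlen, model$alpha))
}

#' Annotate a candidate set with within-genome uniqueness scores
#'
#' Runs [self_uniqueness()] for every candidate interval and attaches the
#' columns `s0`, `d0`, `best_chain_score` and `n_self_hits` to the set,
#' plus the candidate sequences. This is the per-genome precomputation
#' whose output can be stored as a simple annotation track and reused for
#' any number of pairwise comparisons.
#'
#' @param g a [genome()].
#' @param cs a [build_candidates()] result for `g`.
#' @param model a [score_model()].
#' @param overlap_tol,floor see [self_uniqueness()].
#' @return `cs` with annotation columns added and `model` attached.
#' @export
annotate_uniqueness <- function(g, cs, model = score_model(),
                                overlap_tol = 0.25, floor = 40) {
  stopifnot(inherits(g, "genome"), inherits(cs, "candidate_set"))
  if (!identical(g$genome_id, cs$genome_id))
    stop("genome and candidate set ids differ")
  df <- cs$candidates
  n <- nrow(df)
  df$sequence <- character(n)
  df$s0 <- df$d0 <- df$best_chain_score <- numeric(n)
  df$n_self_hits <- integer(n)
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    df$sequence[i] <- fragment_seq(g, df$fragment[i], df$start[i], df$end[i])
    u <- self_uniqueness(g, df$fragment[i], df$start[i], df$end[i],
                         model = model, overlap_tol = overlap_tol,
                         floor = floor)
    df$s0[i] <- u$s0
    df$d0[i] <- u$d0
    df$best_chain_score[i] <- u$best_chain_score
    df$n_self_hits[i] <- u$n_hits
    tracks[[i]] <- u$track
  }
  cs$candidates <- df
  cs$tracks <- tracks
  cs$model <- model
  cs$floor <- floor
  cs
}
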