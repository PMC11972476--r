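#' Anchor-match acceptance threshold
#'
#' For a candidate pair with within-genome uniqueness scores `s0_x`, `s0_y`
#' (bits, already floored), the cross-genome score must exceed
#' `max(s0_x + sqrt(s0_x), s0_y + sqrt(s0_y))` when each candidate has at
#' most one raw hit on the other side (the square-root margin absorbs the
#' variance of the score estimates), and the more conservative
#' `2 * max(s0_x, s0_y)` as soon as either side is ambiguous (more than one
#' raw hit). Vectorised.
#'
#' @param s0_x,s0_y uniqueness scores in bits.
#' @param n_hits_x,n_hits_y number of distinct raw partner candidates of
#'   each side (before threshold filtering).
#' @return data.frame with `threshold` (bits) and `rule`
#'   (`"standard"` or `"multi-hit"`).
#' @export
compute_threshold <- function(s0_x, s0_y, n_hits_x = 1L, n_hits_y = 1L) {
  if (any(s0_x < 0) || any(s0_y < 0)) stop("s0 must be non-negative")
  n <- max(length(s0_x), length(s0_y), length(n_hits_x), length(n_hits_y))
  s0_x <- rep_len(s0_x, n); s0_y <- rep_len(s0_y, n)
  n_hits_x <- rep_len(n_hits_x, n); n_hits_y <- rep_len(n_hits_y, n)
  std <- pmax(s0_x + sqrt(s0_x), s0_y + sqrt(s0_y))
  multi <- 2 * pmax(s0_x, s0_y)
  use_multi <- n_hits_x > 1L | n_hits_y > 1L
  data.frame(threshold = ifelse(use_multi, multi, std),
             rule = ifelse(use_multi, "multi-hit", "standard"),
             stringsAsFactors = FALSE)
}

#' Guaranteed anchor-match condition
#'
#' Flags matches whose score satisfies
#' `s > max(s0_x, s0_y) / 2 + alpha * l / 2`, the bit-score form of the
#' triangle-inequality guarantee `d(w, y) <= min(d0_x, d0_y) / 2` under
#' which a pair of sufficiently unique candidates is provably an anchor
#' match. For partners of unequal length, the shorter partner's length is
#' used. The flag is diagnostic only and never used to reject a match.
#'
#' @param score match score in bits.
#' @param s0_x,s0_y uniqueness scores in bits.
#' @param len_x,len_y candidate lengths in nt.
#' @param alpha bits per position (default 2).
#' @return logical.
#' @export
lemma_guarantee_check <- function(score, s0_x, s0_y, len_x, len_y,
                                  alpha = 2) {
  l <- pmin(len_x, len_y)
  score > pmax(s0_x, s0_y) / 2 + alpha * l / 2
}

# greedy 1-1 resolution of close, overlapping partners: keep the best
# scoring match, then any further match whose subinterval on the shared
# candidate overlaps every kept one by less than `disjoint_overlap` of the
# shorter subinterval
resolve_close_partners <- function(starts, ends, scores, disjoint_overlap) {
  o <- order(-scores, starts)
  kept <- integer(0)
  for (i in o) {
    ok <- TRUE
    for (j in kept) {
      ov <- min(ends[i], ends[j]) - max(starts[i], starts[j])
      shorter <- min(ends[i] - starts[i], ends[j] - starts[j])
      if (ov >= disjoint_overlap * shorter) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# gap between two loci; Inf across fragments
locus_gap <- function(frag1, s1, e1, frag2, s2, e2) {
  if (!identical(frag1, frag2)) return(Inf)
  max(0, max(s1, s2) - min(e1, e2))
}

# apply the multi-partner rule on one side of the match table.
# side: list with per-match partner locus (frag/start/end on the OTHER
# genome) and the subinterval on THIS side's candidate.
apply_omission <- function(m, cand_col, part_frag, part_s, part_e,
                           sub_s, sub_e, proximity, disjoint_overlap) {
  drop <- rep(FALSE, nrow(m))
  for (cand in unique(m[[cand_col]])) {
    idx <- which(m[[cand_col]] == cand & !drop)
    if (length(idx) < 2) next
    # any two partners far apart (or on different fragments)?
    far <- FALSE
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      if (locus_gap(m[[part_frag]][i], m[[part_s]][i], m[[part_e]][i],
                    m[[part_frag]][j], m[[part_s]][j], m[[part_e]][j]) >
            proximity) { far <- TRUE; break }
    }
    if (far) { drop[idx] <- TRUE; next }
    keep <- resolve_close_partners(m[[sub_s]][idx], m[[sub_e]][idx],
                                   m$score[idx], disjoint_overlap)
    drop[setdiff(idx, idx[keep])] <- TRUE
  }
  m[!drop, , drop = FALSE]
}

#' Find anchor matches between two annotated candidate sets
#'
#' Aligns every candidate of one genome against the candidate sequences of
#' the other (both strands), chains the fragments per candidate pair, and
#' accepts a pair as an anchor match when its best chain score exceeds
#' [compute_threshold()] for the pair. A candidate whose accepted partners
#' on the other side lie further apart than `proximity` nt (or on
#' different fragments) is omitted altogether; partners in close proximity
#' are all retained provided their alignments occupy essentially disjoint
#' subintervals of the shared candidate, otherwise only the best-scoring
#' match survives, so the result is in near-perfect 1-1 correspondence.
#'
#' Matches are computed with the lexicographically smaller genome id as
#' the query side and mirrored on return, which makes
#' `find_anchor_matches(G, H)` and `find_anchor_matches(H, G)` exactly
#' symmetric.
#'
#' @param cs_x,cs_y candidate sets annotated by [annotate_uniqueness()].
#' @param model a [score_model()]; must be the one used for annotation.
#' @param proximity maximal genomic gap (nt) between multiple partners of
#'   one candidate before the candidate is omitted (default 10000).
#' @param disjoint_overlap maximal subinterval overlap fraction (of the
#'   shorter subinterval) under which close multiple partners count as
#'   disjoint (default 0.2).
#' @return data.frame with one row per anchor match: candidate ids and
#'   loci of both sides, matched subintervals in genome coordinates
#'   (`x_sub_start` etc.), `strand` (relative orientation), `score`
#'   (bits), `threshold`, `rule`, `lemma_guaranteed`, `n_hits_x`,
#'   `n_hits_y`.
#' @export
find_anchor_matches <- function(cs_x, cs_y, model = score_model(),
                                proximity = 10000L,
                                disjoint_overlap = 0.2) {
  stopifnot(inherits(cs_x, "candidate_set"), inherits(cs_y, "candidate_set"))
  if (is.null(cs_x$candidates$s0) || is.null(cs_y$candidates$s0))
    stop("candidate sets must carry s0 annotations; ",
         "run annotate_uniqueness() first")
  if (identical(cs_x$genome_id, cs_y$genome_id))
    stop("candidate sets come from the same genome")
  swapped <- cs_x$genome_id > cs_y$genome_id
  A <- if (swapped) cs_y else cs_x
  B <- if (swapped) cs_x else cs_y

  da <- A$candidates; db <- B$candidates
  cols <- c("genome_x", "candidate_x", "x_frag", "x_start", "x_end",
            "genome_y", "candidate_y", "y_frag", "y_start", "y_end",
            "x_sub_start", "x_sub_end", "y_sub_start", "y_sub_end",
            "strand", "score", "threshold", "rule", "lemma_guaranteed",
            "n_hits_x", "n_hits_y")
  empty <- stats::setNames(
    data.frame(character(0), character(0), character(0), integer(0),
               integer(0), character(0), character(0), character(0),
               integer(0), integer(0), integer(0), integer(0), integer(0),
               integer(0), character(0), numeric(0), numeric(0),
               character(0), logical(0), integer(0), integer(0)), cols)
  if (nrow(da) == 0 || nrow(db) == 0) return(empty)

  subj <- stats::setNames(db$sequence, db$candidate_id)
  hits <- align_sequences(da$sequence, subj, model)
  if (nrow(hits) == 0) return(empty)

  # raw ambiguity counts (distinct partners with any surviving fragment)
  pairs_raw <- unique(hits[, c("query", "sfrag")])
  n_hits_a <- table(factor(pairs_raw$query, levels = seq_len(nrow(da))))
  n_hits_b <- table(factor(pairs_raw$sfrag, levels = db$candidate_id))

  rows <- list()
  for (qi in unique(hits$query)) {
    ch <- chain_fragments(hits[hits$query == qi, , drop = FALSE])
    if (nrow(ch) == 0) next
    for (b_id in unique(ch$sfrag)) {
      sub <- ch[ch$sfrag == b_id, , drop = FALSE]
      best <- sub[order(-sub$score, sub$strand), ][1, , drop = FALSE]
      bi <- match(b_id, db$candidate_id)
      thr <- compute_threshold(da$s0[qi], db$s0[bi],
                               as.integer(n_hits_a[[as.character(qi)]]),
                               as.integer(n_hits_b[[b_id]]))
      if (best$score <= thr$threshold) next
      rows[[length(rows) + 1L]] <- data.frame(
        genome_x = A$genome_id, candidate_x = da$candidate_id[qi],
        x_frag = da$fragment[qi], x_start = da$start[qi],
        x_end = da$end[qi],
        genome_y = B$genome_id, candidate_y = b_id,
        y_frag = db$fragment[bi], y_start = db$start[bi],
        y_end = db$end[bi],
        x_sub_start = da$start[qi] + best$qstart,
        x_sub_end = da$start[qi] + best$qend,
        y_sub_start = db$start[bi] + best$sstart,
        y_sub_end = db$start[bi] + best$send,
        strand = best$strand, score = best$score,
        threshold = thr$threshold, rule = thr$rule,
        lemma_guaranteed = lemma_guarantee_check(
          best$score, da$s0[qi], db$s0[bi],
          da$end[qi] - da$start[qi], db$end[bi] - db$start[bi],
          model$alpha),
        n_hits_x = as.integer(n_hits_a[[as.character(qi)]]),
        n_hits_y = as.integer(n_hits_b[[b_id]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  m <- do.call(rbind, rows)

  # multi-partner handling, both sides
  m <- apply_omission(m, "candidate_x", "y_frag", "y_start", "y_end",
                      "x_sub_start", "x_sub_end", proximity,
                      disjoint_overlap)
  m <- apply_omission(m, "candidate_y", "x_frag", "x_start", "x_end",
                      "y_sub_start", "y_sub_end", proximity,
                      disjoint_overlap)
  rownames(m) <- NULL

  if (swapped) m <- mirror_matches(m)
  m
}

#' Mirror a match table (swap the two genome sides)
#' @param m a [find_anchor_matches()] table.
#' @return the table with x and y sides exchanged.
#' @export
mirror_matches <- function(m) {
  swap <- function(d, a, b) {
    tmp <- d[[a]]; d[[a]] <- d[[b]]; d[[b]] <- tmp; d
  }
  for (p in list(c("genome_x", "genome_y"), c("candidate_x", "candidate_y"),
                 c("x_frag", "y_frag"), c("x_start", "y_start"),
                 c("x_end", "y_end"), c("x_sub_start", "y_sub_start"),
                 c("x_sub_end", "y_sub_end"), c("n_hits_x", "n_hits_y")))
    m <- swap(m, p[1], p[2])
  m
}

#' Write an anchor-match table as TSV
#' @param m a [find_anchor_matches()] table.
#' @param path output path.
#' @param header optional `#`-prefixed header line(s).
#' @return `path`, invisibly.
#' @export
write_match_table <- function(m, path, header = NULL) {
  con <- file(path, "w")
  if (!is.null(header)) writeLines(header, con)
  suppressWarnings(utils::write.table(m, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  close(con)
  invisible(path)
}

#' Read an anchor-match table written by [write_match_table()]
#' @param path input path.
#' @return the match data.frame.
#' @export
read_match_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Export matches in MCScanX-style input layout
#'
#' Writes `<prefix>.homology` (candidate_x, candidate_y, score) and one
#' `<prefix>.<genome>.gff` per genome side (fragment, candidate id, start,
#' end; 1-based inclusive display coordinates), the tab-separated layout
#' collinearity tools expect.
#'
#' @param m a [find_anchor_matches()] table.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
export_mcscanx <- function(m, prefix) {
  paths <- character(0)
  hom <- data.frame(m$candidate_x, m$candidate_y, round(m$score, 1))
  p <- paste0(prefix, ".homology")
  utils::write.table(hom, p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths <- c(paths, p)
  sides <- rbind(
    data.frame(genome = m$genome_x, frag = m$x_frag, id = m$candidate_x,
               start = m$x_start, end = m$x_end),
    data.frame(genome = m$genome_y, frag = m$y_frag, id = m$candidate_y,
               start = m$y_start, end = m$y_end))
  sides <- unique(sides)
  for (gid in unique(sides$genome)) {
    d <- sides[sides$genome == gid, , drop = FALSE]
    gff <- data.frame(d$frag, d$id, d$start + 1L, d$end)
    p <- paste0(prefix, ".", gid, ".gff")
    utils::write.table(gff, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
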