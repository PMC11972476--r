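#' Build the anchor graph from pairwise match tables
#'
#' Vertices are anchor candidates (labelled `genome::candidate_id`), one
#' per candidate that takes part in at least one pairwise anchor match;
#' every match is an edge. Connected components are putative single-locus
#' clusters across the genomes; component ids are the lexicographically
#' smallest member label, so they are deterministic.
#'
#' @param matches a match table from [find_anchor_matches()], or a list of
#'   such tables over several genome pairs.
#' @return an `anchor_graph`: list with `graph` (igraph), `vertices`
#'   (data.frame `genome`, `candidate`, `component`), `edges` (the row-bound
#'   match tables), `components` (split of vertex labels).
#' @export
build_anchor_graph <- function(matches) {
  if (is.data.frame(matches)) matches <- list(matches)
  m <- do.call(rbind, matches)
  if (is.null(m) || nrow(m) == 0)
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          vertices = data.frame(genome = character(0),
                                                candidate = character(0),
                                                component = character(0)),
                          edges = m, components = list()),
                     class = "anchor_graph"))
  vx <- paste0(m$genome_x, "::", m$candidate_x)
  vy <- paste0(m$genome_y, "::", m$candidate_y)
  g <- igraph::graph_from_data_frame(data.frame(from = vx, to = vy),
                                     directed = FALSE)
  comp <- igraph::components(g)
  labels <- igraph::V(g)$name
  comp_members <- split(labels, comp$membership)
  comp_ids <- vapply(comp_members, function(v) min(v), "")
  vert_comp <- comp_ids[as.character(comp$membership)]
  parts <- strsplit(labels, "::", fixed = TRUE)
  vertices <- data.frame(
    genome = vapply(parts, `[`, "", 1),
    candidate = vapply(parts, `[`, "", 2),
    component = vert_comp, stringsAsFactors = FALSE)
  names(comp_members) <- comp_ids
  structure(list(graph = g, vertices = vertices, edges = m,
                 components = comp_members[order(comp_ids)]),
            class = "anchor_graph")
}

#' @export
print.anchor_graph <- function(x, ...) {
  cat(sprintf("<anchor_graph>: %d vertices, %d edges, %d component(s)\n",
              nrow(x$vertices), if (is.null(x$edges)) 0L else nrow(x$edges),
              length(x$components)))
  invisible(x)
}

#' Multi-genome cluster table
#' @param ag an [build_anchor_graph()] result.
#' @return data.frame `component_id`, `genome`, `candidate`.
#' @export
anchor_clusters <- function(ag) {
  stopifnot(inherits(ag, "anchor_graph"))
  v <- ag$vertices[order(ag$vertices$component, ag$vertices$genome,
                         ag$vertices$candidate), , drop = FALSE]
  data.frame(component_id = v$component, genome = v$genome,
             candidate = v$candidate, stringsAsFactors = FALSE,
             row.names = NULL)
}

audit_report <- function(summary, cases) {
  structure(list(summary = summary, cases = cases), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %s: %s\n", nm, format(x$summary[[nm]])))
  invisible(x)
}

#' Transitivity audit of an anchor graph
#'
#' If (w, y) and (y, z) are anchor matches across three genomes, the match
#' (w, z) is implied. The audit enumerates, per connected component, every
#' pair of members from distinct genomes that is not joined by an edge,
#' counts them as implied-missing, and (when candidate sets are supplied)
#' recomputes the similarity of each missing pair directly by alignment
#' and chaining, recording whether a significant alignment exists.
#'
#' @param ag an [build_anchor_graph()] result.
#' @param candidate_sets optional named list of annotated candidate sets
#'   (names = genome ids) enabling realignment of missing pairs.
#' @param model a [score_model()] for realignment.
#' @param significant_bits bit-score level above which a recomputed
#'   alignment counts as significant (default 40).
#' @return an `audit_report`: `summary` has `n_clusters`,
#'   `n_clusters_missing_edges`, `n_implied_checked`, `n_implied_missing`;
#'   `cases` lists each missing pair with `realigned_score` and
#'   `significant` when realignment was possible.
#' @export
audit_transitivity <- function(ag, candidate_sets = NULL,
                               model = score_model(),
                               significant_bits = 40) {
  stopifnot(inherits(ag, "anchor_graph"))
  adj <- character(0)
  if (!is.null(ag$edges) && nrow(ag$edges) > 0)
    adj <- paste(paste0(ag$edges$genome_x, "::", ag$edges$candidate_x),
                 paste0(ag$edges$genome_y, "::", ag$edges$candidate_y))
  has_edge <- function(u, v) paste(u, v) %in% adj | paste(v, u) %in% adj

  cases <- list()
  n_checked <- 0L
  clusters_missing <- character(0)
  for (cid in names(ag$components)) {
    members <- ag$components[[cid]]
    if (length(members) < 3) next
    gi <- sub("::.*$", "", members)
    for (a in seq_along(members)) for (b in seq_len(a - 1L)) {
      if (gi[a] == gi[b]) next
      n_checked <- n_checked + 1L
      if (has_edge(members[a], members[b])) next
      clusters_missing <- union(clusters_missing, cid)
      rec <- data.frame(component_id = cid,
                        vertex_1 = members[a], vertex_2 = members[b],
                        realigned_score = NA_real_, significant = NA,
                        stringsAsFactors = FALSE)
      if (!is.null(candidate_sets)) {
        seq1 <- candidate_seq(candidate_sets, members[a])
        seq2 <- candidate_seq(candidate_sets, members[b])
        if (!is.null(seq1) && !is.null(seq2)) {
          hits <- align_sequences(seq1, c(other = seq2), model)
          ch <- chain_fragments(hits)
          rec$realigned_score <- if (nrow(ch)) max(ch$score) else 0
          rec$significant <- rec$realigned_score > significant_bits
        }
      }
      cases[[length(cases) + 1L]] <- rec
    }
  }
  cases <- if (length(cases)) do.call(rbind, cases)
           else data.frame(component_id = character(0),
                           vertex_1 = character(0), vertex_2 = character(0),
                           realigned_score = numeric(0),
                           significant = logical(0))
  audit_report(
    summary = list(n_clusters = length(ag$components),
                   n_clusters_missing_edges = length(clusters_missing),
                   n_implied_checked = n_checked,
                   n_implied_missing = nrow(cases)),
    cases = cases)
}

candidate_seq <- function(candidate_sets, vertex) {
  parts <- strsplit(vertex, "::", fixed = TRUE)[[1]]
  cs <- candidate_sets[[parts[1]]]
  if (is.null(cs)) return(NULL)
  i <- match(parts[2], cs$candidates$candidate_id)
  if (is.na(i)) return(NULL)
  cs$candidates$sequence[i]
}

#' Reciprocal-best audit of anchor matches
#'
#' For every anchor match (w, y), searches the candidate sequence of `w`
#' against the whole of the partner genome and `y` against the whole of
#' `w`'s genome (alignment + chaining), and flags the match when a
#' genome-wide best hit lies more than `max_distance` nt away from the
#' matched locus (a best hit on a different fragment always counts as a
#' violation). Per violation the overlap between the subsequence producing
#' the offending best hit and the originally matched subinterval is
#' recorded as a fraction of their combined length.
#'
#' @param matches a [find_anchor_matches()] table.
#' @param genomes named list of [genome()] objects (names = genome ids).
#' @param model a [score_model()].
#' @param max_distance genomic distance (nt) beyond which a best hit
#'   violates reciprocal-best status (default 10000).
#' @return an `audit_report` with `summary` (`n_matches`,
#'   `n_rbh_violations`, `median_violation_overlap`) and per-case records.
#' @export
audit_reciprocal_best <- function(matches, genomes, model = score_model(),
                                  max_distance = 10000L) {
  m <- matches
  cases <- list()
  if (nrow(m) > 0) {
    for (side in c("x", "y")) {
      qg <- m[[paste0("genome_", side)]]
      other <- if (side == "x") "y" else "x"
      tg <- m[[paste0("genome_", other)]]
      for (target_id in unique(tg)) {
        rows <- which(tg == target_id)
        target <- genomes[[target_id]]
        if (is.null(target)) stop("genome not supplied: ", target_id)
        queries <- vapply(rows, function(i) {
          gq <- genomes[[qg[i]]]
          if (is.null(gq)) stop("genome not supplied: ", qg[i])
          fragment_seq(gq, m[[paste0(side, "_frag")]][i],
                       m[[paste0(side, "_start")]][i],
                       m[[paste0(side, "_end")]][i])
        }, "")
        hits <- align_sequences(queries, target, model)
        for (ri in seq_along(rows)) {
          i <- rows[ri]
          h <- hits[hits$query == ri, , drop = FALSE]
          if (nrow(h) == 0) next
          ch <- chain_fragments(h)
          best <- ch[which.max(ch$score), , drop = FALSE]
          gap <- locus_gap(best$sfrag, best$sstart, best$send,
                           m[[paste0(other, "_frag")]][i],
                           m[[paste0(other, "_start")]][i],
                           m[[paste0(other, "_end")]][i])
          if (gap <= max_distance) next
          # overlap of the offending subsequence (on the query candidate)
          # with the originally matched subinterval, per combined length
          ms <- m[[paste0(side, "_sub_start")]][i] -
            m[[paste0(side, "_start")]][i]
          me <- m[[paste0(side, "_sub_end")]][i] -
            m[[paste0(side, "_start")]][i]
          ov <- max(0, min(best$qend, me) - max(best$qstart, ms))
          comb <- (best$qend - best$qstart) + (me - ms) - ov
          cases[[length(cases) + 1L]] <- data.frame(
            candidate = m[[paste0("candidate_", side)]][i],
            genome_searched = target_id,
            partner = m[[paste0("candidate_", other)]][i],
            best_frag = best$sfrag, best_start = best$sstart,
            best_end = best$send, best_score = best$score,
            distance = gap,
            overlap_fraction = if (comb > 0) ov / comb else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  cases <- if (length(cases)) do.call(rbind, cases)
           else data.frame(candidate = character(0),
                           genome_searched = character(0),
                           partner = character(0), best_frag = character(0),
                           best_start = integer(0), best_end = integer(0),
                           best_score = numeric(0), distance = numeric(0),
                           overlap_fraction = numeric(0))
  audit_report(
    summary = list(n_matches = nrow(m), n_rbh_violations = nrow(cases),
                   median_violation_overlap =
                     if (nrow(cases)) stats::median(cases$overlap_fraction,
                                                    na.rm = TRUE)
                     else NA_real_),
    cases = cases)
}

#' Write cluster and audit artifacts
#'
#' Cluster table as TSV; audit cases as TSV plus a JSON count summary.
#'
#' @param ag an [build_anchor_graph()] result.
#' @param reports named list of `audit_report`s.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_cluster_audit <- function(ag, reports, prefix) {
  paths <- character(0)
  p <- paste0(prefix, ".clusters.tsv")
  utils::write.table(anchor_clusters(ag), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  summaries <- list()
  for (nm in names(reports)) {
    rp <- reports[[nm]]
    p <- paste0(prefix, ".", nm, ".tsv")
    utils::write.table(rp$cases, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    summaries[[nm]] <- rp$summary
  }
  p <- paste0(prefix, ".audit.json")
  jsonlite::write_json(summaries, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
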