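# Synthetic genomes with exact ground truth: i.i.d. background, planted
# repeat families, and evolved copies (substitutions, single-nucleotide
# indels, and logged rearrangement events) together with an interval-level
# orthology map. Every generator is deterministic under its seed; replaying
# the logged events on the source reproduces the derived genome exactly.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_sequence <- function(seq, rate) {
  n <- nchar(seq)
  npos <- stats::rbinom(1, n, rate)
  if (npos == 0) return(seq)
  pos <- sort(sample.int(n, npos))
  chars <- strsplit(seq, "")[[1]]
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  chars[pos] <- vapply(chars[pos], function(b) {
    i <- sample.int(3, 1)
    substr(alt[[b]], i, i)
  }, "")
  paste(chars, collapse = "")
}

#' Repeat family specification for the genome simulator
#' @param n_families number of independent repeat families.
#' @param copy_number copies planted per family.
#' @param unit_length length of the repeat unit in nt.
#' @param divergence per-copy substitution rate relative to the family
#'   consensus (intra-family divergence).
#' @return a list of class `repeat_spec`.
#' @export
repeat_spec <- function(n_families = 1L, copy_number = 8L,
                        unit_length = 2000L, divergence = 0.05) {
  structure(list(n_families = as.integer(n_families),
                 copy_number = as.integer(copy_number),
                 unit_length = as.integer(unit_length),
                 divergence = divergence),
            class = "repeat_spec")
}

#' Simulate a genome with planted repeat families
#'
#' Background is i.i.d. uniform over `{A,C,G,T}` (so the idealised
#' per-position self-information `alpha = 2` bits is exact); repeat copies
#' are planted at random non-overlapping positions, each mutated away from
#' the family consensus at the stated divergence.
#'
#' @param length total genome length in nt (>= 1000 per fragment).
#' @param n_fragments number of fragments to split the genome into.
#' @param repeats a [repeat_spec()], or `NULL` for a repeat-free genome.
#' @param seed RNG seed; the run is reproducible byte-for-byte.
#' @param genome_id identifier.
#' @param gc GC fraction of the background (default 0.5, uniform).
#' @return list with `genome` (a [genome()]) and `truth` (a `truth_map`
#'   holding the repeat annotation and the seed).
#' @export
simulate_genome <- function(length, n_fragments = 1L, repeats = NULL,
                            seed = 1L, genome_id = "sim", gc = 0.5) {
  length <- as.integer(length); n_fragments <- as.integer(n_fragments)
  if (length < n_fragments * 1000L)
    stop("genome too short: need at least 1 kb per fragment")
  if (!is.null(repeats)) {
    rep_total <- repeats$n_families * repeats$copy_number *
      repeats$unit_length
    if (rep_total > 0.8 * length)
      stop("repeat content exceeds 80% of the genome length")
  }
  with_seed(seed, {
    frag_len <- rep(length %/% n_fragments, n_fragments)
    frag_len[n_fragments] <- frag_len[n_fragments] + length %% n_fragments
    frag_names <- sprintf("frag%02d", seq_len(n_fragments))
    frs <- stats::setNames(
      vapply(frag_len, random_dna, "", gc = gc), frag_names)

    rep_ann <- data.frame(family = character(0), copy = integer(0),
                          fragment = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
    if (!is.null(repeats) && repeats$n_families > 0) {
      occupied <- lapply(frag_names, function(x) matrix(0L, 0, 2))
      names(occupied) <- frag_names
      for (fam in seq_len(repeats$n_families)) {
        unit <- random_dna(repeats$unit_length, gc = gc)
        for (cp in seq_len(repeats$copy_number)) {
          placed <- FALSE
          for (try in 1:1000) {
            fi <- sample.int(n_fragments, 1)
            fl <- frag_len[fi]
            if (fl < repeats$unit_length + 2L) next
            s <- sample.int(fl - repeats$unit_length, 1) # 1-based start
            occ <- occupied[[fi]]
            if (nrow(occ) > 0 &&
                any(occ[, 1] < s + repeats$unit_length & occ[, 2] > s))
              next
            copy_seq <- mutate_sequence(unit, repeats$divergence)
            substr(frs[[fi]], s, s + repeats$unit_length - 1L) <- copy_seq
            occupied[[fi]] <- rbind(occ, c(s, s + repeats$unit_length))
            rep_ann <- rbind(rep_ann, data.frame(
              family = sprintf("fam%02d", fam), copy = cp,
              fragment = frag_names[fi], start = s - 1L,
              end = s - 1L + repeats$unit_length,
              stringsAsFactors = FALSE))
            placed <- TRUE
            break
          }
          if (!placed)
            stop("could not place repeat copy without overlap; ",
                 "reduce repeat content")
        }
      }
    }
    g <- genome(frs, genome_id = genome_id)
    truth <- structure(list(kind = "simulated", genome_id = genome_id,
                            repeats = rep_ann, seed = seed),
                       class = "truth_map")
    list(genome = g, truth = truth)
  })
}

#' Rearrangement event constructors
#'
#' Events carry 0-based half-open coordinates interpreted on the genome
#' state at the moment the event is applied (events are applied in list
#' order, after point mutations and indels). For translocations and
#' duplications the destination position refers to the state after the
#' source span was removed (translocation) or with the span still in place
#' (duplication).
#'
#' @param fragment,start,end source span of the event.
#' @param dest_fragment,dest_pos insertion point (translocation,
#'   duplication).
#' @return a list of class `rearrangement`.
#' @name rearrangements
NULL

#' @rdname rearrangements
#' @export
ev_inversion <- function(fragment, start, end) {
  structure(list(type = "inversion", fragment = fragment,
                 start = as.integer(start), end = as.integer(end)),
            class = "rearrangement")
}

#' @rdname rearrangements
#' @export
ev_translocation <- function(fragment, start, end, dest_fragment,
                             dest_pos) {
  structure(list(type = "translocation", fragment = fragment,
                 start = as.integer(start), end = as.integer(end),
                 dest_fragment = dest_fragment,
                 dest_pos = as.integer(dest_pos)),
            class = "rearrangement")
}

#' @rdname rearrangements
#' @export
ev_duplication <- function(fragment, start, end, dest_fragment, dest_pos) {
  structure(list(type = "duplication", fragment = fragment,
                 start = as.integer(start), end = as.integer(end),
                 dest_fragment = dest_fragment,
                 dest_pos = as.integer(dest_pos)),
            class = "rearrangement")
}

#' @rdname rearrangements
#' @export
ev_deletion <- function(fragment, start, end) {
  structure(list(type = "deletion", fragment = fragment,
                 start = as.integer(start), end = as.integer(end)),
            class = "rearrangement")
}

# ---- internal block bookkeeping -------------------------------------------
# blocks: data.frame src_frag, src_start, src_end, der_frag, der_start,
# der_end, strand, duplicate. All coords 0-based half-open; src/der lengths
# equal per block.

block_clip <- function(b, a, z) {
  # clip one block row to derived window [a, z); returns clipped row
  ds <- b$der_start; de <- b$der_end
  na <- max(ds, a); nz <- min(de, z)
  off_l <- na - ds; off_r <- de - nz
  if (b$strand == "+") {
    b$src_start <- b$src_start + off_l
    b$src_end <- b$src_end - off_r
  } else {
    b$src_start <- b$src_start + off_r
    b$src_end <- b$src_end - off_l
  }
  b$der_start <- na; b$der_end <- nz
  b
}

# split blocks of one fragment at derived window [a, z); returns
# list(inside = blocks within window with der coords relative to a,
#      outside = remaining blocks with the window removed and downstream
#                der coords shifted by -(z - a))
blocks_extract <- function(blocks, frag, a, z) {
  w <- z - a
  sel <- blocks$der_frag == frag
  other <- blocks[!sel, , drop = FALSE]
  fb <- blocks[sel, , drop = FALSE]
  inside <- list(); outside <- list()
  for (i in seq_len(nrow(fb))) {
    b <- fb[i, , drop = FALSE]
    if (b$der_end <= a) { outside[[length(outside) + 1L]] <- b; next }
    if (b$der_start >= z) {
      b$der_start <- b$der_start - w; b$der_end <- b$der_end - w
      outside[[length(outside) + 1L]] <- b; next
    }
    if (b$der_start < a) {
      left <- block_clip(b, b$der_start, a)
      outside[[length(outside) + 1L]] <- left
    }
    mid <- block_clip(b, a, z)
    mid$der_start <- mid$der_start - a; mid$der_end <- mid$der_end - a
    inside[[length(inside) + 1L]] <- mid
    if (b$der_end > z) {
      right <- block_clip(b, z, b$der_end)
      right$der_start <- right$der_start - w
      right$der_end <- right$der_end - w
      outside[[length(outside) + 1L]] <- right
    }
  }
  list(inside = do.call(rbind, c(inside, list(NULL))),
       outside = rbind(other, do.call(rbind, c(outside, list(NULL)))))
}

blocks_insert <- function(blocks, frag, pos, w, new_blocks) {
  # split any block spanning the insertion point
  span <- which(blocks$der_frag == frag & blocks$der_start < pos &
                  blocks$der_end > pos)
  if (length(span) > 0) {
    left <- do.call(rbind, lapply(span, function(i)
      block_clip(blocks[i, , drop = FALSE], blocks$der_start[i], pos)))
    right <- do.call(rbind, lapply(span, function(i)
      block_clip(blocks[i, , drop = FALSE], pos, blocks$der_end[i])))
    blocks <- rbind(blocks[-span, , drop = FALSE], left, right)
  }
  sel <- blocks$der_frag == frag & blocks$der_start >= pos
  blocks$der_start[sel] <- blocks$der_start[sel] + w
  blocks$der_end[sel] <- blocks$der_end[sel] + w
  if (!is.null(new_blocks) && nrow(new_blocks) > 0) {
    new_blocks$der_frag <- frag
    new_blocks$der_start <- new_blocks$der_start + pos
    new_blocks$der_end <- new_blocks$der_end + pos
    blocks <- rbind(blocks, new_blocks)
  }
  blocks[order(blocks$der_frag, blocks$der_start), , drop = FALSE]
}

str_excise <- function(s, a, z) {
  paste0(substr(s, 1L, a), substr(s, z + 1L, nchar(s)))
}

str_insert <- function(s, pos, piece) {
  paste0(substr(s, 1L, pos), piece, substr(s, pos + 1L, nchar(s)))
}

apply_event <- function(frs, blocks, ev) {
  f <- ev$fragment
  if (!f %in% names(frs)) stop("event on unknown fragment: ", f)
  len <- nchar(frs[[f]])
  if (ev$start < 0L || ev$end > len || ev$start >= ev$end)
    stop("event coordinates out of bounds on fragment ", f)
  span_seq <- substr(frs[[f]], ev$start + 1L, ev$end)
  w <- ev$end - ev$start
  if (ev$type == "inversion") {
    ex <- blocks_extract(blocks, f, ev$start, ev$end)
    inb <- ex$inside
    if (!is.null(inb) && nrow(inb) > 0) {
      ns <- w - inb$der_end; ne <- w - inb$der_start
      inb$der_start <- ns; inb$der_end <- ne
      inb$strand <- ifelse(inb$strand == "+", "-", "+")
    }
    frs[[f]] <- str_excise(frs[[f]], ev$start, ev$end)
    frs[[f]] <- str_insert(frs[[f]], ev$start,
                           as.character(cpp_revcomp(span_seq)))
    blocks <- blocks_insert(ex$outside, f, ev$start, w, inb)
  } else if (ev$type == "deletion") {
    ex <- blocks_extract(blocks, f, ev$start, ev$end)
    frs[[f]] <- str_excise(frs[[f]], ev$start, ev$end)
    blocks <- ex$outside
  } else if (ev$type == "translocation") {
    ex <- blocks_extract(blocks, f, ev$start, ev$end)
    frs[[f]] <- str_excise(frs[[f]], ev$start, ev$end)
    df <- ev$dest_fragment
    if (!df %in% names(frs)) stop("unknown destination fragment: ", df)
    if (ev$dest_pos < 0L || ev$dest_pos > nchar(frs[[df]]))
      stop("destination position out of bounds on fragment ", df)
    frs[[df]] <- str_insert(frs[[df]], ev$dest_pos, span_seq)
    blocks <- blocks_insert(ex$outside, df, ev$dest_pos, w, ex$inside)
  } else if (ev$type == "duplication") {
    ex <- blocks_extract(blocks, f, ev$start, ev$end)
    copy <- ex$inside
    if (!is.null(copy) && nrow(copy) > 0) copy$duplicate <- TRUE
    # re-insert originals where they were
    blocks <- blocks_insert(ex$outside, f, ev$start, w, ex$inside)
    df <- ev$dest_fragment
    if (!df %in% names(frs)) stop("unknown destination fragment: ", df)
    if (ev$dest_pos < 0L || ev$dest_pos > nchar(frs[[df]]))
      stop("destination position out of bounds on fragment ", df)
    frs[[df]] <- str_insert(frs[[df]], ev$dest_pos, span_seq)
    blocks <- blocks_insert(blocks, df, ev$dest_pos, w, copy)
  } else stop("unknown event type: ", ev$type)
  list(frs = frs, blocks = blocks)
}

# apply logged substitutions/indels/events to a source genome; shared by
# evolve_genome() and replay_truth()
apply_logs <- function(g, subs, indels, events, derived_id) {
  frs <- g$fragments
  # substitutions: no coordinate change
  if (nrow(subs) > 0) {
    for (f in unique(subs$fragment)) {
      d <- subs[subs$fragment == f, , drop = FALSE]
      chars <- strsplit(frs[[f]], "")[[1]]
      chars[d$pos + 1L] <- d$to
      frs[[f]] <- paste(chars, collapse = "")
    }
  }
  # identity blocks, then indels (single-nucleotide)
  blocks <- list()
  for (f in names(frs)) {
    ind <- indels[indels$fragment == f, , drop = FALSE]
    ind <- ind[order(ind$pos), , drop = FALSE]
    src_len <- nchar(frs[[f]])
    pieces <- character(0)
    cur_src <- 0L; cur_der <- 0L
    emit <- function(upto) {
      if (upto > cur_src) {
        pieces <<- c(pieces, substr(frs[[f]], cur_src + 1L, upto))
        blocks[[length(blocks) + 1L]] <<- data.frame(
          src_frag = f, src_start = cur_src, src_end = upto,
          der_frag = f, der_start = cur_der,
          der_end = cur_der + (upto - cur_src), strand = "+",
          duplicate = FALSE, stringsAsFactors = FALSE)
        cur_der <<- cur_der + (upto - cur_src)
        cur_src <<- upto
      }
    }
    for (i in seq_len(nrow(ind))) {
      p <- ind$pos[i]
      if (ind$type[i] == "del") {
        emit(p)
        cur_src <- cur_src + 1L # skip the deleted base
      } else {
        emit(p)
        pieces <- c(pieces, ind$base[i])
        cur_der <- cur_der + 1L
      }
    }
    emit(src_len)
    frs[[f]] <- paste(pieces, collapse = "")
  }
  blocks <- do.call(rbind, c(blocks, list(NULL)))
  for (ev in events) {
    st <- apply_event(frs, blocks, ev)
    frs <- st$frs; blocks <- st$blocks
  }
  blocks <- blocks[order(blocks$der_frag, blocks$der_start), , drop = FALSE]
  rownames(blocks) <- NULL
  list(genome = genome(frs, genome_id = derived_id), blocks = blocks)
}

#' Evolve a genome into a derived copy with exact orthology truth
#'
#' Applies point substitutions, single-nucleotide indels, and then the
#' given rearrangement events, and returns the derived genome together
#' with the exact interval-level orthology map: blocks pairing source and
#' derived intervals, with strand flipped across inversions, and
#' duplication copies flagged (excluded from the unique-orthology subset).
#' The mutation and event logs are stored in the truth map so that
#' [replay_truth()] reproduces the derived genome byte-for-byte.
#'
#' @param g the source [genome()].
#' @param substitution_rate,indel_rate per-site rates in `[0, 0.3]`.
#' @param events list of [rearrangements] applied in order after the point
#'   mutations; event source spans must not overlap.
#' @param seed RNG seed.
#' @param genome_id id of the derived genome.
#' @param source_truth optional truth from [simulate_genome()]; its repeat
#'   annotation is carried over.
#' @return list with `genome` and `truth`; `truth$blocks` is the orthology
#'   map, `truth$subs`/`truth$indels`/`truth$events` the logs.
#' @export
evolve_genome <- function(g, substitution_rate = 0, indel_rate = 0,
                          events = list(), seed = 1L,
                          genome_id = paste0(g$genome_id, "_derived"),
                          source_truth = NULL) {
  stopifnot(inherits(g, "genome"))
  if (substitution_rate < 0 || substitution_rate > 0.3 ||
      indel_rate < 0 || indel_rate > 0.3)
    stop("rates must lie in [0, 0.3]")
  if (length(events) > 0) {
    for (ev in events)
      if (!inherits(ev, "rearrangement")) stop("events must be rearrangements")
    for (a in seq_along(events)) for (b in seq_len(a - 1L)) {
      ea <- events[[a]]; eb <- events[[b]]
      if (identical(ea$fragment, eb$fragment) &&
          ea$start < eb$end && eb$start < ea$end)
        stop("overlapping event coordinates: events ", b, " and ", a)
    }
  }
  with_seed(seed, {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    subs <- list(); indels <- list()
    for (f in names(g$fragments)) {
      n <- nchar(g$fragments[[f]])
      ns <- stats::rbinom(1, n, substitution_rate)
      if (ns > 0) {
        pos <- sort(sample.int(n, ns)) - 1L
        from <- substring(g$fragments[[f]], pos + 1L, pos + 1L)
        keep <- from %in% c("A", "C", "G", "T")
        pos <- pos[keep]; from <- from[keep]
        to <- vapply(from, function(b) sample(alt[[b]], 1), "")
        subs[[f]] <- data.frame(fragment = f, pos = pos, from = from,
                                to = unname(to), stringsAsFactors = FALSE)
      }
      ni <- stats::rbinom(1, n, indel_rate)
      if (ni > 0) {
        pos <- sort(sample.int(n, ni)) - 1L
        type <- sample(c("ins", "del"), ni, replace = TRUE)
        base <- ifelse(type == "ins",
                       sample(c("A", "C", "G", "T"), ni, replace = TRUE),
                       NA_character_)
        indels[[f]] <- data.frame(fragment = f, pos = pos, type = type,
                                  base = base, stringsAsFactors = FALSE)
      }
    }
    subs <- do.call(rbind, c(subs, list(NULL)))
    indels <- do.call(rbind, c(indels, list(NULL)))
    if (is.null(subs))
      subs <- data.frame(fragment = character(0), pos = integer(0),
                         from = character(0), to = character(0))
    if (is.null(indels))
      indels <- data.frame(fragment = character(0), pos = integer(0),
                           type = character(0), base = character(0))
    res <- apply_logs(g, subs, indels, events, genome_id)
    blocks <- res$blocks
    # realized identity per block
    if (nrow(blocks) > 0) {
      blocks$identity <- vapply(seq_len(nrow(blocks)), function(i) {
        sel <- subs$fragment == blocks$src_frag[i] &
          subs$pos >= blocks$src_start[i] & subs$pos < blocks$src_end[i]
        1 - sum(sel) / (blocks$src_end[i] - blocks$src_start[i])
      }, 0)
    } else blocks$identity <- numeric(0)
    truth <- structure(
      list(kind = "evolved", source_id = g$genome_id,
           derived_id = genome_id,
           blocks = blocks, subs = subs, indels = indels, events = events,
           repeats = if (!is.null(source_truth)) source_truth$repeats
                     else NULL,
           seed = seed),
      class = "truth_map")
    list(genome = res$genome, truth = truth)
  })
}

#' Replay a truth map's logs against the source genome
#'
#' Applies the logged substitutions, indels and rearrangement events to the
#' source genome. The result must equal the derived genome byte-for-byte;
#' this is the consistency guarantee of the truth map.
#'
#' @param g the source [genome()].
#' @param truth a truth map from [evolve_genome()].
#' @return the reconstructed derived [genome()].
#' @export
replay_truth <- function(g, truth) {
  stopifnot(inherits(truth, "truth_map"))
  if (!identical(truth$kind, "evolved"))
    stop("only evolved truth maps can be replayed")
  if (!identical(g$genome_id, truth$source_id))
    stop("genome id does not match the truth map's source")
  apply_logs(g, truth$subs, truth$indels, truth$events,
             truth$derived_id)$genome
}

# map a source interval [s, e) through one block row; returns derived
# interval (list ds, de) of the clipped part plus the clipped source range
map_through_block <- function(b, s, e) {
  cs <- max(s, b$src_start); ce <- min(e, b$src_end)
  if (cs >= ce) return(NULL)
  if (b$strand == "+") {
    ds <- b$der_start + (cs - b$src_start)
    de <- b$der_start + (ce - b$src_start)
  } else {
    ds <- b$der_start + (b$src_end - ce)
    de <- b$der_start + (b$src_end - cs)
  }
  list(cs = cs, ce = ce, ds = ds, de = de)
}

#' Score anchor matches against a truth map
#'
#' A match is counted true when its matched subintervals are consistent
#' with a (non-duplicate) truth block: the source-side subinterval
#' overlaps the block by at least half of its length, the partner
#' fragment and relative orientation agree with the block, and the
#' observed partner subinterval agrees with the truth-mapped image of the
#' source subinterval within `slack` nt at both ends. Recall is the
#' fraction of truth blocks that are at least `min_len` nt long and lie in
#' unique (repeat-free) source regions which are hit by at least one true
#' match; precision is the fraction of matches that are true. An empty
#' match set yields recall 0 and (vacuous) precision 1 with a warning.
#'
#' @param matches a [find_anchor_matches()] table for the source/derived
#'   genome pair of `truth`.
#' @param truth a truth map from [evolve_genome()].
#' @param slack endpoint tolerance in nt (default 50).
#' @param min_len minimal truth-block length entering recall (default 500,
#'   the candidate window length).
#' @return list with `precision`, `recall`, `n_true`, `n_matches`, and a
#'   per-match `details` data.frame.
#' @export
evaluate_anchors <- function(matches, truth, slack = 50L, min_len = 500L) {
  stopifnot(inherits(truth, "truth_map"))
  if (!identical(truth$kind, "evolved"))
    stop("evaluation needs an evolved truth map")
  blocks <- truth$blocks[!truth$blocks$duplicate, , drop = FALSE]

  eligible <- blocks[blocks$src_end - blocks$src_start >= min_len, ,
                     drop = FALSE]
  if (!is.null(truth$repeats) && nrow(truth$repeats) > 0 &&
      nrow(eligible) > 0) {
    keep <- vapply(seq_len(nrow(eligible)), function(i) {
      r <- truth$repeats
      !any(r$fragment == eligible$src_frag[i] &
             r$start < eligible$src_end[i] & r$end > eligible$src_start[i])
    }, TRUE)
    eligible <- eligible[keep, , drop = FALSE]
  }

  if (nrow(matches) == 0) {
    warning("empty match set: precision is vacuous")
    return(list(precision = 1, recall = 0, n_true = 0L, n_matches = 0L,
                details = data.frame()))
  }
  ids <- c(matches$genome_x[1], matches$genome_y[1])
  if (identical(ids, c(truth$derived_id, truth$source_id))) {
    matches <- mirror_matches(matches)
  } else if (!identical(ids, c(truth$source_id, truth$derived_id))) {
    stop("matches and truth refer to different genome pairs")
  }

  details <- matches[, c("candidate_x", "candidate_y", "strand", "score")]
  details$true <- FALSE
  hits_per_block <- integer(nrow(eligible))
  for (i in seq_len(nrow(matches))) {
    xs <- matches$x_sub_start[i]; xe <- matches$x_sub_end[i]
    xf <- matches$x_frag[i]
    cand <- blocks[blocks$src_frag == xf & blocks$src_start < xe &
                     blocks$src_end > xs, , drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- pmin(cand$src_end, xe) - pmax(cand$src_start, xs)
    b <- cand[which.max(ov), , drop = FALSE]
    if (max(ov) < 0.5 * (xe - xs)) next
    if (!identical(matches$y_frag[i], b$der_frag)) next
    if (!identical(matches$strand[i], b$strand)) next
    mp <- map_through_block(b, xs, xe)
    if (is.null(mp)) next
    # expected observed-partner subinterval for the clipped source part,
    # assuming the alignment is colinear within the match
    ys <- matches$y_sub_start[i]; ye <- matches$y_sub_end[i]
    if (matches$strand[i] == "+") {
      obs_s <- ys + (mp$cs - xs); obs_e <- ys + (mp$ce - xs)
    } else {
      obs_s <- ye - (mp$ce - xs); obs_e <- ye - (mp$cs - xs)
    }
    if (abs(obs_s - mp$ds) <= slack && abs(obs_e - mp$de) <= slack) {
      details$true[i] <- TRUE
      if (nrow(eligible) > 0) {
        hit <- eligible$src_frag == xf & eligible$src_start < xe &
          eligible$src_end > xs
        hits_per_block[hit] <- hits_per_block[hit] + 1L
      }
    }
  }
  precision <- mean(details$true)
  recall <- if (nrow(eligible) > 0) mean(hits_per_block > 0) else NA_real_
  list(precision = precision, recall = recall,
       n_true = sum(details$true), n_matches = nrow(matches),
       details = details)
}

#' Write simulator outputs to disk
#'
#' FASTA for the genome, TSV for the orthology blocks and repeat
#' annotation, JSON for the event log and seeds.
#'
#' @param sim a `list(genome, truth)` from [simulate_genome()] or
#'   [evolve_genome()].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- character(0)
  p <- paste0(prefix, ".fa")
  write_genome_fasta(sim$genome, p)
  paths <- c(paths, p)
  tr <- sim$truth
  if (!is.null(tr$blocks)) {
    p <- paste0(prefix, ".blocks.tsv")
    utils::write.table(tr$blocks, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(tr$repeats) && nrow(tr$repeats) > 0) {
    p <- paste0(prefix, ".repeats.tsv")
    utils::write.table(tr$repeats, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, ".events.json")
  jsonlite::write_json(
    list(kind = tr$kind, seed = tr$seed,
         events = lapply(tr$events, function(e) unclass(e))),
    p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
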