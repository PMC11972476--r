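#' Aggregated window rareness
#'
#' For windows of length `window` starting every `step` nt on each fragment,
#' sums the per-position k-mer occurrence counts across the window:
#' `f = sum_{j=0}^{window-k} h_k(i+j)`. Low values mark windows composed of
#' genomically rare k-mers, i.e. candidate anchor regions. Windows that
#' would extend past a fragment end are not emitted; windows containing a
#' poison (N-bearing) position get `f = NA`.
#'
#' @param track a [count_kmers()] result.
#' @param window window length `l` in nt (default 500).
#' @param step window start spacing in nt (default 250).
#' @return data.frame with columns `fragment`, `start`, `end`, `f`, plus
#'   attributes `k`, `mismatches`, `genome_id`.
#' @export
window_rareness <- function(track, window = 500L, step = 250L) {
  stopifnot(inherits(track, "kmer_count_track"))
  window <- as.integer(window); step <- as.integer(step)
  if (window < track$k) stop("window length must be >= k")
  if (step < 1L) stop("step must be >= 1")
  nterms <- window - track$k + 1L

  res <- lapply(names(track$counts), function(nm) {
    v <- track$counts[[nm]]
    flen <- length(v) + track$k - 1L
    if (flen < window) return(NULL)
    starts <- seq.int(0L, flen - window, by = step)
    # f over count positions [start, start + nterms); zero-padded cumsums
    # so 0-based window starts index cleanly
    cs <- c(0, cumsum(ifelse(is.na(v), 0, as.numeric(v))))
    csna <- c(0, cumsum(is.na(v)))
    f <- cs[starts + nterms + 1L] - cs[starts + 1L]
    npois <- csna[starts + nterms + 1L] - csna[starts + 1L]
    f[npois > 0] <- NA_real_
    data.frame(fragment = nm, start = starts, end = starts + window, f = f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(fragment = character(0), start = integer(0),
                      end = integer(0), f = numeric(0))
  attr(out, "k") <- track$k
  attr(out, "mismatches") <- track$mismatches
  attr(out, "genome_id") <- track$genome_id
  out
}

#' Keep the rarest windows by nearest-rank percentile
#'
#' Keeps windows whose rareness `f` is at most the p-th nearest-rank
#' percentile of the finite `f` values; ties at the cutoff are all kept.
#' Poison windows are excluded before ranking.
#'
#' @param windows a [window_rareness()] data.frame.
#' @param p percentile in (0, 100] (default 15).
#' @return the kept subset, same columns, with attribute `cutoff`.
#' @export
select_percentile <- function(windows, p = 15) {
  if (!is.numeric(p) || p <= 0 || p > 100) stop("p must be in (0, 100]")
  fin <- windows[!is.na(windows$f), , drop = FALSE]
  if (nrow(fin) == 0) {
    warning("no finite-rareness windows; empty selection")
    out <- fin
    attr(out, "cutoff") <- NA_real_
    return(out)
  }
  fs <- sort(fin$f)
  cutoff <- fs[ceiling(p / 100 * length(fs))]
  out <- fin[fin$f <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Merge new candidate windows into an existing candidate set
#'
#' Each new window is compared against the current intervals of its
#' fragment: if it overlaps an existing interval by at least 30 percent of
#' the existing interval's length, that interval is extended to the union;
#' if it overlaps by less, the window is discarded; windows overlapping
#' nothing are appended. Windows are processed in fragment order, then by
#' start position, so the first profile's windows coalesce into runs and
#' later profiles refine them. Merged intervals may grow beyond the window
#' length without bound.
#'
#' @param existing data.frame with `fragment`, `start`, `end`, `profiles`
#'   (may have zero rows: the first profile seeds the set).
#' @param new_windows data.frame with `fragment`, `start`, `end`.
#' @param overlap_frac minimum overlap as a fraction of the existing
#'   interval's length (default 0.30).
#' @param profile_label label recorded for windows of this round.
#' @return updated `existing` data.frame.
#' @export
merge_candidates <- function(existing, new_windows, overlap_frac = 0.30,
                             profile_label = NA_character_) {
  if (is.null(existing) || nrow(existing) == 0)
    existing <- data.frame(fragment = character(0), start = integer(0),
                           end = integer(0), profiles = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(new_windows) == 0) return(existing)
  nw <- new_windows[order(new_windows$fragment, new_windows$start), ,
                    drop = FALSE]
  frag <- existing$fragment; lo <- existing$start; hi <- existing$end
  prof <- existing$profiles
  for (i in seq_len(nrow(nw))) {
    f <- nw$fragment[i]; s <- nw$start[i]; e <- nw$end[i]
    idx <- which(frag == f & lo < e & hi > s)
    if (length(idx) == 0) {
      frag <- c(frag, f); lo <- c(lo, s); hi <- c(hi, e)
      prof <- c(prof, profile_label)
      next
    }
    ov <- pmin(hi[idx], e) - pmax(lo[idx], s)
    fr <- ov / (hi[idx] - lo[idx])
    j <- idx[which.max(fr)]
    if (max(fr) >= overlap_frac) {
      lo[j] <- min(lo[j], s)
      hi[j] <- max(hi[j], e)
      if (!is.na(profile_label) && !grepl(profile_label, prof[j], fixed = TRUE))
        prof[j] <- paste(prof[j], profile_label, sep = ",")
    } # else: discarded
  }
  out <- data.frame(fragment = frag, start = lo, end = hi, profiles = prof,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fragment, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default k-mer profiles
#'
#' The default candidate search combines three profiles applied in order:
#' exact 13-mers, exact 15-mers, and 21-mers allowing up to two mismatches,
#' each filtered at the 15th rareness percentile.
#'
#' @return list of profile lists with elements `k`, `mismatches`, `p`.
#' @export
default_profiles <- function() {
  list(list(k = 13L, mismatches = 0L, p = 15),
       list(k = 15L, mismatches = 0L, p = 15),
       list(k = 21L, mismatches = 2L, p = 15))
}

#' Build the anchor-candidate set of a genome
#'
#' Runs k-mer counting, window rareness, percentile selection and merging
#' for each profile in order, feeding [merge_candidates()] cumulatively.
#' Deterministic for a fixed genome and configuration.
#'
#' @param g a [genome()].
#' @param profiles list of profiles as in [default_profiles()].
#' @param window,step window geometry (defaults 500 / 250).
#' @param overlap_frac merge rule fraction (default 0.30).
#' @return a `candidate_set`: list with `genome_id` and `candidates`, a
#'   data.frame with `candidate_id`, `fragment`, `start`, `end`, `profiles`.
#' @export
build_candidates <- function(g, profiles = default_profiles(),
                             window = 500L, step = 250L,
                             overlap_frac = 0.30) {
  stopifnot(inherits(g, "genome"))
  cand <- NULL
  if (max(nchar(g$fragments)) < window) {
    warning("genome '", g$genome_id, "': no fragment fits a full window (",
            window, " nt); empty candidate set")
    cand <- data.frame(fragment = character(0), start = integer(0),
                       end = integer(0), profiles = character(0))
  } else {
    for (pr in profiles) {
      lab <- sprintf("k%d_m%d", pr$k, pr$mismatches)
      track <- count_kmers(g, pr$k, pr$mismatches)
      w <- window_rareness(track, window = window, step = step)
      kept <- select_percentile(w, p = pr$p)
      cand <- merge_candidates(cand, kept, overlap_frac = overlap_frac,
                               profile_label = lab)
    }
  }
  if (is.null(cand))
    cand <- data.frame(fragment = character(0), start = integer(0),
                       end = integer(0), profiles = character(0))
  if (nrow(cand) > 0)
    cand$candidate_id <- sprintf("%s_c%04d", g$genome_id, seq_len(nrow(cand)))
  else cand$candidate_id <- character(0)
  cand <- cand[, c("candidate_id", "fragment", "start", "end", "profiles")]
  structure(list(genome_id = g$genome_id, candidates = cand),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set '%s'>: %d candidate(s)\n",
              x$genome_id, nrow(x$candidates)))
  invisible(x)
}

#' Write a candidate set as BED6 plus a TSV sidecar
#'
#' BED score holds the interval rank as a per-mille value for quick genome
#' browser inspection; strand is always `+` (candidates are strandless).
#'
#' @param cs a [build_candidates()] result (annotated or not).
#' @param prefix output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @param header optional `#`-prefixed header line(s) for the TSV.
#' @return named character vector of the written paths, invisibly.
#' @export
write_candidates <- function(cs, prefix, header = NULL) {
  stopifnot(inherits(cs, "candidate_set"))
  df <- cs$candidates
  bed <- data.frame(df$fragment, df$start, df$end, df$candidate_id,
                    score = if (nrow(df)) as.integer(
                      rank(df$start, ties.method = "first") /
                        max(1L, nrow(df)) * 1000) else integer(0),
                    strand = rep("+", nrow(df)))
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  con <- file(tsv_path, "w")
  if (!is.null(header)) writeLines(header, con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  close(con)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
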