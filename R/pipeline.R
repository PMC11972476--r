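#' Pipeline configuration
#'
#' Bundles every parameter that influences candidate selection, uniqueness
#' scores or match thresholds. Defaults follow the method's published
#' settings: profiles 13/0mm, 15/0mm, 21/2mm at the 15th percentile,
#' window 500 nt / step 250 nt, 30% merge rule, word size 11, E = 0.001,
#' 40-bit floor, 10 kb proximity limit. The configuration hash guards
#' against mixing uniqueness scores computed under different scoring
#' models.
#'
#' @param profiles list of k-mer profiles (see [default_profiles()]).
#' @param window,step candidate window geometry in nt.
#' @param overlap_frac window merge rule fraction.
#' @param model a [score_model()].
#' @param self_overlap_tol origin-overlap tolerance in [self_uniqueness()].
#' @param floor minimum uniqueness score in bits.
#' @param proximity multi-partner proximity limit in nt.
#' @param disjoint_overlap disjointness bound for close multiple partners.
#' @param seed seed recorded in output headers.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(profiles = default_profiles(), window = 500L,
                            step = 250L, overlap_frac = 0.30,
                            model = score_model(), self_overlap_tol = 0.25,
                            floor = 40, proximity = 10000L,
                            disjoint_overlap = 0.2, seed = 1L) {
  structure(list(profiles = profiles, window = as.integer(window),
                 step = as.integer(step), overlap_frac = overlap_frac,
                 model = model, self_overlap_tol = self_overlap_tol,
                 floor = floor, proximity = as.integer(proximity),
                 disjoint_overlap = disjoint_overlap,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Configuration hash
#'
#' 32-bit FNV-1a hash over the serialised configuration (seed excluded:
#' the pipeline stages are deterministic, the seed only tags simulator
#' provenance). Tracks produced under different hashes are refused by
#' [match_anchor_tracks()] because their `s0` scales are not comparable.
#'
#' @param config a [pipeline_config()].
#' @return character scalar, 8 hex digits.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- unclass(config)
  cfg$seed <- NULL
  txt <- paste(deparse(cfg), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (bytes are < 256), keeping h a double
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)
    # multiply by the FNV prime 16777619 modulo 2^32 in 16-bit halves so
    # every intermediate stays exactly representable in a double
    h16 <- h %/% 65536
    h <- ((h %% 65536) * 16777619 +
            ((h16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

output_header <- function(config) {
  sprintf("# syntenyanchors %s\tconfig=%s\tseed=%d",
          as.character(utils::packageVersion("syntenyanchors")),
          config_hash(config), config$seed)
}

#' Precompute the anchor-candidate track of one genome
#'
#' Stage one of the pipeline: candidate windows from k-mer rareness,
#' within-genome uniqueness scores, and the on-disk annotation track
#' (BED6 + TSV, headed by version, configuration hash and seed). The
#' track is all later stages need from this genome besides its sequence;
#' re-running over the same inputs reproduces byte-identical files.
#'
#' @param fasta path to the genome FASTA, or a [genome()] object.
#' @param config a [pipeline_config()].
#' @param out_prefix path prefix for the track files, or `NULL` to skip
#'   writing.
#' @param genome_id optional id override.
#' @return the annotated `candidate_set`, invisibly when writing.
#' @export
precompute_anchor_track <- function(fasta, config = pipeline_config(),
                                    out_prefix = NULL, genome_id = NULL) {
  g <- if (inherits(fasta, "genome")) fasta
       else read_genome_fasta(fasta, genome_id = genome_id)
  cs <- build_candidates(g, profiles = config$profiles,
                         window = config$window, step = config$step,
                         overlap_frac = config$overlap_frac)
  cs <- annotate_uniqueness(g, cs, model = config$model,
                            overlap_tol = config$self_overlap_tol,
                            floor = config$floor)
  cs$config_hash <- config_hash(config)
  if (!is.null(out_prefix)) {
    write_candidates(cs, out_prefix, header = output_header(config))
    return(invisible(cs))
  }
  cs
}

#' Read back a precomputed anchor track
#'
#' Restores the annotated candidate set from `<prefix>.tsv` written by
#' [precompute_anchor_track()]; the genome FASTA is needed only by stages
#' that realign against the full genome.
#'
#' @param prefix the path prefix used when writing.
#' @param genome_id genome id of the track.
#' @return a `candidate_set` with annotation columns and the recorded
#'   configuration hash.
#' @export
read_anchor_track <- function(prefix, genome_id) {
  path <- paste0(prefix, ".tsv")
  first <- readLines(path, n = 1)
  hash <- sub(".*config=([0-9a-f]+).*", "\\1", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  structure(list(genome_id = genome_id, candidates = df,
                 config_hash = if (grepl("^[0-9a-f]{8}$", hash)) hash
                               else NA_character_),
            class = "candidate_set")
}

#' Match the anchor candidates of two genomes
#'
#' Stage two: cross-genome comparison of two precomputed tracks. Tracks
#' must carry the same configuration hash; mixing `s0` values computed
#' under different scoring models is refused rather than warned about.
#'
#' @param track_x,track_y annotated candidate sets from
#'   [precompute_anchor_track()].
#' @param config a [pipeline_config()].
#' @param out_prefix path prefix for the match table and MCScanX-style
#'   exports, or `NULL` to skip writing.
#' @return the match table (see [find_anchor_matches()]).
#' @export
match_anchor_tracks <- function(track_x, track_y,
                                config = pipeline_config(),
                                out_prefix = NULL) {
  hx <- track_x$config_hash; hy <- track_y$config_hash
  if (!is.null(hx) && !is.null(hy) && !is.na(hx) && !is.na(hy) &&
      !identical(hx, hy))
    stop("configuration hash mismatch between tracks (", hx, " vs ", hy,
         "); uniqueness scores are not comparable")
  m <- find_anchor_matches(track_x, track_y, model = config$model,
                           proximity = config$proximity,
                           disjoint_overlap = config$disjoint_overlap)
  if (!is.null(out_prefix)) {
    write_match_table(m, paste0(out_prefix, ".matches.tsv"),
                      header = output_header(config))
    export_mcscanx(m, out_prefix)
    return(invisible(m))
  }
  m
}

#' Cluster pairwise matches and audit their consistency
#'
#' Stage three: consolidates match tables over two or more genomes into
#' anchor-graph clusters and runs the transitivity audit (plus the
#' reciprocal-best audit when genome sequences are supplied).
#'
#' @param match_tables list of match tables.
#' @param candidate_sets optional named list of annotated candidate sets
#'   for transitivity realignment.
#' @param genomes optional named list of [genome()] objects enabling the
#'   reciprocal-best audit.
#' @param config a [pipeline_config()].
#' @param out_prefix path prefix for cluster/audit files, or `NULL`.
#' @return list with `graph`, `clusters`, `transitivity`, and
#'   `reciprocal_best` (NULL without genomes).
#' @export
cluster_and_audit <- function(match_tables, candidate_sets = NULL,
                              genomes = NULL, config = pipeline_config(),
                              out_prefix = NULL) {
  if (is.data.frame(match_tables)) match_tables <- list(match_tables)
  gids <- unlist(lapply(match_tables, function(m)
    c(m$genome_x, m$genome_y)))
  if (!is.null(genomes)) {
    missing <- setdiff(unique(gids), names(genomes))
    if (length(missing) > 0)
      stop("genome id(s) in match tables without sequence: ",
           paste(missing, collapse = ", "))
  }
  ag <- build_anchor_graph(match_tables)
  trans <- audit_transitivity(ag, candidate_sets = candidate_sets,
                              model = config$model,
                              significant_bits = config$floor)
  rbh <- NULL
  if (!is.null(genomes)) {
    all_m <- do.call(rbind, match_tables)
    rbh <- audit_reciprocal_best(all_m, genomes, model = config$model,
                                 max_distance = config$proximity)
  }
  if (!is.null(out_prefix)) {
    reports <- list(transitivity = trans)
    if (!is.null(rbh)) reports$reciprocal_best <- rbh
    write_cluster_audit(ag, reports, out_prefix)
  }
  list(graph = ag, clusters = anchor_clusters(ag), transitivity = trans,
       reciprocal_best = rbh)
}
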