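# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (string-level enumeration, exhaustive search) and share
# no code with the implementation they check.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_genome <- function(n, n_frag = 1, id = "g", with_n = FALSE) {
  frs <- character(n_frag)
  per <- rep(n %/% n_frag, n_frag)
  per[n_frag] <- per[n_frag] + n %% n_frag
  for (i in seq_len(n_frag)) {
    s <- rand_seq(per[i])
    if (with_n && per[i] > 10) {
      # drop a short N run somewhere in the middle
      p <- sample.int(per[i] - 3, 1)
      substr(s, p, p + 1) <- "NN"
    }
    frs[i] <- s
  }
  names(frs) <- sprintf("f%d", seq_len(n_frag))
  genome(frs, genome_id = id)
}

str_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# all k-mers of a string as a character vector (invalid -> NA)
string_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# Naive both-strand k-mer counting: for every valid forward k-mer position,
# count universe k-mers (forward k-mers of all fragments plus of their
# reverse complements) within Hamming distance m. N-containing windows are
# poison (NA) and excluded from the universe.
naive_kmer_counts <- function(g, k, m) {
  universe <- character(0)
  for (s in g$fragments) {
    universe <- c(universe, string_kmers(s, k),
                  string_kmers(str_revcomp(s), k))
  }
  universe <- universe[!grepl("N", universe)]
  umat <- do.call(rbind, strsplit(universe, ""))
  lapply(g$fragments, function(s) {
    km <- string_kmers(s, k)
    if (length(km) == 0) return(integer(0))
    vapply(km, function(x) {
      if (grepl("N", x)) return(NA_integer_)
      xs <- strsplit(x, "")[[1]]
      dist <- rowSums(umat != matrix(xs, nrow(umat), k, byrow = TRUE))
      sum(dist <= m)
    }, 1L, USE.NAMES = FALSE)
  })
}

# Exhaustive best-chain score per (sfrag, strand) group by enumerating all
# ordered subsets of fragments under the collinearity constraint.
brute_best_chain <- function(frags) {
  groups <- split(seq_len(nrow(frags)),
                  paste(frags$sfrag, frags$strand))
  res <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    gf <- frags[idx, , drop = FALSE]
    if (gf$strand[1] == "+") { ts <- gf$sstart; te <- gf$send }
    else { ts <- -gf$send; te <- -gf$sstart }
    o <- order(gf$qstart, ts)
    gf <- gf[o, ]; ts <- ts[o]; te <- te[o]
    n <- nrow(gf)
    best <- -Inf
    # DFS over subsets in sorted order, last chosen fragment as state
    recurse <- function(i, last, total) {
      if (total > best) best <<- total
      if (i > n) return()
      for (j in i:n) {
        ok <- last == 0L ||
          (gf$qend[last] <= gf$qstart[j] && te[last] <= ts[j])
        if (ok) recurse(j + 1L, j, total + gf$bits[j])
      }
    }
    recurse(1L, 0L, 0)
    res[[gname]] <- best
  }
  res
}

# Smith-Waterman local score via Biostrings, independent of the package's
# own scorers. Biostrings charges gapOpening + L * gapExtension for a gap
# of length L, the same affine convention as the package.
biostrings_sw <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE))
}

# a diverged copy of `seq`: point substitutions plus up to `n_indel`
# single-nucleotide indels, keeping an untouched core so an exact seed word
# is guaranteed to exist
diverge_seq <- function(seq, sub_rate = 0.05, n_indel = 0, core = 15) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  core_lo <- max(1, (n - core) %/% 2)
  core_hi <- min(n, core_lo + core - 1)
  pos <- which(stats::runif(n) < sub_rate)
  pos <- setdiff(pos, core_lo:core_hi)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (p in pos) chars[p] <- sample(alt[[chars[p]]], 1)
  if (n_indel > 0) {
    spots <- setdiff(seq_len(length(chars)), core_lo:core_hi)
    spots <- sample(spots, min(n_indel, length(spots)))
    for (p in sort(spots, decreasing = TRUE)) {
      if (stats::runif(1) < 0.5) {
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = p)
      } else {
        chars <- chars[-p]
      }
    }
  }
  paste(chars, collapse = "")
}

# default-model bit scale helpers for expected values in tests
default_bits <- function(raw) bit_score(raw, score_model())
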