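make_track <- function(counts_list, k = 3L, m = 0L, id = "t") {
  structure(list(genome_id = id, k = as.integer(k), mismatches = m,
                 counts = counts_list),
            class = "kmer_count_track")
}

test_that("window rareness sums l - k + 1 count terms per window", {
  # uniform unique counts, default geometry: f = 500 - 13 + 1 = 488
  tr <- make_track(list(f1 = rep(1L, 2000 - 13 + 1)), k = 13L)
  w <- window_rareness(tr, 500, 250)
  expect_true(all(w$f == 488))
  expect_identical(w$start, seq(0L, 1500L, by = 250L))

  # a 600 nt fragment fits exactly one 500 nt window at step 250
  tr <- make_track(list(f1 = rep(1L, 600 - 13 + 1)), k = 13L)
  expect_identical(nrow(window_rareness(tr, 500, 250)), 1L)

  # counts 1,2,3,4 with l=4, k=3: single window, f = 1 + 2
  tr <- make_track(list(f1 = c(1L, 2L, 3L, 4L)), k = 3L)
  w <- window_rareness(tr, 4, 2)
  expect_identical(w$f[1], 3)

  expect_error(window_rareness(make_track(list(f1 = 1:5), k = 6L), 4, 2),
               ">= k")
})

test_that("window rareness equals naive summation on a random genome", {
  set.seed(71)
  g <- rand_genome(3000, n_frag = 2, id = "t", with_n = TRUE)
  tr <- count_kmers(g, 5)
  w <- window_rareness(tr, window = 100, step = 37)
  for (i in seq_len(nrow(w))) {
    v <- tr$counts[[w$fragment[i]]][(w$start[i] + 1):(w$start[i] + 96)]
    want <- if (anyNA(v)) NA_real_ else sum(v)
    expect_equal(w$f[i], want)
  }
})

test_that("poison windows are emitted as NA and never selected", {
  tr <- make_track(list(f1 = c(rep(1L, 300), NA_integer_,
                               rep(1L, 1000))), k = 13L)
  w <- window_rareness(tr, 500, 250)
  expect_true(is.na(w$f[1]))  # window [0, 500) covers the poison position
  kept <- select_percentile(w, 15)
  expect_false(any(is.na(kept$f)))

  allpois <- make_track(list(f1 = rep(NA_integer_, 988)), k = 13L)
  wp <- window_rareness(allpois, 500, 250)
  expect_warning(kp <- select_percentile(wp, 15), "no finite")
  expect_identical(nrow(kp), 0L)
})

test_that("nearest-rank percentile selection keeps ties at the cutoff", {
  w <- data.frame(fragment = "f", start = 0:99 * 10L,
                  end = 0:99 * 10L + 500L, f = as.numeric(sample(1:100)))
  kept <- select_percentile(w, 15)
  expect_setequal(kept$f, 1:15)
  expect_identical(attr(kept, "cutoff"), 15)

  w$f <- rep(7, 100)
  expect_identical(nrow(select_percentile(w, 15)), 100L)

  expect_error(select_percentile(w, 0), "in \\(0, 100\\]")
})

test_that("the 30% merge rule discards, extends, or appends", {
  ex <- data.frame(fragment = "f", start = 0L, end = 500L,
                   profiles = "k13_m0")
  # 100/500 = 20% overlap of the existing interval: discarded
  nw <- data.frame(fragment = "f", start = 400L, end = 900L)
  out <- merge_candidates(ex, nw, profile_label = "k15_m0")
  expect_identical(out[, c("start", "end")],
                   data.frame(start = 0L, end = 500L))

  # 250/500 = 50%: existing extended to the union
  nw <- data.frame(fragment = "f", start = 250L, end = 750L)
  out <- merge_candidates(ex, nw, profile_label = "k15_m0")
  expect_identical(out$end, 750L)
  expect_identical(out$profiles, "k13_m0,k15_m0")

  # empty set: the first profile seeds it
  out <- merge_candidates(NULL, data.frame(fragment = "f", start = 0L,
                                           end = 500L),
                          profile_label = "k13_m0")
  expect_identical(nrow(out), 1L)

  # different fragment: appended, not merged
  nw <- data.frame(fragment = "g", start = 0L, end = 500L)
  out <- merge_candidates(ex, nw, profile_label = "k15_m0")
  expect_identical(nrow(out), 2L)
})

test_that("candidate construction is deterministic and repeat-averse", {
  set.seed(81)
  sim <- simulate_genome(60000, repeats = repeat_spec(1, 6, 1500, 0),
                         seed = 313, genome_id = "rep")
  cs1 <- build_candidates(sim$genome)
  cs2 <- build_candidates(sim$genome)
  expect_identical(cs1$candidates, cs2$candidates)
  expect_gt(nrow(cs1$candidates), 0)
  expect_true(all(cs1$candidates$end - cs1$candidates$start >= 500))

  # identical 1.5 kb hexa-copy repeat: its interior can never be a candidate
  rep_ann <- sim$truth$repeats
  interior_hit <- vapply(seq_len(nrow(rep_ann)), function(i) {
    any(cs1$candidates$fragment == rep_ann$fragment[i] &
          cs1$candidates$start < rep_ann$end[i] - 21 &
          cs1$candidates$end > rep_ann$start[i] + 21)
  }, TRUE)
  expect_false(any(interior_hit))
})

test_that("a genome shorter than the window yields an empty set", {
  g <- genome(c(f = rand_seq(400)), genome_id = "short")
  expect_warning(cs <- build_candidates(g), "no fragment fits")
  expect_identical(nrow(cs$candidates), 0L)
})

test_that("candidate tracks round-trip through BED and TSV", {
  set.seed(91)
  g <- rand_genome(3000, id = "io")
  cs <- build_candidates(g, profiles = list(list(k = 7, mismatches = 0L,
                                                 p = 25)),
                         window = 300, step = 150)
  prefix <- withr::local_tempfile()
  write_candidates(cs, prefix, header = "# test")
  bed <- read.table(paste0(prefix, ".bed"), sep = "\t")
  expect_identical(nrow(bed), nrow(cs$candidates))
  expect_identical(bed$V2, cs$candidates$start)   # BED is 0-based, as internal
  expect_identical(bed$V3, cs$candidates$end)
})
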