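test_that("simulation is seed-deterministic and seed-sensitive", {
  s1 <- simulate_genome(5000, seed = 1)
  s2 <- simulate_genome(5000, seed = 1)
  s3 <- simulate_genome(5000, seed = 2)
  expect_identical(s1$genome$fragments, s2$genome$fragments)
  expect_false(identical(s1$genome$fragments, s3$genome$fragments))
  expect_identical(genome_length(s1$genome), 5000L)
})

test_that("planted repeats are recorded exactly in the truth map", {
  sim <- simulate_genome(30000, repeats = repeat_spec(1, 8, 1000, 0),
                         seed = 3)
  ann <- sim$truth$repeats
  expect_identical(nrow(ann), 8L)
  seqs <- vapply(seq_len(8), function(i)
    fragment_seq(sim$genome, ann$fragment[i], ann$start[i], ann$end[i]),
    "")
  expect_identical(length(unique(seqs)), 1L) # divergence 0: byte-identical

  div <- simulate_genome(30000, repeats = repeat_spec(1, 4, 1000, 0.05),
                         seed = 4)
  dseqs <- vapply(seq_len(4), function(i) {
    a <- div$truth$repeats
    fragment_seq(div$genome, a$fragment[i], a$start[i], a$end[i])
  }, "")
  expect_gt(length(unique(dseqs)), 1L)
})

test_that("excessive repeat content and bad rates are rejected", {
  expect_error(simulate_genome(10000,
                               repeats = repeat_spec(1, 9, 1000, 0)),
               "80%")
  expect_error(simulate_genome(1500, n_fragments = 2), "1 kb per fragment")
  g <- simulate_genome(5000, seed = 1)$genome
  expect_error(evolve_genome(g, substitution_rate = 0.5), "0, 0.3")
  expect_error(
    evolve_genome(g, events = list(ev_inversion("frag01", 100, 600),
                                   ev_deletion("frag01", 500, 900))),
    "overlapping event")
})

test_that("a clone has an identity truth map", {
  g <- simulate_genome(5000, seed = 5)$genome
  ev <- evolve_genome(g, 0, 0, seed = 6)
  expect_identical(ev$genome$fragments[[1]], g$fragments[[1]])
  b <- ev$truth$blocks
  expect_identical(nrow(b), 1L)
  expect_identical(b$src_start, 0L)
  expect_identical(b$src_end, 5000L)
  expect_identical(b$der_start, 0L)
  expect_identical(b$strand, "+")
})

test_that("realized substitution rate concentrates around the target", {
  g <- simulate_genome(100000, seed = 7)$genome
  ev <- evolve_genome(g, substitution_rate = 0.05, seed = 8)
  a <- strsplit(g$fragments[[1]], "")[[1]]
  b <- strsplit(ev$genome$fragments[[1]], "")[[1]]
  rate <- mean(a != b)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("inversions flip strand and remap coordinates exactly", {
  g <- simulate_genome(10000, seed = 9)$genome
  ev <- evolve_genome(g, 0, 0,
                      events = list(ev_inversion("frag01", 2000, 3000)),
                      seed = 10)
  b <- ev$truth$blocks
  inv <- b[b$strand == "-", ]
  expect_identical(nrow(inv), 1L)
  expect_identical(c(inv$src_start, inv$src_end), c(2000L, 3000L))
  expect_identical(c(inv$der_start, inv$der_end), c(2000L, 3000L))
  expect_identical(
    substr(ev$genome$fragments[[1]], 2001, 3000),
    reverse_complement(substr(g$fragments[[1]], 2001, 3000)))
})

test_that("duplications create flagged one-to-many truth entries", {
  g <- simulate_genome(10000, seed = 11)$genome
  ev <- evolve_genome(
    g, 0, 0,
    events = list(ev_duplication("frag01", 1000, 1500, "frag01", 8000)),
    seed = 12)
  b <- ev$truth$blocks
  expect_identical(sum(b$duplicate), 1L)
  expect_identical(genome_length(ev$genome), 10500L)
  dup <- b[b$duplicate, ]
  expect_identical(
    substr(ev$genome$fragments[[1]], dup$der_start + 1, dup$der_end),
    substr(g$fragments[[1]], 1001, 1500))
})

test_that("replaying the logged events reproduces the derived genome", {
  for (seed in c(13, 14)) {
    g <- simulate_genome(20000, n_fragments = 2, seed = seed)$genome
    ev <- evolve_genome(
      g, substitution_rate = 0.03, indel_rate = 0.002,
      events = list(ev_inversion("frag01", 2000, 4000),
                    ev_translocation("frag02", 1000, 3000, "frag01", 500)),
      seed = seed + 100)
    replayed <- replay_truth(g, ev$truth)
    expect_identical(replayed$fragments, ev$genome$fragments)
  }
})

test_that("truth blocks tile the derived genome consistently", {
  g <- simulate_genome(20000, seed = 15)$genome
  ev <- evolve_genome(
    g, substitution_rate = 0.02, indel_rate = 0.001,
    events = list(ev_inversion("frag01", 5000, 8000),
                  ev_deletion("frag01", 12000, 12500)),
    seed = 16)
  b <- ev$truth$blocks
  expect_true(all(b$der_end - b$der_start == b$src_end - b$src_start))
  # derived intervals of one fragment are disjoint and inside the genome
  for (f in unique(b$der_frag)) {
    d <- b[b$der_frag == f, ]
    d <- d[order(d$der_start), ]
    expect_true(all(d$der_start[-1] >= d$der_end[-nrow(d)]))
    expect_lte(max(d$der_end), nchar(ev$genome$fragments[[f]]))
  }
  # every derived block matches its source text (modulo substitutions)
  for (i in seq_len(nrow(b))) {
    src <- substr(g$fragments[[b$src_frag[i]]], b$src_start[i] + 1,
                  b$src_end[i])
    der <- substr(ev$genome$fragments[[b$der_frag[i]]],
                  b$der_start[i] + 1, b$der_end[i])
    if (b$strand[i] == "-") der <- reverse_complement(der)
    same <- mean(strsplit(src, "")[[1]] == strsplit(der, "")[[1]])
    expect_gt(same, 0.9)
  }
})

test_that("anchor evaluation is strand-aware and handles empty input", {
  g <- simulate_genome(10000, seed = 17, genome_id = "src")$genome
  ev <- evolve_genome(g, 0, 0,
                      events = list(ev_inversion("frag01", 4000, 6000)),
                      seed = 18, genome_id = "der")
  # a hand-made perfect match inside the inversion must carry strand "-"
  m <- data.frame(genome_x = "src", candidate_x = "c1", x_frag = "frag01",
                  x_start = 4500L, x_end = 5000L,
                  genome_y = "der", candidate_y = "d1", y_frag = "frag01",
                  y_start = 5000L, y_end = 5500L,
                  x_sub_start = 4500L, x_sub_end = 5000L,
                  y_sub_start = 5000L, y_sub_end = 5500L,
                  strand = "-", score = 900, threshold = 46.3,
                  rule = "standard", lemma_guaranteed = TRUE,
                  n_hits_x = 1L, n_hits_y = 1L, stringsAsFactors = FALSE)
  ev_res <- evaluate_anchors(m, ev$truth, slack = 10)
  expect_identical(ev_res$precision, 1)
  m_plus <- m; m_plus$strand <- "+"
  expect_identical(evaluate_anchors(m_plus, ev$truth, slack = 10)$precision,
                   0)

  expect_warning(r <- evaluate_anchors(m[0, ], ev$truth), "vacuous")
  expect_identical(r$precision, 1)
  expect_identical(r$recall, 0)

  bad <- m; bad$genome_x <- "elsewhere"
  expect_error(evaluate_anchors(bad, ev$truth), "different genome pairs")
})

test_that("simulator artifacts are written as plain text", {
  sim <- simulate_genome(5000, repeats = repeat_spec(1, 2, 500, 0),
                         seed = 19)
  ev <- evolve_genome(sim$genome, 0.01, 0,
                      events = list(ev_inversion("frag01", 1000, 1400)),
                      seed = 20, source_truth = sim$truth)
  prefix <- withr::local_tempfile()
  paths <- write_simulation(ev, prefix)
  expect_true(all(file.exists(paths)))
  g2 <- read_genome_fasta(paste0(prefix, ".fa"))
  expect_identical(unname(g2$fragments), unname(ev$genome$fragments))
  js <- jsonlite::read_json(paste0(prefix, ".events.json"))
  expect_identical(js$events[[1]]$type, "inversion")
})
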