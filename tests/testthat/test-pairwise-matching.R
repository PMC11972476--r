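annotated_set <- function(g, model = score_model(), ...) {
  annotate_uniqueness(g, build_candidates(g, ...), model = model)
}

# hand-built annotated candidate set (for threshold/omission logic tests
# that need full control over loci and sequences)
fake_set <- function(genome_id, seqs, starts, fragment = "f1", s0 = 40) {
  n <- length(seqs)
  df <- data.frame(
    candidate_id = sprintf("%s_c%04d", genome_id, seq_len(n)),
    fragment = fragment, start = as.integer(starts),
    end = as.integer(starts + nchar(seqs)),
    profiles = "k13_m0", sequence = seqs,
    s0 = rep(s0, length.out = n), d0 = 0,
    best_chain_score = NA_real_, n_self_hits = 0L,
    stringsAsFactors = FALSE)
  structure(list(genome_id = genome_id, candidates = df),
            class = "candidate_set")
}

test_that("threshold arithmetic matches the margin and multi-hit rules", {
  t1 <- compute_threshold(100, 64, 1, 1)
  expect_equal(t1$threshold, 110)
  expect_identical(t1$rule, "standard")

  t2 <- compute_threshold(100, 64, 2, 1)
  expect_equal(t2$threshold, 200)
  expect_identical(t2$rule, "multi-hit")

  t3 <- compute_threshold(40, 40, 1, 1)
  expect_equal(t3$threshold, 40 + sqrt(40), tolerance = 1e-12)
  expect_equal(t3$threshold, 46.32456, tolerance = 1e-5)

  # vectorised over a grid; multi-hit dominates standard whenever s0 >= 1
  s0 <- c(1, 40, 64, 100, 400, 1000)
  grid <- expand.grid(x = s0, y = s0)
  std <- compute_threshold(grid$x, grid$y, 1, 1)
  mlt <- compute_threshold(grid$x, grid$y, 2, 2)
  expect_true(all(mlt$threshold >= std$threshold))
  expect_true(all(std$threshold == pmax(grid$x + sqrt(grid$x),
                                        grid$y + sqrt(grid$y))))
})

test_that("the guarantee flag mirrors the half-distance condition", {
  expect_true(lemma_guarantee_check(1000, 40, 40, 500, 500))
  expect_false(lemma_guarantee_check(519, 40, 40, 500, 500))
  # distance form: d0G = 10, d0H = 8, d(w,y) = 3 <= min/2 = 4
  alpha <- 2; l <- 500
  s <- alpha * l - 3; s0g <- alpha * l - 10; s0h <- alpha * l - 8
  expect_true(lemma_guarantee_check(s, s0g, s0h, l, l))
  # just past the boundary: d = 5 > 4
  expect_false(lemma_guarantee_check(alpha * l - 5, s0g, s0h, l, l))
  # unequal lengths use the shorter partner
  expect_true(lemma_guarantee_check(600, 40, 40, 500, 550))
  expect_false(lemma_guarantee_check(600, 40, 40, 700, 620))
})

test_that("two clonal unique candidates form one standard-rule match", {
  set.seed(301)
  shared <- rand_seq(500)
  gA <- genome(c(f1 = paste0(rand_seq(4000), shared, rand_seq(4000))),
               genome_id = "A")
  gB <- genome(c(f1 = paste0(rand_seq(2000), shared, rand_seq(6000))),
               genome_id = "B")
  csA <- fake_set("A", shared, 4000)
  csB <- fake_set("B", shared, 2000)
  m <- find_anchor_matches(csA, csB)
  expect_identical(nrow(m), 1L)
  expect_identical(m$rule, "standard")
  expect_equal(m$score, default_bits(1000), tolerance = 1e-8)
  expect_gt(m$score, m$threshold)
  expect_true(m$lemma_guaranteed)
  expect_identical(m$strand, "+")
  expect_identical(m$x_sub_start, 4000L)
  expect_identical(m$y_sub_end, 2500L)
})

test_that("a candidate matching two distant partners is omitted entirely", {
  set.seed(311)
  left <- rand_seq(500); right <- rand_seq(500)
  # one long candidate in A; B carries its halves 50 kb apart
  csA <- fake_set("A", paste0(left, right), 1000)
  csB <- fake_set("B", c(left, right), c(1000, 51000))
  m <- find_anchor_matches(csA, csB)
  expect_identical(nrow(m), 0L)
})

test_that("close disjoint partners are all retained", {
  set.seed(321)
  left <- rand_seq(500); right <- rand_seq(500)
  csA <- fake_set("A", paste0(left, right), 1000)
  # same two partners, but adjacent (gap 200 nt < proximity limit)
  csB <- fake_set("B", c(left, right), c(1000, 1700))
  m <- find_anchor_matches(csA, csB)
  expect_identical(nrow(m), 2L)
  expect_setequal(m$candidate_y, c("B_c0001", "B_c0002"))
  # the two matches cover disjoint halves of the A candidate
  expect_lte(min(m$x_sub_end) - 1, max(m$x_sub_start))
})

test_that("close overlapping partners collapse to the best-scoring match", {
  set.seed(331)
  core <- rand_seq(500)
  csA <- fake_set("A", core, 1000)
  # two B candidates exposing the same sequence close together: both hit
  # the same subinterval of the A candidate, only the best survives
  csB <- fake_set("B", c(core, diverge_seq(core, 0.04)), c(1000, 1800))
  m <- find_anchor_matches(csA, csB)
  expect_identical(nrow(m), 1L)
  expect_identical(m$candidate_y, "B_c0001") # the perfect copy wins
})

test_that("match tables are exactly symmetric under argument swap", {
  set.seed(341)
  src <- simulate_genome(30000, seed = 51, genome_id = "gA")
  der <- evolve_genome(src$genome, substitution_rate = 0.03, seed = 52,
                       genome_id = "gB")
  csA <- annotated_set(src$genome)
  csB <- annotated_set(der$genome)
  m1 <- find_anchor_matches(csA, csB)
  m2 <- find_anchor_matches(csB, csA)
  expect_gt(nrow(m1), 0)
  m2m <- mirror_matches(m2)
  o1 <- do.call(order, m1[c("candidate_x", "candidate_y")])
  o2 <- do.call(order, m2m[c("candidate_x", "candidate_y")])
  rownames(m1) <- rownames(m2m) <- NULL
  expect_equal(m1[o1, ], m2m[o2, names(m1)], ignore_attr = TRUE)
})

test_that("missing uniqueness annotation is refused", {
  set.seed(351)
  g <- rand_genome(20000, id = "A")
  cs <- build_candidates(g)
  expect_error(find_anchor_matches(cs, cs), "s0 annotations")
})

test_that("MCScanX-style exports carry the homology and position layout", {
  set.seed(361)
  shared <- rand_seq(500)
  csA <- fake_set("A", shared, 4000)
  csB <- fake_set("B", shared, 2000)
  m <- find_anchor_matches(csA, csB)
  prefix <- withr::local_tempfile()
  paths <- export_mcscanx(m, prefix)
  hom <- read.table(paste0(prefix, ".homology"), sep = "\t")
  expect_identical(hom$V1, "A_c0001")
  expect_identical(hom$V2, "B_c0001")
  gffA <- read.table(paste0(prefix, ".A.gff"), sep = "\t")
  expect_identical(ncol(gffA), 4L)
  expect_identical(gffA$V3, 4001L) # 1-based inclusive display coordinates
  expect_identical(gffA$V4, 4500L)
})
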