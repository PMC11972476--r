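# minimal match-table row connecting candidate cx in genome gx with cy in gy
edge_row <- function(gx, cx, gy, cy, frag_x = "f1", start_x = 0L,
                     frag_y = "f1", start_y = 0L, len = 500L,
                     score = 900) {
  data.frame(genome_x = gx, candidate_x = cx, x_frag = frag_x,
             x_start = start_x, x_end = start_x + len,
             genome_y = gy, candidate_y = cy, y_frag = frag_y,
             y_start = start_y, y_end = start_y + len,
             x_sub_start = start_x, x_sub_end = start_x + len,
             y_sub_start = start_y, y_sub_end = start_y + len,
             strand = "+", score = score, threshold = 46.3,
             rule = "standard", lemma_guaranteed = TRUE,
             n_hits_x = 1L, n_hits_y = 1L, stringsAsFactors = FALSE)
}

test_that("connected components become deterministic clusters", {
  m <- rbind(edge_row("A", "w", "B", "y"), edge_row("B", "y", "C", "z"))
  ag <- build_anchor_graph(m)
  expect_identical(length(ag$components), 1L)
  expect_setequal(ag$components[[1]], c("A::w", "B::y", "C::z"))
  expect_identical(names(ag$components), "A::w")

  cl <- anchor_clusters(ag)
  expect_identical(nrow(cl), 3L)
  expect_true(all(cl$component_id == "A::w"))

  empty <- build_anchor_graph(m[0, ])
  expect_identical(length(empty$components), 0L)

  two <- rbind(edge_row("A", "w1", "B", "y1"),
               edge_row("A", "w2", "B", "y2"))
  ag2 <- build_anchor_graph(two)
  expect_identical(lengths(ag2$components), c(`A::w1` = 2L, `A::w2` = 2L))
})

test_that("transitivity audit counts exactly the non-adjacent pairs", {
  # path w - y - z across three genomes: one implied-missing pair (w, z)
  m <- rbind(edge_row("A", "w", "B", "y"), edge_row("B", "y", "C", "z"))
  rep1 <- audit_transitivity(build_anchor_graph(m))
  expect_identical(rep1$summary$n_implied_missing, 1L)
  expect_identical(rep1$summary$n_clusters_missing_edges, 1L)
  expect_setequal(unlist(rep1$cases[1, c("vertex_1", "vertex_2")]),
                  c("A::w", "C::z"))

  # closing the triangle clears the audit
  m3 <- rbind(m, edge_row("A", "w", "C", "z"))
  rep2 <- audit_transitivity(build_anchor_graph(m3))
  expect_identical(rep2$summary$n_implied_missing, 0L)
  expect_identical(rep2$summary$n_clusters_missing_edges, 0L)

  # path across four genomes: non-adjacent pairs (w,z), (y,v), (w,v)
  m4 <- rbind(m, edge_row("C", "z", "D", "v"))
  rep3 <- audit_transitivity(build_anchor_graph(m4))
  expect_identical(rep3$summary$n_implied_missing, 3L)

  # two candidates of one genome in a cluster are never an implied pair
  m5 <- rbind(edge_row("A", "w1", "B", "y"), edge_row("A", "w2", "B", "y"))
  rep4 <- audit_transitivity(build_anchor_graph(m5))
  expect_identical(rep4$summary$n_implied_missing, 0L)
})

test_that("audit counts are invariant to genome input order", {
  m <- rbind(edge_row("A", "w", "B", "y"), edge_row("B", "y", "C", "z"))
  m_rev <- mirror_matches(m[2:1, ])
  r1 <- audit_transitivity(build_anchor_graph(m))
  r2 <- audit_transitivity(build_anchor_graph(m_rev))
  expect_identical(r1$summary$n_implied_missing,
                   r2$summary$n_implied_missing)
  expect_identical(r1$summary$n_implied_checked,
                   r2$summary$n_implied_checked)
})

test_that("transitivity realignment recognises genuinely similar pairs", {
  set.seed(401)
  core <- rand_seq(500)
  css <- lapply(c("A", "B", "C"), function(id) {
    df <- data.frame(candidate_id = paste0(id, "_c0001"), fragment = "f1",
                     start = 0L, end = 500L, profiles = "k13_m0",
                     sequence = diverge_seq(core, 0.02), s0 = 40, d0 = 960,
                     best_chain_score = NA_real_, n_self_hits = 0L,
                     stringsAsFactors = FALSE)
    structure(list(genome_id = id, candidates = df),
              class = "candidate_set")
  })
  names(css) <- c("A", "B", "C")
  m <- rbind(edge_row("A", "A_c0001", "B", "B_c0001"),
             edge_row("B", "B_c0001", "C", "C_c0001"))
  rep <- audit_transitivity(build_anchor_graph(m), candidate_sets = css)
  expect_identical(rep$summary$n_implied_missing, 1L)
  expect_true(rep$cases$significant[1])
  expect_gt(rep$cases$realigned_score[1], 500)
})

test_that("clonal genomes pass the reciprocal-best audit cleanly", {
  set.seed(411)
  body <- rand_seq(20000)
  gA <- genome(c(f1 = body), genome_id = "A")
  gB <- genome(c(f1 = body), genome_id = "B")
  m <- edge_row("A", "A_c1", "B", "B_c1", start_x = 5000L,
                start_y = 5000L)
  rep <- audit_reciprocal_best(m, list(A = gA, B = gB))
  expect_identical(rep$summary$n_rbh_violations, 0L)
})

test_that("a planted distant better copy is flagged at distance > 10 kb", {
  set.seed(421)
  body <- rand_seq(20000)
  w <- substr(body, 5001, 5500)
  gA <- genome(c(f1 = body), genome_id = "A")
  # partner genome: diverged copy at the syntenic locus, perfect copy
  # 11.5 kb downstream
  fragB <- body
  substr(fragB, 5001, 5500) <- diverge_seq(w, 0.04)
  fragB <- paste0(substr(fragB, 1, 17000), w,
                  substr(fragB, 17501, 20000))
  gB <- genome(c(f1 = fragB), genome_id = "B")
  m <- edge_row("A", "A_c1", "B", "B_c1", start_x = 5000L,
                start_y = 5000L)
  rep <- audit_reciprocal_best(m, list(A = gA, B = gB))
  expect_identical(rep$summary$n_rbh_violations, 1L)
  expect_gt(rep$cases$distance[1], 10000)
  expect_identical(rep$cases$genome_searched[1], "B")
  # the offending best hit is the same subsequence, so overlap is high
  expect_gt(rep$cases$overlap_fraction[1], 0.8)

  # a best hit within 10 kb of the matched locus is not flagged
  fragC <- body
  substr(fragC, 5001, 5500) <- diverge_seq(w, 0.04)
  fragC <- paste0(substr(fragC, 1, 9000), w, substr(fragC, 9501, 20000))
  gC <- genome(c(f1 = fragC), genome_id = "B")
  rep2 <- audit_reciprocal_best(m, list(A = gA, B = gC))
  expect_identical(rep2$summary$n_rbh_violations, 0L)
})

test_that("cluster and audit artifacts are written together", {
  m <- rbind(edge_row("A", "w", "B", "y"), edge_row("B", "y", "C", "z"))
  ag <- build_anchor_graph(m)
  rep <- audit_transitivity(ag)
  prefix <- withr::local_tempfile()
  paths <- write_cluster_audit(ag, list(transitivity = rep), prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paste0(prefix, ".audit.json"))
  expect_identical(js$transitivity$n_implied_missing, 1L)
})
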