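test_that("BSR is hit over self score, guarded and clamped", {
  expect_equal(compute_bsr(450, 450), 1.0)
  expect_equal(compute_bsr(225, 450), 0.5)
  expect_error(compute_bsr(450, 0), "positive")
  expect_warning(r <- compute_bsr(451, 450), "clamped")
  expect_equal(r, 1.0)
})

test_that("best hit wins on bit score with the documented tie chain", {
  mk <- function(s, bit, ev, pid) {
    data.frame(query_id = "g1", subject_id = s, pct_identity = pid,
               aln_length = 100L, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
               evalue = ev, bit_score = bit, stringsAsFactors = FALSE)
  }
  b <- best_hits(rbind(mk("h1", 500, 1e-50, 90), mk("h2", 300, 1e-20, 99)))
  expect_identical(b$subject_id, "h1")
  expect_false(b$ambiguous)
  # bit tie resolved at the e-value level is not ambiguous
  b2 <- best_hits(rbind(mk("hA", 400, 1e-50, 90), mk("hB", 400, 1e-40, 90)))
  expect_identical(b2$subject_id, "hA")
  expect_false(b2$ambiguous)
  # tie through all numeric levels falls to subject id and is flagged
  b3 <- best_hits(rbind(mk("hB", 400, 1e-50, 90), mk("hA", 400, 1e-50, 90)))
  expect_identical(b3$subject_id, "hA")
  expect_true(b3$ambiguous)
})

test_that("best hits equal the argmax oracle on random tables", {
  for (seed in 1:6) {
    tabs <- random_hit_tables(seed)
    got <- best_hits(tabs$ab)
    want <- best_hit_oracle(tabs$ab)
    expect_identical(stats::setNames(got$subject_id, got$query_id), want)
  }
})

test_that("reciprocal best hits equal the set-intersection oracle and are symmetric", {
  expect_identical(
    reciprocal_best_hits(
      data.frame(query_id = "a1", subject_id = "b1", bsr = NA_real_),
      data.frame(query_id = "b1", subject_id = "a1", bsr = NA_real_))[, 1:2],
    data.frame(a_id = "a1", b_id = "b1", stringsAsFactors = FALSE))
  expect_equal(nrow(reciprocal_best_hits(
    data.frame(query_id = "a1", subject_id = "b1", bsr = NA_real_),
    data.frame(query_id = "b1", subject_id = "a2", bsr = NA_real_))), 0L)
  for (seed in 7:12) {
    tabs <- random_hit_tables(seed, n_a = 40, n_b = 40)
    fwd <- best_hits(tabs$ab); bwd <- best_hits(tabs$ba)
    got <- reciprocal_best_hits(fwd, bwd)
    expect_identical(sort(paste(got$a_id, got$b_id, sep = "|")),
                     rbh_oracle(tabs$ab, tabs$ba))
    # symmetry under swapped inputs
    swapped <- reciprocal_best_hits(bwd, fwd)
    expect_identical(sort(paste(swapped$b_id, swapped$a_id, sep = "|")),
                     sort(paste(got$a_id, got$b_id, sep = "|")))
    # RBH is a sub-relation of best hits and ids are unique
    expect_true(all(!duplicated(got$a_id)) && all(!duplicated(got$b_id)))
    expect_true(all(got$b_id == stats::setNames(fwd$subject_id,
                                                fwd$query_id)[got$a_id]))
  }
})

test_that("planted one-to-one orthologs are recovered completely as RBH edges", {
  res <- build_fixture_graph(31, layers = c("genome", "homology"))
  g <- res$graph
  truth <- res$fx$truth$orthologs
  e <- graph_edges(g)
  rbh <- e[e$rel_type == "RECIPROCAL_BEST_HIT", ]
  want <- sort(paste(pmin(truth$a_id, truth$b_id),
                     pmax(truth$a_id, truth$b_id), sep = "|"))
  expect_identical(sort(paste(rbh$source, rbh$target, sep = "|")), want)
  # undirected semantics: retrievable from either endpoint
  expect_true("spB_g01" %in% neighbor_ids(g, "spA_g01", "RECIPROCAL_BEST_HIT"))
  expect_true("spA_g01" %in% neighbor_ids(g, "spB_g01", "RECIPROCAL_BEST_HIT"))
  # BSR attributes on hit edges are in (0, 1]
  bp <- e[e$rel_type == "BLASTP_HIT", ][1, ]
  a <- g$edges[[paste(bp$source, bp$target, bp$rel_type, sep = "\x1f")]]$attributes
  expect_true(a$bsr > 0 && a$bsr <= 1)
})

test_that("rewriting homology edges leaves counts unchanged", {
  res <- build_fixture_graph(32, layers = c("genome", "homology"))
  g <- res$graph; fx <- res$fx
  e0 <- n_edges(g)
  write_homology_edges(g, fx$hits$spA__vs__spB, fx$hits$spB__vs__spA,
                       fx$self_scores$spA, fx$self_scores$spB)
  expect_equal(n_edges(g), e0)
})
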