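# a small graph with two species, explicit homology edges, for controlled
# synteny scans
synteny_toy <- function(target_order_homologs, extra = character(0)) {
  g <- property_graph()
  q_ids <- sprintf("q%d", seq_len(3))
  qf <- data.frame(feature_id = q_ids, landmark = "chr1",
                   start = (seq_len(3) - 1L) * 1000L,
                   end = (seq_len(3) - 1L) * 1000L + 500L, strand = "+",
                   ftype = "gene", parent_id = NA_character_,
                   stringsAsFactors = FALSE)
  qf$attributes <- replicate(3, list(), simplify = FALSE)
  import_genome(g, "qsp", qf)
  t_ids <- target_order_homologs
  tf <- data.frame(feature_id = t_ids, landmark = "chr9",
                   start = (seq_along(t_ids) - 1L) * 1000L,
                   end = (seq_along(t_ids) - 1L) * 1000L + 500L, strand = "+",
                   ftype = "gene", parent_id = NA_character_,
                   stringsAsFactors = FALSE)
  tf$attributes <- replicate(length(t_ids), list(), simplify = FALSE)
  import_genome(g, "tsp", tf)
  # homology edges by naming convention: tX is homologous to qX
  for (t in t_ids) {
    q <- sub("^t", "q", t)
    if (has_node(g, q)) {
      upsert_edge(g, q, t, "BLASTP_HIT", list(bsr = 1.0))
    }
  }
  g
}

test_that("an inserted unrelated gene is tolerated at max_gaps=1 only", {
  g <- synteny_toy(c("t1", "t2", "x_unrelated", "t3"))
  m1 <- find_syntenic_regions(g, "qsp", c("q1", "q2", "q3"), "tsp",
                              max_gaps = 1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$insertions, 1L)
  expect_equal(m1$deletions, 0L)
  expect_equal(m1$score, 3 - 0.5)
  expect_identical(m1$target_gene_ids[[1]], c("t1", "t2", "x_unrelated", "t3"))
  m0 <- find_syntenic_regions(g, "qsp", c("q1", "q2", "q3"), "tsp",
                              max_gaps = 0)
  expect_equal(nrow(m0), 0L)
})

test_that("a deleted target gene is tolerated as one deletion", {
  g <- synteny_toy(c("t1", "t3"))  # homolog of q2 deleted
  m1 <- find_syntenic_regions(g, "qsp", c("q1", "q2", "q3"), "tsp",
                              max_gaps = 1)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$deletions, 1L)
  expect_equal(m1$insertions, 0L)
  expect_equal(nrow(find_syntenic_regions(g, "qsp", c("q1", "q2", "q3"),
                                          "tsp", max_gaps = 0)), 0L)
})

test_that("reversed blocks match only on the reversed scan", {
  g <- synteny_toy(c("t3", "t2", "t1"))
  fwd_only <- find_syntenic_regions(g, "qsp", c("q1", "q2", "q3"), "tsp",
                                    max_gaps = 0, orientation = "forward")
  expect_equal(nrow(fwd_only), 0L)
  both <- find_syntenic_regions(g, "qsp", c("q1", "q2", "q3"), "tsp",
                                max_gaps = 0, orientation = "both")
  expect_equal(nrow(both), 1L)
  expect_identical(both$orientation, "reverse")
})

test_that("non-colinear queries are rejected as input errors", {
  g <- synteny_toy(c("t1", "t2", "t3"))
  expect_error(find_syntenic_regions(g, "qsp", c("q2", "q1", "q3"), "tsp"),
               "colinear")
  expect_error(find_syntenic_regions(g, "qsp", c("q1", "ghost"), "tsp"),
               "not found")
})

test_that("random searches match the window-enumeration oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n_t <- 14
    g <- property_graph()
    q_ids <- sprintf("q%d", 1:4)
    qf <- data.frame(feature_id = q_ids, landmark = "chr1",
                     start = (0:3) * 1000L, end = (0:3) * 1000L + 500L,
                     strand = "+", ftype = "gene", parent_id = NA_character_,
                     stringsAsFactors = FALSE)
    qf$attributes <- replicate(4, list(), simplify = FALSE)
    import_genome(g, "qsp", qf)
    t_ids <- sprintf("t%d", seq_len(n_t))
    tf <- data.frame(feature_id = t_ids, landmark = "chrT",
                     start = (seq_len(n_t) - 1L) * 1000L,
                     end = (seq_len(n_t) - 1L) * 1000L + 500L, strand = "+",
                     ftype = "gene", parent_id = NA_character_,
                     stringsAsFactors = FALSE)
    tf$attributes <- replicate(n_t, list(), simplify = FALSE)
    import_genome(g, "tsp", tf)
    homolog_sets <- lapply(1:4, function(i) {
      hs <- sample(t_ids, sample(0:3, 1))
      for (t in hs) upsert_edge(g, q_ids[i], t, "BLASTP_HIT", list(bsr = 1))
      hs
    })
    for (mg in 0:2) {
      got <- find_syntenic_regions(g, "qsp", q_ids, "tsp", max_gaps = mg,
                                   orientation = "forward")
      want_best <- synteny_oracle_best(homolog_sets, t_ids, mg)
      if (is.infinite(want_best)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_gt(nrow(got), 0L)
        expect_equal(max(got$score), want_best)
      }
    }
  }
})

test_that("scores never increase when max_gaps decreases", {
  res <- build_fixture_graph(51, layers = c("genome", "homology"))
  g <- res$graph
  q <- res$fx$truth$block$spA
  best_at <- vapply(0:2, function(mg) {
    m <- find_syntenic_regions(g, "spA", q, "spC", max_gaps = mg)
    if (nrow(m)) max(m$score) else -Inf
  }, numeric(1))
  expect_true(all(diff(best_at) >= 0))
})
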