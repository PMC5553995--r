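chain_graph <- function() {
  g <- property_graph()
  for (t in c("A", "B", "C")) upsert_node(g, t, "GOTerm")
  upsert_edge(g, "A", "B", "IS_A")
  upsert_edge(g, "B", "C", "IS_A")
  upsert_node(g, "gene1", "Gene")
  upsert_edge(g, "gene1", "A", "HAS_GO_TERM")
  g
}

test_that("effective term sets are the transitive is_a closure", {
  g <- chain_graph()
  expect_identical(effective_go_terms(g, "gene1"), c("A", "B", "C"))
  expect_identical(effective_go_terms(g, upsert_node(g, "lonely", "Gene")),
                   character(0))
})

test_that("querying a parent term returns genes annotated only to its child", {
  res <- build_fixture_graph(71, layers = c("genome", "annotation", "ontology"))
  g <- res$graph; fx <- res$fx
  anc <- ontology_ancestors(g)
  parent <- fx$truth$domain_parent_term
  genes <- Filter(function(x) parent %in% effective_go_terms(g, x, anc),
                  node_ids(g, "Gene"))
  expect_identical(sort(genes), sort(fx$truth$fig_domain_genes))
})

test_that("ancestor sets equal a BFS oracle on random DAGs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 20
    g <- property_graph()
    terms <- sprintf("T%02d", 1:n)
    for (t in terms) upsert_node(g, t, "GOTerm")
    parents_of <- stats::setNames(vector("list", n), terms)
    for (i in 2:n) {
      ps <- sample(terms[seq_len(i - 1)], sample(0:min(2, i - 1), 1))  # edges point to
      parents_of[[terms[i]]] <- ps                          # earlier terms: acyclic
      for (p in ps) upsert_edge(g, terms[i], p, "IS_A")
    }
    anc <- ontology_ancestors(g)
    for (t in terms) {
      expect_identical(anc[[t]], closure_oracle(parents_of, t))
    }
  }
})

test_that("is_a cycles abort naming the cycle", {
  g <- property_graph()
  for (t in c("X", "Y", "Z")) upsert_node(g, t, "GOTerm")
  upsert_edge(g, "X", "Y", "IS_A")
  upsert_edge(g, "Y", "Z", "IS_A")
  upsert_edge(g, "Z", "X", "IS_A")
  expect_error(ontology_ancestors(g), "cycle.*X")
})

test_that("propagation is idempotent and materialized edges are marked inferred", {
  g <- chain_graph()
  n1 <- propagate_ontology(g, materialize = TRUE)
  expect_equal(n1, 2L)  # B and C implied
  e_before <- n_edges(g)
  n2 <- propagate_ontology(g, materialize = TRUE)
  expect_equal(n2, n1)
  expect_equal(n_edges(g), e_before)
  expect_identical(neighbor_ids(g, "gene1", "INFERRED_GO_TERM", "out"),
                   c("B", "C"))
  # direct and inferred stay distinguishable
  expect_identical(neighbor_ids(g, "gene1", "HAS_GO_TERM", "out"), "A")
})

test_that("homolog transfer is one hop, provenance-stamped and opt-in", {
  g <- property_graph()
  for (x in c("g", "h", "h2")) upsert_node(g, x, "Gene")
  upsert_node(g, "t", "GOTerm")
  upsert_node(g, "PF1", "Domain")
  upsert_edge(g, "g", "h", "RECIPROCAL_BEST_HIT", list(bsr = 0.9))
  upsert_edge(g, "h", "h2", "RECIPROCAL_BEST_HIT", list(bsr = 0.9))
  upsert_edge(g, "h", "t", "HAS_GO_TERM")
  upsert_edge(g, "h2", "PF1", "HAS_DOMAIN")
  inf <- infer_from_homolog(g, "g")
  expect_equal(nrow(inf), 1L)  # h's term, never h2's domain (2 hops away)
  expect_identical(inf$annotation_id, "t")
  expect_identical(inf$path, "g -> h -> t")
  expect_equal(inf$bsr, 0.9)
  # nothing written unless asked
  expect_length(neighbor_ids(g, "g", "INFERRED_GO_TERM", "out"), 0L)
  infer_from_homolog(g, "g", write = TRUE)
  e <- omicsgraph:::get_edge(g, "g", "t", "INFERRED_GO_TERM")
  expect_identical(e$attributes$source_gene, "h")
  expect_identical(e$attributes$via, "RECIPROCAL_BEST_HIT")
  # BSR floor is respected
  upsert_node(g, "weak", "Gene")
  upsert_node(g, "t2", "GOTerm")
  upsert_edge(g, "g", "weak", "BEST_HIT", list(bsr = 0.1))
  upsert_edge(g, "weak", "t2", "HAS_GO_TERM")
  expect_false("t2" %in% infer_from_homolog(g, "g")$annotation_id)
  expect_error(infer_from_homolog(g, "ghost"), "unknown gene")
})

test_that("planted homolog transfer matches the hand-computed table", {
  res <- build_fixture_graph(72, layers = c("genome", "homology", "annotation"))
  g <- res$graph
  # spB_g01 is unannotated; its RBH partners spA_g01 (PF00002, GO:0000007)
  # and spC_g01 (unannotated) imply exactly one GO and one domain transfer
  inf <- infer_from_homolog(g, "spB_g01")
  expect_identical(inf$annotation_id[inf$annotation_type == "go"], "GO:0000007")
  expect_identical(inf$annotation_id[inf$annotation_type == "domain"], "PF00002")
  expect_identical(unique(inf$source_gene), "spA_g01")
})
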