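toy_features <- function(starts, ends, landmark = "chr1",
                         ids = sprintf("g%d", seq_along(starts))) {
  out <- data.frame(feature_id = ids, landmark = landmark, start = starts,
                    end = ends, strand = "+", ftype = "gene",
                    parent_id = NA_character_, stringsAsFactors = FALSE)
  out$attributes <- replicate(length(ids), list(), simplify = FALSE)
  out
}

test_that("gene-order backbone chains genes by start within each landmark", {
  g <- property_graph()
  s <- import_genome(g, "sp", toy_features(c(0L, 500L, 900L),
                                           c(100L, 600L, 1000L)))
  expect_equal(unname(s[c("Gene", "Landmark", "NEXT_GENE")]), c(3L, 1L, 2L))
  expect_identical(neighbor_ids(g, "g1", "NEXT_GENE", "out"), "g2")
  expect_identical(neighbor_ids(g, "g2", "NEXT_GENE", "out"), "g3")

  g2 <- property_graph()
  f <- rbind(toy_features(c(0L, 500L), c(100L, 600L), "chr1", c("a1", "a2")),
             toy_features(c(0L, 500L), c(100L, 600L), "chr2", c("b1", "b2")))
  import_genome(g2, "sp", f)
  # no NEXT_GENE edge crosses landmarks
  e <- graph_edges(g2)
  ng <- e[e$rel_type == "NEXT_GENE", ]
  lm_of <- function(id) node_attr(g2, id, "landmark")
  expect_true(all(mapply(function(a, b) lm_of(a) == lm_of(b),
                         ng$source, ng$target)))
  expect_equal(nrow(ng), 2L)
  expect_error(import_genome(property_graph(), "sp",
                             toy_features(c(0L, 5L), c(2L, 9L),
                                          ids = c("x", "x"))),
               "duplicate gene id")
})

test_that("NEXT_GENE count is genes-minus-one per landmark, in start order", {
  res <- build_fixture_graph(21, layers = "genome")
  g <- res$graph
  for (sp in names(res$fx$species)) {
    ord <- gene_order(g, sp)
    for (lm in names(ord)) {
      ids <- ord[[lm]]
      starts <- vapply(ids, function(x) as.numeric(node_attr(g, x, "start")),
                       numeric(1))
      expect_false(is.unsorted(starts, strictly = TRUE))
      for (i in seq_len(length(ids) - 1L)) {
        expect_identical(neighbor_ids(g, ids[i], "NEXT_GENE", "out"),
                         ids[i + 1L])
      }
    }
  }
})

test_that("importers are idempotent on node and edge counts", {
  res <- build_fixture_graph(22)
  g <- res$graph; fx <- res$fx
  n0 <- n_nodes(g); e0 <- n_edges(g)
  for (sp in names(fx$species)) {
    import_genome(g, sp, fx$species[[sp]]$features, fx$species[[sp]]$sequences)
  }
  import_functional_annotations(g, do.call(rbind, fx$domains))
  import_ontology(g, fx$ontology)
  import_relationship_tuples(g, fx$pathways, target_label = "Pathway")
  build_coexpression(g, fx$expression, min_abs_r = 0.8)
  expect_equal(n_nodes(g), n0)
  expect_equal(n_edges(g), e0)
})

test_that("a shared domain is one node reused across species", {
  res <- build_fixture_graph(23, layers = c("genome", "annotation"))
  g <- res$graph
  expect_true(has_node(g, "PF00001"))
  carriers <- neighbor_ids(g, "PF00001", "HAS_DOMAIN", "in")
  expect_identical(carriers, sort(res$fx$truth$fig_domain_genes))
  sp <- unique(vapply(carriers, function(x) node_attr(g, x, "species"),
                      character(1)))
  expect_length(sp, 2L)  # two species share the domain node
})

test_that("hits without GO terms yield only HAS_DOMAIN edges; unresolvable ids skip", {
  g <- property_graph()
  import_genome(g, "sp", toy_features(0L, 100L, ids = "gA"))
  hits <- data.frame(protein_id = c("gA.1", "ghost.1"), analysis = "Pfam",
                     signature_acc = "PF9", signature_desc = "d",
                     start = 1L, stop = 10L, score = 1.0,
                     interpro_acc = NA_character_, stringsAsFactors = FALSE)
  hits$go_terms <- list(character(0), character(0))
  expect_warning(s <- import_functional_annotations(g, hits), "ghost")
  expect_equal(unname(s[c("HAS_DOMAIN", "HAS_GO_TERM", "skipped")]),
               c(1L, 0L, 1L))
  expect_identical(neighbor_ids(g, "gA", "HAS_DOMAIN", "out"), "PF9")
})

test_that("ontology import enriches GO stubs created by annotation import", {
  res <- build_fixture_graph(24, layers = c("genome", "annotation"))
  g <- res$graph
  expect_true(isTRUE(node_attr(g, "GO:0000003", "stub")))
  s <- import_ontology(g, res$fx$ontology)
  expect_equal(unname(s[c("GOTerm", "IS_A")]), c(7L, 6L))
  expect_false(isTRUE(node_attr(g, "GO:0000003", "stub")))
  expect_identical(node_attr(g, "GO:0000003", "name"),
                   "specialized cell differentiation")
})

test_that("relationship tuples create labeled endpoints without duplication", {
  g <- property_graph()
  fx <- generate_multi_species_fixture(25)
  s <- import_relationship_tuples(g, fx$pathways, target_label = "Pathway")
  expect_equal(unname(s["edges"]), 10L)
  expect_length(node_ids(g, "Pathway"), 2L)
  e0 <- n_edges(g)
  import_relationship_tuples(g, fx$pathways, target_label = "Pathway")
  expect_equal(n_edges(g), e0)
  s_empty <- import_relationship_tuples(g, fx$pathways[0, ])
  expect_equal(unname(s_empty["edges"]), 0L)
})

test_that("queries over never-imported layers return empty results, not errors", {
  res <- build_fixture_graph(26, layers = "genome")  # genes only
  g <- res$graph
  expect_equal(nrow(go_enrichment(g, c("spA_g01", "spA_g02"))), 0L)
  expect_equal(nrow(coexpression_neighborhood(g, "spA_g01")), 0L)
  expect_equal(nrow(list_orthologs(g, "spA_g01")), 0L)
  expect_equal(nrow(infer_from_homolog(g, "spA_g01")), 0L)
  snp <- annotate_gwas(g, data.frame(snp_id = "s", landmark = "spA:chr1",
                                     position = 5L, stringsAsFactors = FALSE))
  expect_false(is.na(snp$nearest_gene_id[1]))
  expect_length(snp$gene_go_terms[[1]], 0L)
  expect_length(snp$expression[[1]], 0L)
  rep <- gene_report(g, "spA_g01")
  expect_equal(nrow(rep$homology), 0L)
})
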