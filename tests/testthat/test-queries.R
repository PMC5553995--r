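enrichment_toy <- function(N = 10, members = 1:5) {
  g <- property_graph()
  ids <- sprintf("g%02d", seq_len(N))
  for (i in seq_len(N)) upsert_node(g, ids[i], "Gene", list(species = "sp"))
  upsert_node(g, "T1", "GOTerm", list(name = "term one"))
  for (i in members) upsert_edge(g, ids[i], "T1", "HAS_GO_TERM")
  list(graph = g, ids = ids)
}

test_that("hypergeometric p matches the exact draw fraction", {
  # N=10, K=5, n=3, k=3: 10 of the 120 draws are all-term
  toy <- enrichment_toy()
  e <- go_enrichment(toy$graph, toy$ids[1:3])
  expect_equal(e$p_value[e$term_id == "T1"], 10 / 120, tolerance = 1e-12)
  expect_equal(e$k[e$term_id == "T1"], 3L)
  expect_equal(e$K[e$term_id == "T1"], 5L)
  # a term annotating every background gene is never enriched
  toy2 <- enrichment_toy(members = 1:10)
  e2 <- go_enrichment(toy2$graph, toy2$ids[1:3])
  expect_equal(e2$p_value[e2$term_id == "T1"], 1.0)
  expect_error(go_enrichment(toy$graph, character(0)), "empty")
})

test_that("enrichment p-values equal the enumeration oracle on random cases", {
  for (seed in 1:6) {
    set.seed(seed)
    N <- 15
    g <- property_graph()
    ids <- sprintf("g%02d", 1:N)
    for (id in ids) upsert_node(g, id, "Gene", list(species = "sp"))
    terms <- sprintf("T%d", 1:4)
    membership <- list()
    for (t in terms) {
      upsert_node(g, t, "GOTerm")
      members <- sort(sample(N, sample(2:8, 1)))
      membership[[t]] <- members
      for (i in members) upsert_edge(g, ids[i], t, "HAS_GO_TERM")
    }
    n_query <- sample(2:4, 1)
    query_idx <- sort(sample(N, n_query))
    res <- go_enrichment(g, ids[query_idx])
    for (row in seq_len(nrow(res))) {
      t <- res$term_id[row]
      want <- enrichment_enum_oracle(N, membership[[t]], n_query,
                                     res$k[row])
      expect_equal(res$p_value[row], want, tolerance = 1e-12)
    }
    # BH-adjusted values are nondecreasing along the p-sorted rows after
    # the cumulative-minimum step
    expect_true(all(diff(res$p_value) >= 0 | diff(res$adj_p) >= 0))
    expect_true(all(res$adj_p >= res$p_value - 1e-15))
    expect_identical(res$adj_p,
                     stats::p.adjust(res$p_value, method = "BH"))
  }
})

test_that("nearest genes follow half-open distances with id tie-breaks", {
  g <- property_graph()
  f <- data.frame(feature_id = c("ga", "gb"), landmark = "chr1",
                  start = c(0L, 300L), end = c(100L, 400L), strand = "+",
                  ftype = "gene", parent_id = NA_character_,
                  stringsAsFactors = FALSE)
  f$attributes <- replicate(2, list(), simplify = FALSE)
  import_genome(g, "sp", f)
  inside <- nearest_genes(g, "sp:chr1", 50L)
  expect_identical(inside$gene_id, "ga")
  expect_equal(inside$distance, 0L)
  expect_true(inside$genic)
  # position 199 is 100 bases from ga's last base (99) and 101 from gb;
  # position 200 is 101 vs 100; midway ties are broken by id
  expect_identical(nearest_genes(g, "sp:chr1", 199L)$gene_id, "ga")
  expect_identical(nearest_genes(g, "sp:chr1", 200L)$gene_id, "gb")
  tie <- nearest_genes(g, "sp:chr1", 199L, k = 2L)
  expect_identical(tie$gene_id, c("ga", "gb"))
  expect_error(nearest_genes(g, "nope", 1L), "unknown landmark")
})

test_that("nearest genes agree with the linear-scan oracle on random SNPs", {
  res <- build_fixture_graph(81, layers = "genome")
  g <- res$graph
  feats <- res$fx$species$spA$features
  set.seed(81)
  positions <- sample(0:max(feats$end + 500L), 200L)
  for (pos in positions) {
    got <- nearest_genes(g, "spA:chr1", pos)
    want <- nearest_oracle(feats$start, feats$end, feats$feature_id, pos)
    expect_identical(got$gene_id[1], want$gene)
    expect_equal(got$distance[1], as.integer(want$distance))
  }
})

test_that("GWAS annotation combines layers and degrades per row", {
  res <- build_fixture_graph(82)
  g <- res$graph; fx <- res$fx
  ann <- annotate_gwas(g, fx$snps)
  expect_identical(ann$nearest_gene_id, fx$truth$snp_truth$nearest)
  expect_equal(ann$distance, fx$truth$snp_truth$distance)
  expect_identical(ann$genic, fx$truth$snp_truth$genic)
  expect_identical(ann$genic, ann$distance == 0L)
  # a genic SNP in an EC/GO-annotated, expressed gene carries all layers
  i <- which(ann$nearest_gene_id == "spA_g01")[1]
  expect_true("GO:0000007" %in% ann$gene_go_terms[[i]])
  expect_true("GO:0000005" %in% ann$gene_go_terms[[i]])  # is_a ancestor
  expect_identical(ann$gene_ec_numbers[[i]], "EC:1.1.1.1")
  expect_length(ann$expression[[i]], 6L)
  # unknown landmark: per-row error, run continues
  bad <- rbind(fx$snps[1, ],
               data.frame(snp_id = "sX", landmark = "noman", position = 1L))
  ann2 <- annotate_gwas(g, bad)
  expect_true(is.na(ann2$error[1]) && !is.na(ann2$error[2]))
  expect_equal(nrow(annotate_gwas(g, fx$snps[0, ])), 0L)
})

test_that("presence-absence lists focal genes with the full term profile", {
  res <- build_fixture_graph(83)
  g <- res$graph
  pa <- comparative_presence_absence(g, "GO:0000002", "spA", c("spB", "spC"))
  expect_identical(sort(pa$gene_id), c("spA_g05", "spA_g06"))
  expect_identical(pa$spB[pa$gene_id == "spA_g05"], "spB_g05")
  expect_identical(pa$spC[pa$gene_id == "spA_g05"], "spC_g05")
  # two terms jointly: no spA gene carries both chains
  pa2 <- comparative_presence_absence(g, c("GO:0000002", "GO:0000007"),
                                      "spA", "spB")
  expect_equal(nrow(pa2), 0L)
  expect_error(comparative_presence_absence(g, "GO:9999999", "spA", "spB"),
               "unknown term")
})

test_that("gene reports summarize every layer deterministically", {
  res <- build_fixture_graph(84)
  g <- res$graph
  rep <- gene_report(g, "spA_g05")
  expect_equal(sum(rep$relationships$count[rep$relationships$rel_type ==
                                             "HAS_DOMAIN"]), 1L)
  expect_identical(rep$go_direct, "GO:0000003")
  expect_true(all(c("GO:0000001", "GO:0000002") %in% rep$go_inferred))
  expect_equal(sum(rep$homology$rel_type == "RECIPROCAL_BEST_HIT"), 2L)
  expect_true(all(!is.na(rep$homology$bsr[rep$homology$rel_type ==
                                            "BLASTP_HIT"])))
  out1 <- utils::capture.output(print(rep))
  out2 <- utils::capture.output(print(gene_report(g, "spA_g05")))
  expect_identical(out1, out2)
  # isolated gene: all sections present and empty
  upsert_node(g, "hermit", "Gene")
  rep2 <- gene_report(g, "hermit")
  expect_equal(nrow(rep2$relationships), 0L)
  expect_length(rep2$go_direct, 0L)
  expect_equal(nrow(rep2$homology), 0L)
  expect_error(gene_report(g, "nobody"), "unknown node")
})

test_that("biological processes and ortholog listings read the graph", {
  res <- build_fixture_graph(85)
  g <- res$graph
  bp <- biological_processes(g, "spA_g01")
  expect_true(all(c("GO:0000007", "GO:0000006", "GO:0000005") %in% bp$term_id))
  orth <- list_orthologs(g, c("spA_g01", "spA_s01"))
  expect_identical(sort(orth$ortholog_id), c("spB_g01", "spC_g01"))
  expect_identical(sort(unique(orth$species)), c("spB", "spC"))
})
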