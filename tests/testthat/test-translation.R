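version_pair_graphs <- function(fx) {
  go <- property_graph()
  import_genome(go, "v_old", fx$features_old, fx$sequences_old)
  gn <- property_graph()
  import_genome(gn, "v_new", fx$features_new, fx$sequences_new)
  list(old = go, new = gn)
}

test_that("candidate lists carry BSR and coverage per event shape", {
  fx <- generate_genome_version_pair(seed = 41)
  gs <- version_pair_graphs(fx)
  qlen <- fx$self_scores / 2
  slen <- stats::setNames(nchar(fx$sequences_new), names(fx$sequences_new))
  cands <- candidate_matches(fx$hits, qlen, slen, fx$self_scores)
  truth <- fx$truth
  # renamed-only gene: one candidate at bsr 1, full mutual coverage
  ren <- truth$old_id[truth$status == "one_to_one"][1]
  expect_equal(cands[[ren]]$bsr[1], 1.0)
  expect_equal(cands[[ren]]$q_cov[1], 1.0)
  expect_equal(cands[[ren]]$s_cov[1], 1.0)
  # split gene: two half-coverage candidates, each covering its full self
  sp <- truth$old_id[truth$status == "split"][1]
  cc <- cands[[sp]]
  expect_equal(nrow(cc), 2L)
  expect_equal(sort(cc$q_cov), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(cc$s_cov, c(1, 1))
  expect_equal(cc$bsr, c(0.5, 0.5), tolerance = 1e-9)
  # deleted gene: no candidates at all
  del <- truth$old_id[truth$status == "missing"][1]
  expect_null(cands[[del]])
})

test_that("synteny support resolves planted duplicates and ties stay ambiguous", {
  fx <- generate_genome_version_pair(seed = 42)
  gs <- version_pair_graphs(fx)
  calls <- suppressWarnings(
    translate_gene_list(gs$old, gs$new, fx$hits, fx$truth$old_id,
                        fx$self_scores, write_edges = FALSE))
  # the duplicate family resolved by neighbors has positive support
  dup_rows <- which(calls$status == "one_to_one" &
                      !is.na(calls$neighbor_support))
  expect_true(length(dup_rows) >= 1)
  expect_true(all(calls$neighbor_support[dup_rows] >= 1))
  # the planted equal-support family is ambiguous
  amb <- fx$truth$old_id[fx$truth$status == "ambiguous"]
  expect_identical(calls$status[match(amb, calls$old_id)],
                   rep("ambiguous", length(amb)))
  # direct use of the disambiguation operation on the planted tie
  amb_cands <- fx$truth$new_ids[[match(amb[1], fx$truth$old_id)]]
  d <- disambiguate_by_synteny(gs$old, gs$new, amb[1], amb_cands,
                               winners = stats::setNames(
                                 vapply(calls$new_ids[calls$status == "one_to_one"],
                                        `[`, character(1), 1),
                                 calls$old_id[calls$status == "one_to_one"]))
  expect_true(is.na(d$choice))
  expect_equal(unname(d$support[1]), unname(d$support[2]))
  # a window larger than the landmark is clamped, not an error
  d2 <- disambiguate_by_synteny(gs$old, gs$new, amb[1], amb_cands,
                                window = 10000L)
  expect_true(is.na(d2$choice))
})

test_that("planted translation events are recovered exactly across seeds", {
  for (seed in c(43, 44, 45)) {
    fx <- generate_genome_version_pair(seed = seed)
    gs <- version_pair_graphs(fx)
    calls <- suppressWarnings(
      translate_gene_list(gs$old, gs$new, fx$hits, fx$truth$old_id,
                          fx$self_scores))
    expect_identical(calls$status, fx$truth$status)
    resolved <- calls$status %in% c("one_to_one", "split", "merge")
    expect_true(all(mapply(function(a, b) identical(sort(a), sort(b)),
                           calls$new_ids[resolved],
                           fx$truth$new_ids[resolved])))
    # TRANSLATES_TO edges written with the status attribute
    one <- calls$old_id[calls$status == "one_to_one"][1]
    e <- omicsgraph:::get_edge(gs$old, one, calls$new_ids[[match(one, calls$old_id)]],
                               "TRANSLATES_TO")
    expect_identical(e$attributes$status, "one_to_one")
  }
})

test_that("an identity version change yields pure one-to-one calls", {
  fx <- generate_genome_version_pair(seed = 46, n_genes = 25, n_splits = 0,
                                     n_merges = 0, n_missing = 0,
                                     n_dup_families = 0, n_ambiguous = 0,
                                     n_insertions = 0)
  gs <- version_pair_graphs(fx)
  calls <- translate_gene_list(gs$old, gs$new, fx$hits, fx$truth$old_id,
                               fx$self_scores, write_edges = FALSE)
  expect_identical(unique(calls$status), "one_to_one")
})

test_that("calls are stable under permutation of the hit table", {
  fx <- generate_genome_version_pair(seed = 47)
  gs <- version_pair_graphs(fx)
  base <- suppressWarnings(
    translate_gene_list(gs$old, gs$new, fx$hits, fx$truth$old_id,
                        fx$self_scores, write_edges = FALSE))
  set.seed(1)
  shuffled <- fx$hits[sample.int(nrow(fx$hits)), , drop = FALSE]
  perm <- suppressWarnings(
    translate_gene_list(gs$old, gs$new, shuffled, fx$truth$old_id,
                        fx$self_scores, write_edges = FALSE))
  expect_identical(perm$status, base$status)
  expect_identical(perm$new_ids, base$new_ids)
})

test_that("unknown ids become per-id error rows and empty input works", {
  fx <- generate_genome_version_pair(seed = 48)
  gs <- version_pair_graphs(fx)
  calls <- suppressWarnings(
    translate_gene_list(gs$old, gs$new, fx$hits,
                        c(fx$truth$old_id[1], "no_such_gene"),
                        fx$self_scores, write_edges = FALSE))
  expect_identical(calls$status, c(fx$truth$status[1], "error"))
  empty <- translate_gene_list(gs$old, gs$new, fx$hits, character(0),
                               fx$self_scores, write_edges = FALSE)
  expect_equal(nrow(empty), 0L)
})

test_that("translation reports round-trip through the TSV writer", {
  fx <- generate_genome_version_pair(seed = 49)
  gs <- version_pair_graphs(fx)
  calls <- suppressWarnings(
    translate_gene_list(gs$old, gs$new, fx$hits, fx$truth$old_id,
                        fx$self_scores, write_edges = FALSE))
  tf <- tempfile()
  write_translation_report(calls, tf)
  back <- utils::read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(calls))
  expect_identical(back$status, calls$status)
})
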