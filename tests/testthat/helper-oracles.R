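# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle recomputes a quantity from raw inputs by the most
# direct method available, never through the code path it checks.

# random labeled graph plus its raw edge list
random_graph_case <- function(seed, n_nodes = 50, n_edges = 120) {
  set.seed(seed)
  g <- property_graph()
  ids <- sprintf("n%02d", seq_len(n_nodes))
  labels <- c("Gene", "Protein", "GOTerm", "Domain")
  rels <- c("HAS_DOMAIN", "HAS_GO_TERM", "BLASTP_HIT", "IS_A")
  for (id in ids) upsert_node(g, id, sample(labels, 1))
  src <- sample(ids, n_edges, replace = TRUE)
  tgt <- sample(ids, n_edges, replace = TRUE)
  rel <- sample(rels, n_edges, replace = TRUE)
  for (i in seq_len(n_edges)) upsert_edge(g, src[i], tgt[i], rel[i])
  edges <- unique(data.frame(source = src, target = tgt, rel_type = rel,
                             stringsAsFactors = FALSE))
  list(graph = g, ids = ids, edges = edges)
}

# neighbors by scanning the raw edge list
neighbors_oracle <- function(edges, v, rel_type = NULL, direction = "both") {
  out <- character(0)
  if (direction %in% c("out", "both")) {
    sel <- edges$source == v
    if (!is.null(rel_type)) sel <- sel & edges$rel_type %in% rel_type
    out <- c(out, edges$target[sel])
  }
  if (direction %in% c("in", "both")) {
    sel <- edges$target == v
    if (!is.null(rel_type)) sel <- sel & edges$rel_type %in% rel_type
    out <- c(out, edges$source[sel])
  }
  sort(out)
}

# random directional similarity tables between two gene sets
random_hit_tables <- function(seed, n_a = 30, n_b = 30, density = 0.25) {
  set.seed(seed)
  a <- sprintf("a%02d", seq_len(n_a)); b <- sprintf("b%02d", seq_len(n_b))
  mk <- function(qs, ss) {
    rows <- expand.grid(query_id = qs, subject_id = ss,
                        stringsAsFactors = FALSE)
    rows <- rows[stats::runif(nrow(rows)) < density, , drop = FALSE]
    n <- nrow(rows)
    data.frame(rows,
               pct_identity = round(stats::runif(n, 40, 100), 1),
               aln_length = sample(50:500, n, replace = TRUE),
               mismatches = 0L, gap_opens = 0L, q_start = 1L, q_end = 10L,
               s_start = 1L, s_end = 10L,
               evalue = 10^-sample(6:100, n, replace = TRUE),
               bit_score = sample(50:900, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  list(ab = mk(a, b), ba = mk(b, a), a = a, b = b)
}

# per-query argmax straight over the raw table, same tie chain
best_hit_oracle <- function(hits, evalue_max = 1e-5) {
  h <- hits[hits$query_id != hits$subject_id & hits$evalue <= evalue_max, ,
            drop = FALSE]
  out <- character(0)
  for (q in sort(unique(h$query_id))) {
    sub <- h[h$query_id == q, , drop = FALSE]
    sub <- sub[sub$bit_score == max(sub$bit_score), , drop = FALSE]
    sub <- sub[sub$evalue == min(sub$evalue), , drop = FALSE]
    sub <- sub[sub$pct_identity == max(sub$pct_identity), , drop = FALSE]
    out[q] <- sort(sub$subject_id)[1]
  }
  out
}

rbh_oracle <- function(hits_ab, hits_ba, evalue_max = 1e-5) {
  fwd <- best_hit_oracle(hits_ab, evalue_max)
  rev <- best_hit_oracle(hits_ba, evalue_max)
  pairs <- character(0)
  for (a in names(fwd)) {
    b <- fwd[[a]]
    if (!is.na(rev[b]) && identical(unname(rev[b]), a)) {
      pairs <- c(pairs, paste(a, b, sep = "|"))
    }
  }
  sort(pairs)
}

# transitive is_a closure by BFS over a raw parent edge list
closure_oracle <- function(parents_of, term) {
  seen <- character(0)
  queue <- parents_of[[term]]
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, parents_of[[t]])
  }
  sort(unique(seen))
}

# enrichment p by exhaustive enumeration of all size-n draws
enrichment_enum_oracle <- function(N, term_members, query_size, k_obs) {
  draws <- utils::combn(N, query_size)
  hits <- apply(draws, 2, function(d) sum(d %in% term_members))
  mean(hits >= k_obs)
}

# nearest genes by direct linear scan, same half-open distance convention
nearest_oracle <- function(starts, ends, ids, pos) {
  d <- ifelse(pos >= starts & pos < ends, 0,
              ifelse(pos < starts, starts - pos, pos - (ends - 1)))
  ord <- order(d, ids)
  list(gene = ids[ord][1], distance = d[ord][1])
}

# best syntenic score per (landmark scan) by full enumeration of spans and
# order-preserving pairings
synteny_oracle_best <- function(homolog_sets, tg, max_gaps) {
  m <- length(homolog_sets); n <- length(tg)
  best <- -Inf
  for (s in seq_len(n)) for (e in s:n) {
    span <- e - s + 1L
    if (span > m + max_gaps) next
    # enumerate subsets of query indices and increasing target assignments
    for (size in seq_len(min(m, span))) {
      qsets <- utils::combn(m, size, simplify = FALSE)
      tsets <- utils::combn(s:e, size, simplify = FALSE)
      for (qs in qsets) for (ts in tsets) {
        if (ts[1] != s || ts[length(ts)] != e) next
        ok <- all(vapply(seq_len(size), function(i)
          tg[ts[i]] %in% homolog_sets[[qs[i]]], logical(1)))
        if (!ok) next
        deletions <- m - size
        insertions <- span - size
        if (deletions > max_gaps || insertions > max_gaps) next
        best <- max(best, size - 0.5 * (insertions + deletions))
      }
    }
  }
  best
}

# small two-species graph with homology edges, from the planted fixture
build_fixture_graph <- function(seed = 101, layers = c("genome", "homology",
                                                       "annotation",
                                                       "ontology",
                                                       "expression",
                                                       "generic")) {
  fx <- generate_multi_species_fixture(seed)
  g <- property_graph()
  if ("genome" %in% layers) {
    for (sp in names(fx$species)) {
      import_genome(g, sp, fx$species[[sp]]$features, fx$species[[sp]]$sequences)
    }
  }
  if ("homology" %in% layers) {
    for (pr in utils::combn(names(fx$species), 2, simplify = FALSE)) {
      write_homology_edges(g, fx$hits[[paste0(pr[1], "__vs__", pr[2])]],
                           fx$hits[[paste0(pr[2], "__vs__", pr[1])]],
                           fx$self_scores[[pr[1]]], fx$self_scores[[pr[2]]])
    }
  }
  if ("annotation" %in% layers) {
    import_functional_annotations(g, do.call(rbind, fx$domains))
  }
  if ("ontology" %in% layers) import_ontology(g, fx$ontology)
  if ("expression" %in% layers) {
    build_coexpression(g, fx$expression, min_abs_r = 0.8)
  }
  if ("generic" %in% layers) {
    import_relationship_tuples(g, fx$pathways, target_label = "Pathway")
    import_relationship_tuples(g, fx$ec, target_label = "ECNumber")
  }
  list(graph = g, fx = fx)
}

# full structural signature (nodes, labels, attributes, edges with
# attributes) for round-trip identity checks
graph_signature <- function(g) {
  nodes <- lapply(node_ids(g), function(id) {
    n <- get_node(g, id)
    n$attributes <- n$attributes[order(names(n$attributes))]
    n
  })
  edges <- graph_edges(g)
  edges <- edges[order(edges$source, edges$target, edges$rel_type), ,
                 drop = FALSE]
  eattrs <- lapply(seq_len(nrow(edges)), function(i) {
    a <- g$edges[[paste(edges$source[i], edges$target[i], edges$rel_type[i],
                        sep = "\x1f")]]$attributes
    a[order(names(a))]
  })
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges, edge_attrs = eattrs)
}
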