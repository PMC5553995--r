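#' GO term enrichment for a gene list
#'
#' One-sided hypergeometric (Fisher upper tail) test per term: with `N`
#' background genes of which `K` carry the term, and `n` query genes of
#' which `k` carry it, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Term membership uses effective term sets
#' (direct annotation plus `is_a` ancestors). Every term with `k >= 1` in
#' the query is tested and forms the Benjamini-Hochberg family. Rows are
#' ordered by p-value, then term id.
#'
#' @param graph A [property_graph()].
#' @param gene_ids Query gene ids (non-empty, or an input error).
#' @param namespace Optional ontology namespace filter (e.g.
#'   `"biological_process"`), matched against the term node's `namespace`
#'   attribute.
#' @param background Optional background gene set; defaults to all genes
#'   of the query genes' species.
#' @return Data frame `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `adj_p`.
#' @export
go_enrichment <- function(graph, gene_ids, namespace = NULL, background = NULL) {
  if (length(gene_ids) == 0) stop("query gene list is empty", call. = FALSE)
  gene_ids <- unique(gene_ids)
  for (g in gene_ids) {
    if (!has_node(graph, g)) stop(sprintf("unknown gene '%s'", g), call. = FALSE)
  }
  if (is.null(background)) {
    sp <- unique(vapply(gene_ids, function(g)
      as.character(node_attr(graph, g, "species", NA_character_)), character(1)))
    sp <- sp[!is.na(sp)]
    all_genes <- node_ids(graph, "Gene")
    background <- if (length(sp)) {
      all_genes[vapply(all_genes, function(g)
        isTRUE(node_attr(graph, g, "species") %in% sp), logical(1))]
    } else all_genes
  }
  background <- unique(c(background, gene_ids))
  ancestors <- ontology_ancestors(graph)
  sets <- lapply(stats::setNames(background, background), function(g)
    effective_go_terms(graph, g, ancestors))
  if (!is.null(namespace)) {
    keep_term <- function(t) isTRUE(node_attr(graph, t, "namespace") == namespace)
    sets <- lapply(sets, function(ts) ts[vapply(ts, keep_term, logical(1))])
  }
  N <- length(background)
  n <- length(gene_ids)
  query_terms <- sort(unique(unlist(sets[gene_ids], use.names = FALSE)))
  if (!length(query_terms)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0), adj_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  k <- vapply(query_terms, function(t)
    sum(vapply(sets[gene_ids], function(ts) t %in% ts, logical(1))), integer(1))
  K <- vapply(query_terms, function(t)
    sum(vapply(sets, function(ts) t %in% ts, logical(1))), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  nm <- vapply(query_terms, function(t)
    as.character(node_attr(graph, t, "name", "")), character(1))
  out <- data.frame(term_id = query_terms, term_name = nm, k = k, n = n,
                    K = K, N = N, p_value = p, adj_p = adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Nearest genes to a genomic position
#'
#' Distances are edge-to-edge on 0-based half-open gene intervals: 0 when
#' the position lies inside `[start, end)` (genic), otherwise the gap to
#' the nearest interval edge. Results are ranked by distance, ties broken
#' by gene id.
#'
#' @param graph A [property_graph()].
#' @param landmark Landmark node id (`species:name`), or a bare landmark
#'   name when unique in the graph.
#' @param position 0-based base position.
#' @param k How many genes to return (default 1; ties at the cutoff are
#'   all returned).
#' @return Data frame `gene_id`, `distance`, `genic`.
#' @export
nearest_genes <- function(graph, landmark, position, k = 1L) {
  lm_id <- resolve_landmark(graph, landmark)
  genes <- vapply(neighbors(graph, lm_id, "LOCATED_ON", "in"), `[[`,
                  character(1), "node")
  if (!length(genes)) {
    return(data.frame(gene_id = character(0), distance = integer(0),
                      genic = logical(0), stringsAsFactors = FALSE))
  }
  st <- vapply(genes, function(g) as.numeric(node_attr(graph, g, "start")), numeric(1))
  en <- vapply(genes, function(g) as.numeric(node_attr(graph, g, "end")), numeric(1))
  d <- ifelse(position >= st & position < en, 0,
              ifelse(position < st, st - position, position - (en - 1)))
  ord <- order(d, genes)
  d <- d[ord]; genes <- genes[ord]
  if (length(genes) > k) {
    cut <- d[k]
    keep <- seq_len(max(which(d <= cut)))  # keep ties at the cutoff
    genes <- genes[keep]; d <- d[keep]
  }
  data.frame(gene_id = genes, distance = as.integer(d), genic = d == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

resolve_landmark <- function(graph, landmark) {
  if (has_node(graph, landmark) &&
      "Landmark" %in% get_node(graph, landmark)$labels) {
    return(landmark)
  }
  all_lm <- node_ids(graph, "Landmark")
  hits <- all_lm[vapply(all_lm, function(l)
    identical(node_attr(graph, l, "name"), landmark), logical(1))]
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L) {
    stop(sprintf("landmark name '%s' is ambiguous (%s); use species:name",
                 landmark, paste(hits, collapse = ", ")), call. = FALSE)
  }
  stop(sprintf("unknown landmark '%s'", landmark), call. = FALSE)
}

#' Annotate SNPs with their nearest gene and its annotation layers
#'
#' One row per SNP combining the nearest gene (genic or not, distance in
#' bases) with the gene's effective GO terms, EC numbers (from generic
#' `HAS_EC` relationships) and per-condition expression. Layers that were
#' never imported yield empty columns, never errors; a SNP on an unknown
#' landmark yields a per-row error entry and the run continues.
#'
#' @param graph A [property_graph()].
#' @param snp_table Data frame from [parse_snp_table()] (`snp_id`,
#'   `landmark`, `position` 0-based). The landmark column may be bare
#'   names or `species:name` ids.
#' @return Data frame `snp_id`, `landmark`, `position`, `nearest_gene_id`,
#'   `distance`, `genic`, `error`, plus list-columns `gene_go_terms`,
#'   `gene_ec_numbers` and `expression` (named FPKM list).
#' @export
annotate_gwas <- function(graph, snp_table) {
  n <- nrow(snp_table)
  ancestors <- if (length(node_ids(graph, "GOTerm"))) ontology_ancestors(graph) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    snp <- snp_table[i, ]
    res <- list(snp_id = snp$snp_id, landmark = snp$landmark,
                position = snp$position, nearest_gene_id = NA_character_,
                distance = NA_integer_, genic = NA, error = NA_character_,
                gene_go_terms = character(0), gene_ec_numbers = character(0),
                expression = list())
    ng <- tryCatch(nearest_genes(graph, snp$landmark, snp$position, k = 1L),
                   error = function(e) conditionMessage(e))
    if (is.character(ng)) {
      res$error <- ng
    } else if (nrow(ng)) {
      g <- ng$gene_id[1]
      res$nearest_gene_id <- g
      res$distance <- ng$distance[1]
      res$genic <- ng$genic[1]
      res$gene_go_terms <- if (is.null(ancestors)) character(0) else
        effective_go_terms(graph, g, ancestors)
      res$gene_ec_numbers <- vapply(neighbors(graph, g, "HAS_EC", "out"),
                                    `[[`, character(1), "node")
      expr <- list()
      for (nb in neighbors(graph, g, "EXPRESSED_IN", "out")) {
        cn <- node_attr(graph, nb$node, "name", nb$node)
        expr[[cn]] <- as.numeric(nb$edge$attributes$fpkm)
      }
      res$expression <- expr
    }
    rows[[i]] <- res
  }
  out <- data.frame(
    snp_id = vapply(rows, `[[`, character(1), "snp_id"),
    landmark = vapply(rows, `[[`, character(1), "landmark"),
    position = vapply(rows, `[[`, integer(1), "position"),
    nearest_gene_id = vapply(rows, `[[`, character(1), "nearest_gene_id"),
    distance = vapply(rows, `[[`, integer(1), "distance"),
    genic = vapply(rows, `[[`, logical(1), "genic"),
    error = vapply(rows, `[[`, character(1), "error"),
    stringsAsFactors = FALSE
  )
  out$gene_go_terms <- lapply(rows, `[[`, "gene_go_terms")
  out$gene_ec_numbers <- lapply(rows, `[[`, "gene_ec_numbers")
  out$expression <- lapply(rows, `[[`, "expression")
  out
}

#' Ortholog presence/absence for genes matching a term profile
#'
#' Finds the focal-species genes whose effective GO set contains *all* of
#' `term_ids`, and reports, per other species, the reciprocal-best-hit
#' ortholog or absence — the "which of my genes with this functional
#' profile exist nowhere else" comparative query.
#'
#' @param graph A [property_graph()].
#' @param term_ids GO term ids (all must exist as nodes, else an input
#'   error).
#' @param focal_species Species whose genes are listed.
#' @param other_species Character vector of species to check for
#'   orthologs.
#' @return Data frame with `gene_id` and one character column per other
#'   species (ortholog id, or `NA` when absent).
#' @export
comparative_presence_absence <- function(graph, term_ids, focal_species,
                                         other_species) {
  for (t in term_ids) {
    if (!has_node(graph, t)) stop(sprintf("unknown term '%s'", t), call. = FALSE)
  }
  ancestors <- ontology_ancestors(graph)
  genes <- node_ids(graph, "Gene")
  genes <- genes[vapply(genes, function(g)
    isTRUE(node_attr(graph, g, "species") == focal_species), logical(1))]
  hitg <- genes[vapply(genes, function(g)
    all(term_ids %in% effective_go_terms(graph, g, ancestors)), logical(1))]
  out <- data.frame(gene_id = hitg, stringsAsFactors = FALSE)
  for (sp in other_species) {
    out[[sp]] <- vapply(hitg, function(g) {
      orth <- vapply(neighbors(graph, g, "RECIPROCAL_BEST_HIT", "both"),
                     `[[`, character(1), "node")
      orth <- orth[vapply(orth, function(o)
        isTRUE(node_attr(graph, o, "species") == sp), logical(1))]
      if (length(orth)) sort(orth)[1] else NA_character_
    }, character(1))
  }
  rownames(out) <- NULL
  out
}

#' Gene-level report
#'
#' The everything-about-one-gene view: attributes; relationship counts
#' grouped by type and direction; direct and inferred (is_a-implied) GO
#' terms; and the homology table with BSR, percent identity and e-value
#' per partner. Output is deterministic — re-running prints byte-identical
#' text.
#'
#' @param graph A [property_graph()].
#' @param gene_id Gene id (unknown id is a referential error).
#' @return An object of class `gene_report` with fields `gene_id`,
#'   `attributes`, `relationships` (data frame `rel_type`, `direction`,
#'   `count`), `go_direct`, `go_inferred`, `homology` (data frame).
#' @export
gene_report <- function(graph, gene_id) {
  node <- get_node(graph, gene_id)
  nbs <- neighbors(graph, gene_id, NULL, "both")
  rel <- vapply(nbs, function(x) x$edge$rel_type, character(1))
  dir <- vapply(nbs, `[[`, character(1), "direction")
  relationships <- if (length(rel)) {
    agg <- stats::aggregate(list(count = rel), by = list(rel_type = rel,
                                                         direction = dir),
                            FUN = length)
    agg <- agg[order(agg$rel_type, agg$direction), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(rel_type = character(0), direction = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  go_direct <- sort(unique(vapply(neighbors(graph, gene_id, "HAS_GO_TERM", "out"),
                                  `[[`, character(1), "node")))
  go_all <- if (length(go_direct)) {
    effective_go_terms(graph, gene_id, ontology_ancestors(graph))
  } else character(0)
  go_inferred <- sort(unique(c(
    setdiff(go_all, go_direct),
    vapply(neighbors(graph, gene_id, "INFERRED_GO_TERM", "out"), `[[`,
           character(1), "node"))))
  hom_rows <- list()
  for (nb in neighbors(graph, gene_id, c("BLASTP_HIT", "BEST_HIT",
                                         "RECIPROCAL_BEST_HIT"), "both")) {
    a <- nb$edge$attributes
    hom_rows[[length(hom_rows) + 1L]] <- list(
      partner = nb$node, rel_type = nb$edge$rel_type,
      bsr = if (is.null(a$bsr)) NA_real_ else as.numeric(a$bsr),
      pct_identity = if (is.null(a$pct_identity)) NA_real_ else as.numeric(a$pct_identity),
      evalue = if (is.null(a$evalue)) NA_real_ else as.numeric(a$evalue))
  }
  homology <- data.frame(
    partner = vapply(hom_rows, `[[`, character(1), "partner"),
    rel_type = vapply(hom_rows, `[[`, character(1), "rel_type"),
    bsr = vapply(hom_rows, `[[`, numeric(1), "bsr"),
    pct_identity = vapply(hom_rows, `[[`, numeric(1), "pct_identity"),
    evalue = vapply(hom_rows, `[[`, numeric(1), "evalue"),
    stringsAsFactors = FALSE
  )
  homology <- homology[order(homology$partner, homology$rel_type), , drop = FALSE]
  rownames(homology) <- NULL
  structure(list(gene_id = gene_id, attributes = node$attributes,
                 relationships = relationships, go_direct = go_direct,
                 go_inferred = go_inferred, homology = homology),
            class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf("== gene %s ==\n", x$gene_id))
  cat("attributes:\n")
  for (k in sort(names(x$attributes))) {
    cat(sprintf("  %s: %s\n", k, format(x$attributes[[k]])))
  }
  cat("relationships:\n")
  if (nrow(x$relationships)) {
    for (i in seq_len(nrow(x$relationships))) {
      cat(sprintf("  %s (%s): %d\n", x$relationships$rel_type[i],
                  x$relationships$direction[i], x$relationships$count[i]))
    }
  }
  cat("GO terms (direct):", paste(x$go_direct, collapse = ", "), "\n")
  cat("GO terms (inferred):", paste(x$go_inferred, collapse = ", "), "\n")
  cat("homology:\n")
  if (nrow(x$homology)) {
    for (i in seq_len(nrow(x$homology))) {
      cat(sprintf("  %s [%s] bsr=%s pid=%s evalue=%s\n",
                  x$homology$partner[i], x$homology$rel_type[i],
                  format(x$homology$bsr[i]), format(x$homology$pct_identity[i]),
                  format(x$homology$evalue[i])))
    }
  }
  invisible(x)
}

#' Biological-process terms for a gene list
#'
#' Effective GO terms restricted to the `biological_process` namespace,
#' per gene.
#'
#' @param graph A [property_graph()].
#' @param gene_ids Gene ids.
#' @return Data frame `gene_id`, `term_id`, `term_name`.
#' @export
biological_processes <- function(graph, gene_ids) {
  ancestors <- if (length(node_ids(graph, "GOTerm"))) ontology_ancestors(graph) else NULL
  rows <- list()
  for (g in gene_ids) {
    if (!has_node(graph, g)) next
    terms <- if (is.null(ancestors)) character(0) else
      effective_go_terms(graph, g, ancestors)
    for (t in terms) {
      if (!isTRUE(node_attr(graph, t, "namespace") == "biological_process")) next
      rows[[length(rows) + 1L]] <- list(gene_id = g, term_id = t,
                                        term_name = as.character(node_attr(graph, t, "name", "")))
    }
  }
  data.frame(gene_id = vapply(rows, `[[`, character(1), "gene_id"),
             term_id = vapply(rows, `[[`, character(1), "term_id"),
             term_name = vapply(rows, `[[`, character(1), "term_name"),
             stringsAsFactors = FALSE)
}

#' Ortholog listing for a gene list
#'
#' Reciprocal-best-hit partners per gene, across all species in the graph.
#'
#' @param graph A [property_graph()].
#' @param gene_ids Gene ids.
#' @return Data frame `gene_id`, `ortholog_id`, `species`, `bsr`.
#' @export
list_orthologs <- function(graph, gene_ids) {
  rows <- list()
  for (g in gene_ids) {
    if (!has_node(graph, g)) next
    for (nb in neighbors(graph, g, "RECIPROCAL_BEST_HIT", "both")) {
      rows[[length(rows) + 1L]] <- list(
        gene_id = g, ortholog_id = nb$node,
        species = as.character(node_attr(graph, nb$node, "species", NA_character_)),
        bsr = if (is.null(nb$edge$attributes$bsr)) NA_real_ else
          as.numeric(nb$edge$attributes$bsr))
    }
  }
  data.frame(gene_id = vapply(rows, `[[`, character(1), "gene_id"),
             ortholog_id = vapply(rows, `[[`, character(1), "ortholog_id"),
             species = vapply(rows, `[[`, character(1), "species"),
             bsr = vapply(rows, `[[`, numeric(1), "bsr"),
             stringsAsFactors = FALSE)
}
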