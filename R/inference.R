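#' Ancestor closure of the ontology
#'
#' Walks `IS_A` edges from every `GOTerm` node to compute each term's
#' ancestor set (transitive closure). A cycle in the generalization
#' hierarchy is a data error and aborts, naming the terms on the cycle.
#'
#' @param graph A [property_graph()].
#' @return Named list term id -> character vector of ancestor term ids
#'   (excluding the term itself).
#' @export
ontology_ancestors <- function(graph) {
  terms <- node_ids(graph, "GOTerm")
  anc <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # "visiting" | "done"
  visit <- function(t, stack) {
    st <- state[[t]]
    if (identical(st, "done")) return(anc[[t]])
    if (identical(st, "visiting")) {
      cyc <- c(stack[which(stack == t)[1]:length(stack)], t)
      stop(sprintf("IS_A cycle detected: %s", paste(cyc, collapse = " -> ")),
           call. = FALSE)
    }
    state[[t]] <- "visiting"
    parents <- vapply(neighbors(graph, t, "IS_A", "out"), `[[`, character(1),
                      "node")
    acc <- character(0)
    for (p in parents) acc <- c(acc, p, visit(p, c(stack, t)))
    anc[[t]] <- sort(unique(acc))
    state[[t]] <- "done"
    anc[[t]]
  }
  out <- lapply(terms, visit, stack = character(0))
  stats::setNames(out, terms)
}

#' Effective GO term set of a gene
#'
#' A gene annotated to a term is implicitly annotated to every `is_a`
#' ancestor of that term (annotation to "collenchyma cell differentiation"
#' implies "cell differentiation"). The effective set is the direct
#' `HAS_GO_TERM` targets plus all their ancestors.
#'
#' @param graph A [property_graph()].
#' @param gene_id Gene id.
#' @param ancestors Optional precomputed [ontology_ancestors()] (pass it
#'   when querying many genes).
#' @return Sorted character vector of term ids.
#' @export
effective_go_terms <- function(graph, gene_id, ancestors = NULL) {
  if (!has_node(graph, gene_id)) {
    stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  }
  direct <- vapply(neighbors(graph, gene_id, "HAS_GO_TERM", "out"), `[[`,
                   character(1), "node")
  if (!length(direct)) return(character(0))
  if (is.null(ancestors)) ancestors <- ontology_ancestors(graph)
  sort(unique(c(direct, unlist(ancestors[direct], use.names = FALSE))))
}

#' Propagate ontology annotation up the is_a DAG
#'
#' Computes, for every annotated gene, its implied ancestor-term
#' assignments. By default the closure is query-time only (see
#' [effective_go_terms()]); with `materialize = TRUE` the implied
#' assignments are written as `INFERRED_GO_TERM` edges (attribute
#' `source = "is_a_closure"`), always distinguishable from direct
#' `HAS_GO_TERM` annotation. Idempotent: re-running changes nothing.
#'
#' @param graph A [property_graph()], modified in place when materializing.
#' @param materialize Write `INFERRED_GO_TERM` edges (default `FALSE`).
#' @return Count of implied (gene, ancestor-term) assignments beyond the
#'   direct ones.
#' @export
propagate_ontology <- function(graph, materialize = FALSE) {
  ancestors <- ontology_ancestors(graph)
  count <- 0L
  for (g in node_ids(graph, "Gene")) {
    direct <- vapply(neighbors(graph, g, "HAS_GO_TERM", "out"), `[[`,
                     character(1), "node")
    if (!length(direct)) next
    implied <- setdiff(unique(unlist(ancestors[direct], use.names = FALSE)),
                       direct)
    count <- count + length(implied)
    if (materialize) {
      for (t in implied) {
        upsert_edge(graph, g, t, "INFERRED_GO_TERM",
                    list(source = "is_a_closure"))
      }
    }
  }
  count
}

#' Transfer annotation from 1-hop homologs
#'
#' For an (often unannotated) gene, collects the annotations of its direct
#' homologs — reciprocal best hits and best hits by default — one homology
#' hop away, never chaining further. Each returned annotation is tagged
#' with its provenance path (`gene -> homolog -> annotation`) and the
#' homolog edge's BSR; a `coexpressed` column reports whether gene and
#' homolog share a co-expression edge (evidence, not a filter). Results
#' are written back as `INFERRED_*` edges only on request, never silently.
#'
#' @param graph A [property_graph()].
#' @param gene_id The gene to annotate.
#' @param via Homology relationship types crossed (default
#'   `RECIPROCAL_BEST_HIT`, `BEST_HIT`).
#' @param annotation_types Subset of `"go"`, `"domain"`, `"pathway"`.
#' @param bsr_floor Homology edges below this BSR are not crossed; edges
#'   without a BSR attribute pass (default 0.4).
#' @param write Materialize `INFERRED_GO_TERM` / `INFERRED_DOMAIN` /
#'   `INFERRED_IN_PATHWAY` edges with provenance attributes (default
#'   `FALSE`).
#' @return Data frame `annotation_id`, `annotation_type`, `source_gene`,
#'   `bsr`, `path`, `coexpressed`.
#' @export
infer_from_homolog <- function(graph, gene_id,
                               via = c("RECIPROCAL_BEST_HIT", "BEST_HIT"),
                               annotation_types = c("go", "domain", "pathway"),
                               bsr_floor = 0.4, write = FALSE) {
  if (!has_node(graph, gene_id)) {
    stop(sprintf("unknown gene '%s'", gene_id), call. = FALSE)
  }
  rel_of_type <- c(go = "HAS_GO_TERM", domain = "HAS_DOMAIN",
                   pathway = "IN_PATHWAY")
  inferred_rel <- c(go = "INFERRED_GO_TERM", domain = "INFERRED_DOMAIN",
                    pathway = "INFERRED_IN_PATHWAY")
  annotation_types <- match.arg(annotation_types, several.ok = TRUE)
  rows <- list()
  for (nb in neighbors(graph, gene_id, via, "both")) {
    b <- nb$edge$attributes$bsr
    if (!is.null(b) && !is.na(b) && b < bsr_floor) next
    homolog <- nb$node
    coex <- !is.null(get_edge(graph, min(gene_id, homolog),
                              max(gene_id, homolog), "COEXPRESSED_WITH"))
    for (ty in annotation_types) {
      for (ann in neighbors(graph, homolog, rel_of_type[[ty]], "out")) {
        rows[[length(rows) + 1L]] <- list(
          annotation_id = ann$node, annotation_type = ty,
          source_gene = homolog,
          bsr = if (is.null(b)) NA_real_ else as.numeric(b),
          path = paste(gene_id, homolog, ann$node, sep = " -> "),
          coexpressed = coex)
        if (write) {
          attrs <- list(source_gene = homolog, via = nb$edge$rel_type)
          if (!is.null(b) && !is.na(b)) attrs$bsr <- as.numeric(b)
          upsert_edge(graph, gene_id, ann$node, inferred_rel[[ty]], attrs)
        }
      }
    }
  }
  out <- data.frame(
    annotation_id = vapply(rows, `[[`, character(1), "annotation_id"),
    annotation_type = vapply(rows, `[[`, character(1), "annotation_type"),
    source_gene = vapply(rows, `[[`, character(1), "source_gene"),
    bsr = vapply(rows, `[[`, numeric(1), "bsr"),
    path = vapply(rows, `[[`, character(1), "path"),
    coexpressed = vapply(rows, `[[`, logical(1), "coexpressed"),
    stringsAsFactors = FALSE
  )
  # one row per (annotation, source gene), whichever homology edge types
  # connect the pair; the strongest BSR is kept
  out <- out[order(out$annotation_type, out$annotation_id, out$source_gene,
                   -xtfrm(out$bsr)), , drop = FALSE]
  out <- out[!duplicated(out[, c("annotation_type", "annotation_id",
                                 "source_gene")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
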