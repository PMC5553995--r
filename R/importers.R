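#' @title Import summaries
#' @description Importers return a named integer vector of class
#'   `import_summary` counting what was created or skipped; `print` renders
#'   `key: count` lines.
#' @param x,... Summary and ignored arguments.
#' @keywords internal
#' @export
print.import_summary <- function(x, ...) {
  for (k in names(x)) cat(sprintf("%s: %d\n", k, x[[k]]))
  invisible(x)
}

import_summary <- function(...) {
  v <- c(...)
  structure(as.integer(v), names = names(v), class = "import_summary")
}

#' Landmark node id (namespaced per species, since chromosome names repeat
#' across genomes)
#' @keywords internal
#' @noRd
landmark_node_id <- function(species, landmark) paste(species, landmark, sep = ":")

#' Import a genome annotation into the graph
#'
#' Creates one `Species` node, one `Landmark` node per landmark
#' (namespaced `species:landmark`), and one `Gene` node per `gene` feature,
#' each with a `LOCATED_ON` edge carrying `start`/`end`/`strand`. Per
#' landmark, genes are chained in physical order (sorted by start, ties by
#' end then id; strand ignored) with `NEXT_GENE` edges — the gene-order
#' backbone that synteny queries and translation disambiguation walk.
#' mRNA features are recorded on their parent gene as a comma-joined
#' `transcripts` attribute; exon/CDS structure is not stored.
#'
#' Re-importing the same file is a no-op on counts (idempotent upserts).
#'
#' @param graph A [property_graph()], modified in place.
#' @param species Non-empty species name.
#' @param features Data frame from [parse_gff3()].
#' @param sequences Optional named vector from [parse_fasta()]; only
#'   sequence lengths are stored (attribute `seq_length`), never sequence
#'   text.
#' @return An `import_summary` with per-label counts.
#' @export
import_genome <- function(graph, species, features, sequences = NULL) {
  stopifnot(inherits(graph, "property_graph"))
  if (!is.character(species) || !nzchar(species)) {
    stop("species name must be non-empty", call. = FALSE)
  }
  upsert_node(graph, species, "Species", list(name = species))
  genes <- features[features$ftype == "gene", , drop = FALSE]
  dup <- genes$feature_id[duplicated(genes$feature_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene id within species '%s': %s", species,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  landmarks <- unique(genes$landmark)
  for (lm in landmarks) {
    upsert_node(graph, landmark_node_id(species, lm), "Landmark",
                list(name = lm, species = species))
  }
  for (i in seq_len(nrow(genes))) {
    gid <- genes$feature_id[i]
    attrs <- list(species = species, landmark = genes$landmark[i],
                  start = genes$start[i], end = genes$end[i],
                  strand = genes$strand[i],
                  length = genes$end[i] - genes$start[i])
    if (!is.null(sequences) && gid %in% names(sequences)) {
      attrs$seq_length <- nchar(sequences[[gid]])
    }
    upsert_node(graph, gid, "Gene", attrs)
    upsert_edge(graph, gid, landmark_node_id(species, genes$landmark[i]),
                "LOCATED_ON",
                list(start = genes$start[i], end = genes$end[i],
                     strand = genes$strand[i]))
  }
  # transcript ids noted on the parent gene
  mrna <- features[features$ftype %in% c("mRNA", "transcript") &
                     !is.na(features$parent_id), , drop = FALSE]
  if (nrow(mrna)) {
    for (parent in unique(mrna$parent_id)) {
      if (!has_node(graph, parent)) next
      tx <- sort(mrna$feature_id[mrna$parent_id == parent])
      upsert_node(graph, parent, "Gene",
                  list(transcripts = paste(tx, collapse = ",")))
    }
  }
  n_next <- 0L
  for (lm in landmarks) {
    sub <- genes[genes$landmark == lm, , drop = FALSE]
    ord <- order(sub$start, sub$end, sub$feature_id)
    ids <- sub$feature_id[ord]
    if (length(ids) > 1) {
      for (i in seq_len(length(ids) - 1L)) {
        upsert_edge(graph, ids[i], ids[i + 1L], "NEXT_GENE",
                    list(landmark = lm, species = species))
        n_next <- n_next + 1L
      }
    }
  }
  import_summary(Species = 1L, Landmark = length(landmarks),
                 Gene = nrow(genes), NEXT_GENE = n_next)
}

#' Resolve a protein/transcript id to a gene node
#'
#' InterProScan reports protein ids; genome projects differ in how those
#' map to gene ids. The default rule keeps an id that is already a node and
#' otherwise strips a trailing `.<digits>` transcript suffix.
#'
#' @keywords internal
#' @noRd
resolve_gene_id <- function(graph, id, id_strip = "\\.\\d+$") {
  if (has_node(graph, id)) return(id)
  stripped <- sub(id_strip, "", id)
  if (has_node(graph, stripped)) return(stripped)
  NA_character_
}

#' Import InterProScan domain hits
#'
#' One `Domain` node per signature accession, shared across species;
#' `HAS_DOMAIN` edges gene -> domain, and `HAS_GO_TERM` edges gene -> GO
#' term for every GO id carried by a hit. GO term nodes are created as
#' stubs when the ontology has not been imported yet; [import_ontology()]
#' later enriches them in place. Hits whose protein id cannot be resolved
#' to a gene node are skipped with a warning and counted.
#'
#' @inheritParams import_genome
#' @param domain_hits Data frame from [parse_interproscan_tsv()].
#' @param id_strip Regex removed from an unresolvable protein id before
#'   retrying (default: trailing `.<digits>`).
#' @return An `import_summary` (`Domain`, `HAS_DOMAIN`, `HAS_GO_TERM`,
#'   `skipped`).
#' @export
import_functional_annotations <- function(graph, domain_hits, id_strip = "\\.\\d+$") {
  stopifnot(inherits(graph, "property_graph"))
  n_dom_edge <- 0L; n_go_edge <- 0L; skipped <- 0L
  new_domains <- character(0)
  for (i in seq_len(nrow(domain_hits))) {
    h <- domain_hits[i, ]
    gid <- resolve_gene_id(graph, h$protein_id, id_strip)
    if (is.na(gid)) {
      warning(sprintf("unresolvable protein id '%s'; hit skipped", h$protein_id),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    if (!has_node(graph, h$signature_acc)) {
      new_domains <- c(new_domains, h$signature_acc)
    }
    upsert_node(graph, h$signature_acc, "Domain",
                list(analysis = h$analysis, description = h$signature_desc))
    attrs <- list(start = h$start, stop = h$stop, analysis = h$analysis)
    if (!is.na(h$score)) attrs$score <- h$score
    upsert_edge(graph, gid, h$signature_acc, "HAS_DOMAIN", attrs)
    n_dom_edge <- n_dom_edge + 1L
    for (go in domain_hits$go_terms[[i]]) {
      if (!has_node(graph, go)) {
        upsert_node(graph, go, "GOTerm", list(stub = TRUE))
      }
      upsert_edge(graph, gid, go, "HAS_GO_TERM",
                  list(source = "interproscan", via = h$signature_acc))
      n_go_edge <- n_go_edge + 1L
    }
  }
  import_summary(Domain = length(unique(new_domains)), HAS_DOMAIN = n_dom_edge,
                 HAS_GO_TERM = n_go_edge, skipped = skipped)
}

#' Import an ontology
#'
#' One `GOTerm` node per non-obsolete term with `name`/`namespace`
#' attributes, and `IS_A` edges child -> parent. Stub term nodes created
#' earlier by [import_functional_annotations()] are enriched in place.
#' Parents referencing terms absent from the document are created as stubs
#' and counted as dangling (reported, not fatal).
#'
#' @inheritParams import_genome
#' @param terms Data frame from [parse_obo()].
#' @return An `import_summary` (`GOTerm`, `IS_A`, `dangling_parents`,
#'   `obsolete_skipped`).
#' @export
import_ontology <- function(graph, terms) {
  stopifnot(inherits(graph, "property_graph"))
  live <- terms[!terms$obsolete, , drop = FALSE]
  known <- live$term_id
  n_isa <- 0L; dangling <- 0L
  for (i in seq_len(nrow(live))) {
    upsert_node(graph, live$term_id[i], "GOTerm",
                list(name = live$name[i], namespace = live$namespace[i],
                     stub = FALSE))
  }
  for (i in seq_len(nrow(live))) {
    for (p in live$is_a_parents[[i]]) {
      if (!(p %in% known)) {
        dangling <- dangling + 1L
        if (!has_node(graph, p)) upsert_node(graph, p, "GOTerm", list(stub = TRUE))
      }
      upsert_edge(graph, live$term_id[i], p, "IS_A")
      n_isa <- n_isa + 1L
    }
  }
  if (dangling > 0) {
    warning(sprintf("%d is_a parent reference(s) dangle outside the document",
                    dangling), call. = FALSE)
  }
  import_summary(GOTerm = nrow(live), IS_A = n_isa,
                 dangling_parents = dangling,
                 obsolete_skipped = sum(terms$obsolete))
}

#' Import generic relationship tuples
#'
#' Endpoints are upserted with configurable labels, edges created with the
#' tuple's relationship type and attributes. This is how pathway
#' memberships, EC assignments, interaction tables and any other TSV-shaped
#' data enter the graph.
#'
#' @inheritParams import_genome
#' @param tuples Data frame from [parse_generic_tsv()].
#' @param source_label,target_label Labels applied to upserted endpoints
#'   (defaults `"Gene"` and `"Entity"`).
#' @return An `import_summary` (`edges`, `new_sources`, `new_targets`).
#' @export
import_relationship_tuples <- function(graph, tuples, source_label = "Gene",
                                       target_label = "Entity") {
  stopifnot(inherits(graph, "property_graph"))
  new_src <- 0L; new_tgt <- 0L
  for (i in seq_len(nrow(tuples))) {
    s <- tuples$source_id[i]; t <- tuples$target_id[i]
    if (!has_node(graph, s)) new_src <- new_src + 1L
    upsert_node(graph, s, source_label)
    if (!has_node(graph, t)) new_tgt <- new_tgt + 1L
    upsert_node(graph, t, target_label)
    upsert_edge(graph, s, t, tuples$rel_type[i], tuples$attributes[[i]])
  }
  import_summary(edges = nrow(tuples), new_sources = new_src,
                 new_targets = new_tgt)
}

#' Physical gene order per landmark
#'
#' Reconstructs the gene-order backbone for one species from node
#' attributes: per landmark, gene ids sorted by start (ties by end then
#' id), matching the `NEXT_GENE` chain laid down by [import_genome()].
#'
#' @inheritParams import_genome
#' @return Named list landmark name -> character vector of gene ids in
#'   physical order.
#' @export
gene_order <- function(graph, species) {
  gids <- node_ids(graph, "Gene")
  keep <- vapply(gids, function(g) identical(node_attr(graph, g, "species"), species),
                 logical(1))
  gids <- gids[keep]
  if (!length(gids)) return(stats::setNames(list(), character(0)))
  lm <- vapply(gids, function(g) node_attr(graph, g, "landmark", NA_character_), character(1))
  st <- vapply(gids, function(g) as.numeric(node_attr(graph, g, "start", NA_real_)), numeric(1))
  en <- vapply(gids, function(g) as.numeric(node_attr(graph, g, "end", NA_real_)), numeric(1))
  out <- list()
  for (l in sort(unique(lm))) {
    idx <- which(lm == l)
    idx <- idx[order(st[idx], en[idx], gids[idx])]
    out[[l]] <- gids[idx]
  }
  out
}
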