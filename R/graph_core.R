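#' Embedded property graph
#'
#' @description
#' `property_graph()` creates an empty in-memory property graph: labeled
#' nodes carrying attribute maps, connected by typed, attributed, directed
#' edges. The graph is the universal store every importer writes into and
#' every query reads from.
#'
#' The object is environment-backed and therefore modified *in place* by
#' [upsert_node()], [upsert_edge()] and all importers; assignment does not
#' copy it. Iteration order is deterministic (sorted identifiers) so query
#' output is reproducible.
#'
#' Edges are unique per `(source, target, rel_type)` triple; repeating an
#' upsert merges attributes instead of creating a parallel edge.
#'
#' @return An object of class `property_graph`.
#' @seealso [upsert_node()], [upsert_edge()], [neighbors()], [save_graph()]
#' @export
#' @examples
#' g <- property_graph()
#' upsert_node(g, "g1", "Gene", list(start = 100L))
#' upsert_node(g, "d1", "Domain")
#' upsert_edge(g, "g1", "d1", "HAS_DOMAIN")
#' neighbors(g, "g1")
property_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- new.env(parent = emptyenv())       # id -> list(id, labels, attributes)
  g$edges <- new.env(parent = emptyenv())       # key -> list(source, target, rel_type, attributes)
  g$adj_out <- new.env(parent = emptyenv())     # id -> character vector of edge keys
  g$adj_in <- new.env(parent = emptyenv())
  g$label_index <- new.env(parent = emptyenv()) # label -> character vector of ids
  class(g) <- "property_graph"
  g
}

edge_key <- function(source, target, rel_type) {
  paste(source, target, rel_type, sep = "")
}

check_attributes <- function(attributes) {
  if (is.null(attributes)) return(structure(list(), names = character(0)))
  if (!is.list(attributes)) stop("attributes must be a named list of scalars", call. = FALSE)
  if (length(attributes) == 0) return(structure(list(), names = character(0)))
  nm <- names(attributes)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("attribute keys must be non-empty strings", call. = FALSE)
  }
  for (i in seq_along(attributes)) {
    v <- attributes[[i]]
    if (length(v) != 1L || !(is.character(v) || is.numeric(v) || is.logical(v))) {
      stop(sprintf("attribute '%s' must be a scalar string/number/boolean", nm[i]),
           call. = FALSE)
    }
  }
  attributes
}

#' Add or update a node
#'
#' Idempotent node insertion. If the node exists, labels are unioned and
#' attributes merged with new values winning (last-write-wins); the label
#' index is kept exactly in step.
#'
#' @param graph A [property_graph()].
#' @param id Non-empty node identifier (scalar character).
#' @param labels Character vector of labels, at least one (e.g. `"Gene"`,
#'   `"GOTerm"`, `"Landmark"`).
#' @param attributes Named list of scalar attributes (string/number/boolean).
#' @return The node id, invisibly. The graph is modified in place.
#' @export
upsert_node <- function(graph, id, labels, attributes = list()) {
  stopifnot(inherits(graph, "property_graph"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("node id must be a non-empty string", call. = FALSE)
  }
  labels <- as.character(labels)
  attributes <- check_attributes(attributes)
  existing <- graph$nodes[[id]]
  if (is.null(existing)) {
    if (length(labels) == 0) stop("a new node needs at least one label", call. = FALSE)
    node <- list(id = id, labels = sort(unique(labels)), attributes = attributes)
    new_labels <- node$labels
  } else {
    node <- existing
    node$labels <- sort(unique(c(node$labels, labels)))
    node$attributes <- merge_attributes(node$attributes, attributes)
    new_labels <- setdiff(node$labels, existing$labels)
  }
  graph$nodes[[id]] <- node
  for (lb in new_labels) {
    graph$label_index[[lb]] <- c(graph$label_index[[lb]], id)
  }
  invisible(id)
}

merge_attributes <- function(old, new) {
  if (length(new) == 0) return(old)
  for (k in names(new)) old[[k]] <- new[[k]]
  old
}

#' Add or update an edge
#'
#' Exactly one edge exists per `(source, target, rel_type)` triple; a repeat
#' upsert merges attributes (new values win). Both endpoints must already be
#' in the graph.
#'
#' @inheritParams upsert_node
#' @param source,target Existing node ids.
#' @param rel_type Non-empty relationship type (e.g. `"LOCATED_ON"`,
#'   `"HAS_GO_TERM"`, `"RECIPROCAL_BEST_HIT"`). Direction is meaningful per
#'   type and documented by each importer.
#' @param attributes Named list of scalar attributes.
#' @return The edge key, invisibly.
#' @export
upsert_edge <- function(graph, source, target, rel_type, attributes = list()) {
  stopifnot(inherits(graph, "property_graph"))
  if (!is.character(rel_type) || length(rel_type) != 1L || !nzchar(rel_type)) {
    stop("rel_type must be a non-empty string", call. = FALSE)
  }
  for (endpoint in c(source, target)) {
    if (is.null(graph$nodes[[endpoint]])) {
      stop(sprintf("edge endpoint '%s' does not exist in the graph", endpoint),
           call. = FALSE)
    }
  }
  attributes <- check_attributes(attributes)
  key <- edge_key(source, target, rel_type)
  existing <- graph$edges[[key]]
  if (is.null(existing)) {
    graph$edges[[key]] <- list(source = source, target = target,
                               rel_type = rel_type, attributes = attributes)
    graph$adj_out[[source]] <- c(graph$adj_out[[source]], key)
    graph$adj_in[[target]] <- c(graph$adj_in[[target]], key)
  } else {
    existing$attributes <- merge_attributes(existing$attributes, attributes)
    graph$edges[[key]] <- existing
  }
  invisible(key)
}

#' @rdname graph_accessors
#' @export
has_node <- function(graph, id) !is.null(graph$nodes[[id]])

#' Node, edge and label accessors
#'
#' @description
#' Small deterministic accessors over a [property_graph()]:
#' `get_node()` returns one node record (id, labels, attributes);
#' `node_attr()` one attribute (or `default`); `node_ids()` all node ids,
#' optionally restricted to a label; `has_node()` tests existence;
#' `graph_edges()` returns all edges as a data frame; `n_nodes()`/`n_edges()`
#' count. All listings are sorted by id/key.
#'
#' @param graph A [property_graph()].
#' @param id Node id.
#' @param label Optional label filter.
#' @param attr Attribute name.
#' @param default Value when the attribute is absent.
#' @name graph_accessors
#' @export
get_node <- function(graph, id) {
  node <- graph$nodes[[id]]
  if (is.null(node)) stop(sprintf("unknown node '%s'", id), call. = FALSE)
  node
}

#' @rdname graph_accessors
#' @export
node_attr <- function(graph, id, attr, default = NULL) {
  v <- get_node(graph, id)$attributes[[attr]]
  if (is.null(v)) default else v
}

#' @rdname graph_accessors
#' @export
node_ids <- function(graph, label = NULL) {
  if (is.null(label)) return(sort(ls(graph$nodes)))
  ids <- graph$label_index[[label]]
  if (is.null(ids)) character(0) else sort(ids)
}

#' @rdname graph_accessors
#' @export
n_nodes <- function(graph) length(ls(graph$nodes))

#' @rdname graph_accessors
#' @export
n_edges <- function(graph) length(ls(graph$edges))

#' @rdname graph_accessors
#' @export
graph_edges <- function(graph) {
  keys <- sort(ls(graph$edges))
  data.frame(
    source = vapply(keys, function(k) graph$edges[[k]]$source, character(1)),
    target = vapply(keys, function(k) graph$edges[[k]]$target, character(1)),
    rel_type = vapply(keys, function(k) graph$edges[[k]]$rel_type, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

get_edge <- function(graph, source, target, rel_type) {
  graph$edges[[edge_key(source, target, rel_type)]]
}

#' Adjacent nodes of a node
#'
#' Returns the nodes adjacent to `id`, optionally filtered by relationship
#' type and direction, as a list of `(node, edge, direction)` entries sorted
#' by neighbor id then relationship type. Traversal is how annotation
#' attached to a gene (GO terms, domains, homologs) is reached.
#'
#' @inheritParams upsert_node
#' @param rel_type Optional single relationship type, or a character vector
#'   of types, to keep; `NULL` keeps all.
#' @param direction `"out"`, `"in"` or `"both"` (default).
#' @return A list; each element has `$node` (neighbor id), `$edge` (the full
#'   edge record) and `$direction` (`"out"`/`"in"` relative to `id`).
#' @export
neighbors <- function(graph, id, rel_type = NULL, direction = c("both", "out", "in")) {
  direction <- match.arg(direction)
  if (!has_node(graph, id)) stop(sprintf("unknown node '%s'", id), call. = FALSE)
  out <- list()
  if (direction %in% c("out", "both")) {
    for (k in graph$adj_out[[id]]) {
      e <- graph$edges[[k]]
      if (!is.null(rel_type) && !(e$rel_type %in% rel_type)) next
      out[[length(out) + 1L]] <- list(node = e$target, edge = e, direction = "out")
    }
  }
  if (direction %in% c("in", "both")) {
    for (k in graph$adj_in[[id]]) {
      e <- graph$edges[[k]]
      if (!is.null(rel_type) && !(e$rel_type %in% rel_type)) next
      out[[length(out) + 1L]] <- list(node = e$source, edge = e, direction = "in")
    }
  }
  ord <- order(vapply(out, `[[`, character(1), "node"),
               vapply(out, function(x) x$edge$rel_type, character(1)))
  out[ord]
}

#' @rdname neighbors
#' @return `neighbor_ids()` returns just the sorted unique neighbor ids.
#' @export
neighbor_ids <- function(graph, id, rel_type = NULL, direction = "both") {
  sort(unique(vapply(neighbors(graph, id, rel_type, direction),
                     `[[`, character(1), "node")))
}

#' Serialize a graph to JSON Lines
#'
#' Writes one JSON record per line: a header record first
#' (`{"kind":"header",...}`), then nodes sorted by id, then edges sorted by
#' key. Doubles are written with a decimal point so integer/double attribute
#' types survive the round trip. `load_graph()` inverts exactly:
#' `load_graph(save_graph(g, p))` is graph-identical to `g`.
#'
#' @inheritParams upsert_node
#' @param path File path to write/read.
#' @return `save_graph()` returns `path` invisibly; `load_graph()` a
#'   [property_graph()].
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "property_graph"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines('{"kind":"header","format":"omicsgraph-jsonl","version":1}', con)
  # scalars are emitted by hand: doubles at %.17g so the round trip is
  # bit-exact, with a decimal point/exponent kept so they re-parse as
  # doubles (never silently becoming integers)
  scalar <- function(v) {
    if (is.character(v)) return(as.character(jsonlite::toJSON(jsonlite::unbox(v))))
    if (is.logical(v)) return(if (is.na(v)) "null" else if (v) "true" else "false")
    if (is.integer(v)) return(if (is.na(v)) "null" else as.character(v))
    if (is.na(v)) return("null")
    s <- sprintf("%.17g", v)
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }
  obj <- function(x) {
    paste0("{", paste(vapply(names(x), function(k)
      paste0(scalar(k), ":", x[[k]]), character(1)), collapse = ","), "}")
  }
  rec <- function(x) {
    fields <- list()
    for (k in names(x)) {
      v <- x[[k]]
      fields[[k]] <- if (k == "labels") {
        paste0("[", paste(vapply(unlist(v), scalar, character(1)),
                          collapse = ","), "]")
      } else if (k == "attributes") {
        obj(lapply(v, scalar))
      } else {
        scalar(v)
      }
    }
    obj(fields)
  }
  for (id in sort(ls(graph$nodes))) {
    node <- graph$nodes[[id]]
    writeLines(rec(list(kind = "node", id = node$id, labels = as.list(node$labels),
                        attributes = node$attributes)), con)
  }
  for (k in sort(ls(graph$edges))) {
    e <- graph$edges[[k]]
    writeLines(rec(list(kind = "edge", source = e$source, target = e$target,
                        rel_type = e$rel_type, attributes = e$attributes)), con)
  }
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  if (!file.exists(path)) stop(sprintf("graph file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty graph file (missing header record)", call. = FALSE)
  parse_line <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) {
                      stop(sprintf("graph file parse error at line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    if (is.null(rec$kind)) {
      stop(sprintf("graph file parse error at line %d: record without 'kind'", i),
           call. = FALSE)
    }
    rec
  }
  header <- parse_line(1L)
  if (!identical(header$kind, "header") ||
      !identical(header$format, "omicsgraph-jsonl")) {
    stop("graph file parse error at line 1: not an omicsgraph JSON Lines header",
         call. = FALSE)
  }
  g <- property_graph()
  for (i in seq_along(lines)[-1]) {
    rec <- parse_line(i)
    attrs <- rec$attributes
    if (is.null(attrs)) attrs <- list()
    if (rec$kind == "node") {
      upsert_node(g, rec$id, unlist(rec$labels), attrs)
    } else if (rec$kind == "edge") {
      upsert_edge(g, rec$source, rec$target, rec$rel_type, attrs)
    } else {
      stop(sprintf("graph file parse error at line %d: unknown kind '%s'",
                   i, rec$kind), call. = FALSE)
    }
  }
  g
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  labs <- sort(ls(x$label_index))
  if (length(labs)) {
    counts <- vapply(labs, function(lb) length(x$label_index[[lb]]), integer(1))
    cat("  labels:", paste(sprintf("%s=%d", labs, counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.property_graph <- function(object, ...) {
  rels <- table(graph_edges(object)$rel_type)
  structure(list(n_nodes = n_nodes(object), n_edges = n_edges(object),
                 labels = vapply(sort(ls(object$label_index)),
                                 function(lb) length(object$label_index[[lb]]),
                                 integer(1)),
                 rel_types = rels),
            class = "summary.property_graph")
}

#' @export
print.summary.property_graph <- function(x, ...) {
  cat(sprintf("property graph: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  for (lb in names(x$labels)) cat(sprintf("  node %s: %d\n", lb, x$labels[[lb]]))
  for (rt in names(x$rel_types)) cat(sprintf("  edge %s: %d\n", rt, x$rel_types[[rt]]))
  invisible(x)
}
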