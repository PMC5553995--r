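#' Build co-expression relationships from an expression matrix
#'
#' Stores the expression layer in the graph — one `Condition` node per
#' condition (namespaced `cond:<name>`) and `EXPRESSED_IN` edges gene ->
#' condition carrying the FPKM — and connects every gene pair whose
#' Pearson correlation across conditions reaches the threshold with a
#' `COEXPRESSED_WITH` edge (undirected semantics: stored once with the
#' lexicographically smaller gene as source; attributes `r`, signed, and
#' `n_conditions`).
#'
#' Correlation is computed on `log2(FPKM + 1)` by default (FPKM spans
#' orders of magnitude; the log stabilizes it), thresholded on `|r|` so
#' anticorrelation also qualifies. Genes with zero variance are excluded
#' with a warning. The all-pairs computation is quadratic in gene count;
#' above `max_genes` a warning is emitted (the tool targets desk scale).
#'
#' @param graph A [property_graph()], modified in place.
#' @param profiles Numeric matrix from [parse_expression_table()] (genes
#'   as rows, conditions as columns).
#' @param method Correlation method; only `"pearson"`.
#' @param min_abs_r Absolute correlation threshold (default 0.9).
#' @param min_conditions Minimum condition count (default 4); fewer is an
#'   input error.
#' @param log_transform Correlate `log2(FPKM + 1)` (default) or raw FPKM.
#' @param max_genes Warning threshold for the quadratic pair scan.
#' @return An `import_summary` (`Condition`, `EXPRESSED_IN`,
#'   `COEXPRESSED_WITH`, `zero_variance_excluded`).
#' @export
build_coexpression <- function(graph, profiles, method = "pearson",
                               min_abs_r = 0.9, min_conditions = 4L,
                               log_transform = TRUE, max_genes = 5000L) {
  stopifnot(inherits(graph, "property_graph"))
  method <- match.arg(method, "pearson")
  if (ncol(profiles) < min_conditions) {
    stop(sprintf("expression table has %d condition(s); at least %d required",
                 ncol(profiles), min_conditions), call. = FALSE)
  }
  if (nrow(profiles) > max_genes) {
    warning(sprintf("%d genes: the all-pairs correlation scan is quadratic; this tool targets desk scale",
                    nrow(profiles)), call. = FALSE)
  }
  conditions <- colnames(profiles)
  for (cn in conditions) {
    upsert_node(graph, paste0("cond:", cn), "Condition", list(name = cn))
  }
  n_expr <- 0L
  for (g in rownames(profiles)) {
    if (!has_node(graph, g)) upsert_node(graph, g, "Gene")
    for (cn in conditions) {
      upsert_edge(graph, g, paste0("cond:", cn), "EXPRESSED_IN",
                  list(fpkm = unname(profiles[g, cn])))
      n_expr <- n_expr + 1L
    }
  }
  x <- if (log_transform) log2(profiles + 1) else profiles
  v <- apply(x, 1, stats::var)
  zero_var <- rownames(x)[v == 0]
  if (length(zero_var)) {
    warning(sprintf("%d gene(s) with zero expression variance excluded: %s",
                    length(zero_var),
                    paste(utils::head(zero_var, 5), collapse = ", ")),
            call. = FALSE)
  }
  x <- x[v > 0, , drop = FALSE]
  n_edge <- 0L
  if (nrow(x) >= 2) {
    r <- stats::cor(t(x), method = method)
    ids <- rownames(x)
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq.int(i + 1L, length(ids))) {
        if (abs(r[i, j]) >= min_abs_r) {
          ends <- sort(c(ids[i], ids[j]))
          upsert_edge(graph, ends[1], ends[2], "COEXPRESSED_WITH",
                      list(r = unname(r[i, j]),
                           n_conditions = ncol(profiles),
                           undirected = TRUE))
          n_edge <- n_edge + 1L
        }
      }
    }
  }
  import_summary(Condition = length(conditions), EXPRESSED_IN = n_expr,
                 COEXPRESSED_WITH = n_edge,
                 zero_variance_excluded = length(zero_var))
}

#' Co-expression neighborhood of a gene set
#'
#' Returns the `COEXPRESSED_WITH` partners of each gene in `gene_ids`,
#' with the stored correlation.
#'
#' @param graph A [property_graph()].
#' @param gene_ids Gene ids.
#' @return Data frame `gene_id`, `partner`, `r`.
#' @export
coexpression_neighborhood <- function(graph, gene_ids) {
  rows <- list()
  for (g in gene_ids) {
    if (!has_node(graph, g)) next
    for (nb in neighbors(graph, g, "COEXPRESSED_WITH", "both")) {
      rows[[length(rows) + 1L]] <- list(gene_id = g, partner = nb$node,
                                        r = nb$edge$attributes$r)
    }
  }
  data.frame(gene_id = vapply(rows, `[[`, character(1), "gene_id"),
             partner = vapply(rows, `[[`, character(1), "partner"),
             r = vapply(rows, function(x) as.numeric(x$r), numeric(1)),
             stringsAsFactors = FALSE)
}
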