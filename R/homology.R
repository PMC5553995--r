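#' BLAST Score Ratio
#'
#' The BSR of a hit is its bit score divided by the query's self-hit bit
#' score, so 1.0 means a match as strong as the sequence against itself.
#' Values marginally above 1 (floating-point slack in bit scores) are
#' clamped to 1 with a warning.
#'
#' @param hit_bit_score Bit score(s) of the hit(s).
#' @param query_self_bit_score Self-hit bit score(s) of the query; must be
#'   positive.
#' @return Numeric ratio(s) in (0, 1].
#' @export
#' @examples
#' compute_bsr(225, 450)  # 0.5
compute_bsr <- function(hit_bit_score, query_self_bit_score) {
  if (any(is.na(query_self_bit_score)) || any(query_self_bit_score <= 0)) {
    stop("query self bit score must be positive", call. = FALSE)
  }
  r <- hit_bit_score / query_self_bit_score
  if (any(r > 1)) {
    warning(sprintf("%d BSR value(s) > 1 clamped to 1", sum(r > 1)), call. = FALSE)
    r <- pmin(r, 1)
  }
  r
}

#' Self-hit bit scores from a similarity table
#'
#' Extracts, per query, the bit score of its hit against itself (the BSR
#' denominator). Typically applied to a self-vs-self search table.
#'
#' @param hits Data frame from [parse_blast_tab()].
#' @return Named numeric vector query_id -> self bit score.
#' @export
self_scores_from_hits <- function(hits) {
  self <- hits[hits$query_id == hits$subject_id, , drop = FALSE]
  if (!nrow(self)) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(self$bit_score, self$query_id, max)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Best hit per query
#'
#' For each query the subject with the highest bit score wins; ties are
#' broken by lower e-value, then higher percent identity, then
#' lexicographic subject id. A winner decided only at the lexicographic
#' level is flagged `ambiguous` (recent duplications and gene families
#' produce identical hits; the translation machinery consumes the flag).
#' Self-hits (query == subject) are never candidates. Hits above the
#' e-value ceiling are discarded before selection.
#'
#' @param hits Data frame from [parse_blast_tab()], one query-species ->
#'   subject-species direction.
#' @param self_scores Optional named vector of query self bit scores (see
#'   [self_scores_from_hits()]); when present a `bsr` column is filled,
#'   queries without a self score get `bsr = NA` and `no_self_score = TRUE`.
#' @param evalue_max E-value ceiling applied before selection (default
#'   `1e-5`).
#' @return Data frame `query_id`, `subject_id`, `bit_score`, `evalue`,
#'   `pct_identity`, `bsr`, `ambiguous`, `no_self_score`, sorted by query.
#' @export
best_hits <- function(hits, self_scores = NULL, evalue_max = 1e-5) {
  h <- hits[hits$query_id != hits$subject_id & hits$evalue <= evalue_max, ,
            drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      bit_score = numeric(0), evalue = numeric(0),
                      pct_identity = numeric(0), bsr = numeric(0),
                      ambiguous = logical(0), no_self_score = logical(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(h$query_id, -h$bit_score, h$evalue, -h$pct_identity, h$subject_id)
  h <- h[ord, , drop = FALSE]
  first <- !duplicated(h$query_id)
  win <- h[first, , drop = FALSE]
  # ambiguous: another subject ties through bit score, e-value and identity
  amb <- logical(nrow(win))
  idx <- which(first)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (i < nrow(h) && h$query_id[i + 1L] == h$query_id[i] &&
        h$bit_score[i + 1L] == h$bit_score[i] &&
        h$evalue[i + 1L] == h$evalue[i] &&
        h$pct_identity[i + 1L] == h$pct_identity[i]) {
      amb[j] <- TRUE
    }
  }
  bsr <- rep(NA_real_, nrow(win))
  no_self <- rep(FALSE, nrow(win))
  if (!is.null(self_scores)) {
    have <- win$query_id %in% names(self_scores)
    no_self <- !have
    if (any(have)) {
      bsr[have] <- compute_bsr(win$bit_score[have],
                               as.numeric(self_scores[win$query_id[have]]))
    }
  }
  data.frame(query_id = win$query_id, subject_id = win$subject_id,
             bit_score = win$bit_score, evalue = win$evalue,
             pct_identity = win$pct_identity, bsr = bsr, ambiguous = amb,
             no_self_score = no_self, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits
#'
#' The standard ortholog proxy: `(a, b)` is kept iff `b` is `a`'s best hit
#' in the A->B direction and `a` is `b`'s best hit in B->A. Each id occurs
#' in at most one pair; output is sorted by `a_id`.
#'
#' @param best_ab,best_ba Outputs of [best_hits()] for the two directions.
#' @return Data frame `a_id`, `b_id` (plus `bsr_ab`, `bsr_ba` when
#'   available).
#' @export
reciprocal_best_hits <- function(best_ab, best_ba) {
  fwd <- stats::setNames(best_ab$subject_id, best_ab$query_id)
  rev <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  a_ids <- sort(names(fwd))
  keep <- vapply(a_ids, function(a) {
    b <- fwd[[a]]
    !is.null(rev[[b]]) && !is.na(rev[b]) && identical(unname(rev[b]), a)
  }, logical(1))
  a <- a_ids[keep]
  b <- unname(fwd[a])
  bsr_ab <- best_ab$bsr[match(a, best_ab$query_id)]
  bsr_ba <- best_ba$bsr[match(b, best_ba$query_id)]
  data.frame(a_id = a, b_id = b, bsr_ab = bsr_ab, bsr_ba = bsr_ba,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write homology relationships into the graph
#'
#' Retained hits become `BLASTP_HIT` edges (attributes `bsr`,
#' `pct_identity`, `evalue`, `bit_score`), per-query winners become
#' `BEST_HIT` edges, and reciprocal best hits become
#' `RECIPROCAL_BEST_HIT` edges with undirected semantics: stored once
#' (lexicographically smaller endpoint as source) and visible from either
#' endpoint via [neighbors()] with `direction = "both"`. Hits touching
#' unknown gene ids are skipped with a warning. Re-running is idempotent.
#'
#' @param graph A [property_graph()], modified in place.
#' @param hits_ab Hits data frame for the A->B direction.
#' @param hits_ba Optional B->A hits; required for reciprocal calls.
#' @param self_scores_a,self_scores_b Optional self-score vectors for BSR.
#' @param evalue_max E-value ceiling (default `1e-5`).
#' @return An `import_summary` (`BLASTP_HIT`, `BEST_HIT`,
#'   `RECIPROCAL_BEST_HIT`, `skipped`).
#' @export
write_homology_edges <- function(graph, hits_ab, hits_ba = NULL,
                                 self_scores_a = NULL, self_scores_b = NULL,
                                 evalue_max = 1e-5) {
  stopifnot(inherits(graph, "property_graph"))
  skipped <- 0L; n_hit <- 0L
  write_hits <- function(hits, self_scores) {
    h <- hits[hits$query_id != hits$subject_id & hits$evalue <= evalue_max, ,
              drop = FALSE]
    for (i in seq_len(nrow(h))) {
      q <- h$query_id[i]; s <- h$subject_id[i]
      if (!has_node(graph, q) || !has_node(graph, s)) {
        warning(sprintf("hit %s -> %s references an unknown gene; skipped", q, s),
                call. = FALSE)
        skipped <<- skipped + 1L
        next
      }
      attrs <- list(pct_identity = h$pct_identity[i], evalue = h$evalue[i],
                    bit_score = h$bit_score[i])
      if (!is.null(self_scores) && q %in% names(self_scores)) {
        attrs$bsr <- compute_bsr(h$bit_score[i], as.numeric(self_scores[[q]]))
      }
      upsert_edge(graph, q, s, "BLASTP_HIT", attrs)
      n_hit <<- n_hit + 1L
    }
  }
  write_hits(hits_ab, self_scores_a)
  if (!is.null(hits_ba)) write_hits(hits_ba, self_scores_b)

  n_best <- 0L
  best_ab <- best_hits(hits_ab, self_scores_a, evalue_max)
  best_ba <- if (!is.null(hits_ba)) best_hits(hits_ba, self_scores_b, evalue_max) else NULL
  for (b in list(best_ab, best_ba)) {
    if (is.null(b)) next
    for (i in seq_len(nrow(b))) {
      if (!has_node(graph, b$query_id[i]) || !has_node(graph, b$subject_id[i])) next
      attrs <- list(bit_score = b$bit_score[i], evalue = b$evalue[i],
                    pct_identity = b$pct_identity[i], ambiguous = b$ambiguous[i])
      if (!is.na(b$bsr[i])) attrs$bsr <- b$bsr[i]
      upsert_edge(graph, b$query_id[i], b$subject_id[i], "BEST_HIT", attrs)
      n_best <- n_best + 1L
    }
  }

  n_rbh <- 0L
  if (!is.null(best_ba)) {
    rbh <- reciprocal_best_hits(best_ab, best_ba)
    for (i in seq_len(nrow(rbh))) {
      a <- rbh$a_id[i]; b <- rbh$b_id[i]
      if (!has_node(graph, a) || !has_node(graph, b)) next
      ends <- sort(c(a, b))
      attrs <- list(undirected = TRUE)
      if (!is.na(rbh$bsr_ab[i])) attrs$bsr <- min(rbh$bsr_ab[i], rbh$bsr_ba[i], na.rm = TRUE)
      upsert_edge(graph, ends[1], ends[2], "RECIPROCAL_BEST_HIT", attrs)
      n_rbh <- n_rbh + 1L
    }
  }
  import_summary(BLASTP_HIT = n_hit, BEST_HIT = n_best,
                 RECIPROCAL_BEST_HIT = n_rbh, skipped = skipped)
}
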