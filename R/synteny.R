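#' Search for syntenic regions across species
#'
#' Given an ordered, colinear run of query genes, scans every landmark of
#' the target species (in both orientations by default) for windows whose
#' genes can be paired with the query genes order-preservingly through
#' homology edges (`BLASTP_HIT`/`BEST_HIT`/`RECIPROCAL_BEST_HIT` above the
#' BSR floor). A window matches when at least `length(query) - max_gaps`
#' query genes are paired and at most `max_gaps` unpaired target genes are
#' interleaved inside the matched span — so a conserved block still
#' matches when an unrelated gene has been inserted into it, or when one
#' of its genes has been deleted. Matches are scored
#' `paired - 0.5 * (insertions + deletions)`; overlapping matches on one
#' landmark/orientation keep only the best (ties to the leftmost start).
#'
#' @param graph A [property_graph()] with gene-order backbones and
#'   homology edges.
#' @param query_species Species of the query genes.
#' @param query_gene_ids Ordered gene ids, colinear on one landmark (they
#'   must occur along the landmark in the given order, else an input
#'   error).
#' @param target_species Character vector of species to scan.
#' @param max_gaps Maximum tolerated insertions, and separately deletions
#'   (default 1).
#' @param bsr_floor Homology edges below this BSR are ignored; edges
#'   without a `bsr` attribute pass (default 0.4).
#' @param orientation `"both"` (default) scans each landmark forward and
#'   reversed; `"forward"` only as stored.
#' @return A data frame of class `synteny_matches`: `species`, `landmark`,
#'   `orientation`, `score`, `paired`, `insertions`, `deletions`,
#'   list-columns `target_gene_ids` (the matched span, in scan
#'   orientation) and `pairings` (two-column matrix of query/target
#'   indices, strictly increasing in both). Sorted by decreasing score.
#' @export
find_syntenic_regions <- function(graph, query_species, query_gene_ids,
                                  target_species, max_gaps = 1L,
                                  bsr_floor = 0.4,
                                  orientation = c("both", "forward")) {
  orientation <- match.arg(orientation)
  m <- length(query_gene_ids)
  if (m < 1L) stop("query gene list is empty", call. = FALSE)
  oi_q <- order_index(graph, query_species)
  lms <- oi_q$landmark[query_gene_ids]
  if (anyNA(lms)) {
    stop(sprintf("query gene(s) not found for species '%s': %s", query_species,
                 paste(query_gene_ids[is.na(lms)], collapse = ", ")), call. = FALSE)
  }
  if (length(unique(lms)) != 1L ||
      is.unsorted(oi_q$index[query_gene_ids], strictly = TRUE)) {
    stop("query genes must be colinear: one landmark, in landmark order",
         call. = FALSE)
  }
  # homolog sets per query gene, restricted to target species; a gene is
  # trivially homologous to itself, so the query species can be scanned too
  homolog_sets <- lapply(query_gene_ids, function(q) {
    hs <- if (query_species %in% target_species) q else character(0)
    for (nb in neighbors(graph, q, c("BLASTP_HIT", "BEST_HIT",
                                     "RECIPROCAL_BEST_HIT"), "both")) {
      b <- nb$edge$attributes$bsr
      if (!is.null(b) && !is.na(b) && b < bsr_floor) next
      sp <- node_attr(graph, nb$node, "species")
      if (!is.null(sp) && sp %in% target_species) hs <- c(hs, nb$node)
    }
    unique(hs)
  })
  results <- list()
  for (sp in target_species) {
    orders <- gene_order(graph, sp)
    for (lm in names(orders)) {
      scans <- list(forward = orders[[lm]])
      if (orientation == "both") scans$reverse <- rev(orders[[lm]])
      for (orient in names(scans)) {
        tg <- scans[[orient]]
        hits <- scan_target_order(homolog_sets, tg, max_gaps)
        for (hit in hits) {
          results[[length(results) + 1L]] <- c(
            list(species = sp, landmark = lm, orientation = orient), hit)
        }
      }
    }
  }
  results <- merge_overlapping_matches(results)
  df <- data.frame(
    species = vapply(results, `[[`, character(1), "species"),
    landmark = vapply(results, `[[`, character(1), "landmark"),
    orientation = vapply(results, `[[`, character(1), "orientation"),
    score = vapply(results, `[[`, numeric(1), "score"),
    paired = vapply(results, `[[`, integer(1), "paired"),
    insertions = vapply(results, `[[`, integer(1), "insertions"),
    deletions = vapply(results, `[[`, integer(1), "deletions"),
    stringsAsFactors = FALSE
  )
  df$target_gene_ids <- lapply(results, `[[`, "target_gene_ids")
  df$pairings <- lapply(results, `[[`, "pairings")
  df <- df[order(-df$score, df$species, df$landmark,
                 vapply(results, `[[`, integer(1), "span_start"))[seq_len(nrow(df))], ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("synteny_matches", class(df))
  df
}

# Enumerate matching spans over one oriented target gene order.
# A span [s, e] qualifies when an order-preserving pairing exists that
# pairs both span endpoints, leaves <= max_gaps query genes unpaired
# (deletions) and <= max_gaps interior target genes unpaired (insertions).
# The best pairing per span is found with an LCS-style dynamic program.
scan_target_order <- function(homolog_sets, tg, max_gaps) {
  m <- length(homolog_sets)
  n <- length(tg)
  if (n == 0L) return(list())
  match_mat <- vapply(seq_len(n), function(j)
    vapply(seq_len(m), function(i) tg[j] %in% homolog_sets[[i]], logical(1)),
    logical(m))
  match_mat <- matrix(match_mat, nrow = m, ncol = n)
  anchors <- which(apply(match_mat, 2, any))
  out <- list()
  min_len <- max(1L, m - max_gaps)
  for (s in anchors) {
    for (e in anchors[anchors >= s]) {
      span_len <- e - s + 1L
      if (span_len < min_len || span_len > m + max_gaps) next
      pr <- best_span_pairing(match_mat, s, e)
      if (is.null(pr)) next
      paired <- nrow(pr)
      deletions <- m - paired
      insertions <- span_len - paired
      if (deletions > max_gaps || insertions > max_gaps) next
      out[[length(out) + 1L]] <- list(
        score = paired - 0.5 * (insertions + deletions),
        paired = as.integer(paired),
        insertions = as.integer(insertions),
        deletions = as.integer(deletions),
        target_gene_ids = tg[s:e],
        pairings = cbind(query = pr[, 1], target = pr[, 2] - s + 1L),
        span_start = as.integer(s), span_end = as.integer(e))
    }
  }
  out
}

# maximum order-preserving pairing over target columns s..e that pairs
# columns s and e; returns matrix (query_idx, target_idx) or NULL
best_span_pairing <- function(match_mat, s, e) {
  m <- nrow(match_mat)
  cols <- s:e
  k <- length(cols)
  # dp[i, j]: best pairing count using query 1..i, target cols 1..j,
  # with column j paired requirement handled by endpoint check below
  best <- -1L
  best_pairs <- NULL
  qs_first <- which(match_mat[, s])
  qs_last <- which(match_mat[, e])
  if (!length(qs_first) || !length(qs_last)) return(NULL)
  if (s == e) {
    return(matrix(c(qs_first[1], s), ncol = 2,
                  dimnames = list(NULL, c("query", "target"))))
  }
  for (qa in qs_first) {
    for (qb in qs_last[qs_last > qa]) {
      inner <- lcs_pairing(match_mat, qa + 1L, qb - 1L, s + 1L, e - 1L)
      cnt <- 2L + nrow(inner)
      if (cnt > best) {
        best <- cnt
        best_pairs <- rbind(c(qa, s), inner, c(qb, e))
      }
    }
  }
  if (is.null(best_pairs)) return(NULL)
  colnames(best_pairs) <- c("query", "target")
  best_pairs
}

# standard LCS dynamic program over match_mat[qi1..qi2, tj1..tj2],
# returning the paired (query, target) index matrix
lcs_pairing <- function(match_mat, qi1, qi2, tj1, tj2) {
  empty <- matrix(integer(0), ncol = 2)
  if (qi1 > qi2 || tj1 > tj2) return(empty)
  qs <- qi1:qi2; ts <- tj1:tj2
  a <- length(qs); b <- length(ts)
  dp <- matrix(0L, a + 1L, b + 1L)
  for (i in seq_len(a)) {
    for (j in seq_len(b)) {
      dp[i + 1L, j + 1L] <- max(dp[i, j + 1L], dp[i + 1L, j],
                                dp[i, j] + as.integer(match_mat[qs[i], ts[j]]))
    }
  }
  # backtrack
  pairs <- empty
  i <- a; j <- b
  while (i > 0L && j > 0L) {
    if (match_mat[qs[i], ts[j]] && dp[i + 1L, j + 1L] == dp[i, j] + 1L) {
      pairs <- rbind(c(qs[i], ts[j]), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (dp[i, j + 1L] >= dp[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs
}

merge_overlapping_matches <- function(results) {
  if (length(results) <= 1L) return(results)
  keygrp <- vapply(results, function(r)
    paste(r$species, r$landmark, r$orientation, sep = "\r"), character(1))
  kept <- list()
  for (grp in unique(keygrp)) {
    rs <- results[keygrp == grp]
    ord <- order(-vapply(rs, `[[`, numeric(1), "score"),
                 vapply(rs, `[[`, integer(1), "span_start"))
    rs <- rs[ord]
    chosen <- list()
    for (r in rs) {
      overlaps <- any(vapply(chosen, function(c)
        r$span_start <= c$span_end && c$span_start <= r$span_end, logical(1)))
      if (!overlaps) chosen[[length(chosen) + 1L]] <- r
    }
    kept <- c(kept, chosen)
  }
  kept
}

#' @export
print.synteny_matches <- function(x, ...) {
  cat(sprintf("%d syntenic match(es)\n", nrow(x)))
  if (nrow(x)) {
    df <- data.frame(species = x$species, landmark = x$landmark,
                     orientation = x$orientation, score = x$score,
                     paired = x$paired, ins = x$insertions, del = x$deletions,
                     block = vapply(x$target_gene_ids, paste, character(1),
                                    collapse = ","),
                     stringsAsFactors = FALSE)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
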