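#' @title Annotation translation between genome versions
#' @description
#' When a genome project releases a new assembly/annotation, gene
#' identifiers change and gene models are revised: most genes are simple
#' renames, but some are split into several new models, several old models
#' can be merged into one, and some disappear. Coordinate liftover cannot
#' express those events. This module calls, per old gene, one of
#' `one_to_one`, `split`, `merge`, `ambiguous` or `missing` from an
#' all-vs-all nucleotide similarity search between the two gene sets,
#' using BLAST Score Ratios plus alignment coverage to recognize the event
#' shape, and gene-order (synteny) context to break ties that sequence
#' alone cannot resolve (recent duplications, gene families).
#' @name annotation-translation
NULL

default_translation_opts <- function() {
  list(bsr_floor = 0.4,   # candidates below this BSR are dropped
       tie_band = 0.98,   # candidates within this ratio of the top bit score tie
       cov_high = 0.8,    # mutual coverage for a one_to_one call
       cov_min = 0.5,     # per-piece coverage for split/merge membership
       window = 5L)       # +/- genes of synteny context
}

#' Ranked translation candidates per old gene
#'
#' Aggregates an old-vs-new similarity table into per-old-gene candidate
#' lists: per (query, subject) pair the strongest alignment is kept, and
#' each candidate carries its bit score, BSR, and coverage fractions
#' (aligned length over query length, aligned length over subject length).
#' Candidates below the BSR floor are dropped.
#'
#' @param hits Data frame from [parse_blast_tab()] (old gene models as
#'   queries, new models as subjects).
#' @param query_lengths,subject_lengths Named numeric vectors of gene model
#'   lengths (bases).
#' @param self_scores Optional named vector of query self bit scores; when
#'   absent, BSR is `NA` and the floor is not applied.
#' @param bsr_floor Minimum BSR kept (default 0.4).
#' @return Named list old id -> data frame (`subject_id`, `bit_score`,
#'   `evalue`, `bsr`, `q_cov`, `s_cov`, `q_start`, `q_end`) sorted by
#'   descending bit score. Old genes without surviving hits are absent.
#' @export
candidate_matches <- function(hits, query_lengths, subject_lengths,
                              self_scores = NULL,
                              bsr_floor = default_translation_opts()$bsr_floor) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(list(), character(0)))
  # best alignment per (query, subject) pair
  key <- paste(h$query_id, h$subject_id, sep = "\r")
  h <- h[order(key, -h$bit_score), , drop = FALSE]
  h <- h[!duplicated(paste(h$query_id, h$subject_id, sep = "\r")), , drop = FALSE]
  qlen <- as.numeric(query_lengths[h$query_id])
  slen <- as.numeric(subject_lengths[h$subject_id])
  h$q_cov <- ifelse(is.na(qlen) | qlen <= 0, NA_real_, h$aln_length / qlen)
  h$s_cov <- ifelse(is.na(slen) | slen <= 0, NA_real_, h$aln_length / slen)
  h$bsr <- NA_real_
  if (!is.null(self_scores)) {
    have <- h$query_id %in% names(self_scores)
    h$bsr[have] <- compute_bsr(h$bit_score[have],
                               as.numeric(self_scores[h$query_id[have]]))
    h <- h[is.na(h$bsr) | h$bsr >= bsr_floor, , drop = FALSE]
  }
  out <- split(h[, c("subject_id", "bit_score", "evalue", "bsr", "q_cov",
                     "s_cov", "q_start", "q_end")],
               h$query_id)
  lapply(out, function(d) {
    d <- d[order(-d$bit_score, d$evalue, d$subject_id), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

single_species <- function(graph, species) {
  if (!is.null(species)) return(species)
  sp <- node_ids(graph, "Species")
  if (length(sp) != 1L) {
    stop("graph holds several species; pass the species name explicitly",
         call. = FALSE)
  }
  sp
}

# gene -> (landmark, order index) lookup for one species
order_index <- function(graph, species) {
  orders <- gene_order(graph, species)
  lm <- character(0); idx <- integer(0); ids <- character(0)
  for (l in names(orders)) {
    v <- orders[[l]]
    ids <- c(ids, v)
    lm <- c(lm, rep(l, length(v)))
    idx <- c(idx, seq_along(v))
  }
  list(landmark = stats::setNames(lm, ids), index = stats::setNames(idx, ids),
       orders = orders)
}

#' Break a tied translation by genic synteny
#'
#' When an old gene ties between several new candidates (identical or
#' near-identical sequences: tandem duplicates, gene families), the
#' neighborhood decides: for each candidate, count the old gene's
#' neighbors (within `window` genes either side) whose own unambiguous
#' translation lands within `window` genes of that candidate in the new
#' gene order. The candidate with strictly greatest support wins; equal
#' support stays ambiguous — the tool does not guess. A window larger than
#' the landmark simply clamps to the whole landmark.
#'
#' @param graph_old,graph_new Graphs holding the old and new annotation
#'   (may be the same object).
#' @param old_id The tied old gene.
#' @param tied_candidates Character vector of tied new gene ids.
#' @param window Synteny context, genes either side (default 5).
#' @param winners Named character vector of already-settled unambiguous
#'   translations (old id -> new id) used as anchors.
#' @param species_old,species_new Species names; optional when each graph
#'   holds a single species.
#' @return List with `choice` (new id, or `NA` for ambiguous) and
#'   `support` (named integer vector, per candidate).
#' @export
disambiguate_by_synteny <- function(graph_old, graph_new, old_id,
                                    tied_candidates, window = 5L,
                                    winners = character(0),
                                    species_old = NULL, species_new = NULL) {
  oi_old <- order_index(graph_old, single_species(graph_old, species_old))
  oi_new <- order_index(graph_new, single_species(graph_new, species_new))
  support <- synteny_support(old_id, tied_candidates, winners, oi_old, oi_new,
                             window)
  top <- max(support)
  best <- names(support)[support == top]
  list(choice = if (length(best) == 1L) best else NA_character_,
       support = support)
}

synteny_support <- function(old_id, candidates, winners, oi_old, oi_new, window) {
  support <- stats::setNames(integer(length(candidates)), candidates)
  lm <- oi_old$landmark[[old_id]]
  if (is.null(lm) || is.na(lm)) return(support)
  ord <- oi_old$orders[[lm]]
  pos <- oi_old$index[[old_id]]
  lo <- max(1L, pos - window); hi <- min(length(ord), pos + window)
  neigh <- setdiff(ord[lo:hi], old_id)
  for (n in neigh) {
    w <- winners[n]
    if (is.null(w) || is.na(w)) next
    w <- unname(w)
    w_lm <- oi_new$landmark[w]
    if (is.na(w_lm)) next
    for (cand in candidates) {
      c_lm <- oi_new$landmark[cand]
      if (is.na(c_lm) || c_lm != w_lm) next
      if (abs(oi_new$index[[w]] - oi_new$index[[cand]]) <= window) {
        support[cand] <- support[cand] + 1L
      }
    }
  }
  support
}

# union length of 1-based inclusive intervals, as a fraction of len
interval_union_fraction <- function(starts, ends, len) {
  if (!length(starts) || is.na(len) || len <= 0) return(0)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s + 1)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total <- total + (cur_e - cur_s + 1)
  total / len
}

#' Classify translation calls
#'
#' Turns per-gene candidate lists into status calls. Per old gene:
#' \itemize{
#' \item no surviving candidate: `missing`;
#' \item a single full-coverage candidate (mutual coverage at or above
#'   `cov_high`) in the top score band: `one_to_one`;
#' \item several full-coverage candidates tied in the band: synteny
#'   support decides (strict winner: `one_to_one`; equal support:
#'   `ambiguous`);
#' \item no full-coverage candidate but two or more pieces each covering
#'   at least `cov_min` of themselves, jointly covering `cov_high` of the
#'   old gene and adjacent (within `window`) in the new order: `split`;
#' \item otherwise, a top candidate covering at least `cov_min` of the old
#'   gene is held as a merge member: old genes sharing one such new gene
#'   become `merge` (a singleton falls back to `ambiguous`);
#' \item anything left: `ambiguous`.
#' }
#'
#' @param cand_map Named list from [candidate_matches()].
#' @param ids Old gene ids to call, in output order.
#' @param oi_old,oi_new Order indexes (internal; see
#'   [translate_gene_list()] for the user-facing wrapper).
#' @param opts List of thresholds (see `default_translation_opts()`).
#' @return Data frame of calls: `old_id`, `status`, list-column `new_ids`,
#'   `bsr`, `q_cov`, `s_cov`, `neighbor_support`.
#' @keywords internal
#' @export
classify_calls <- function(cand_map, ids, oi_old, oi_new,
                           opts = default_translation_opts()) {
  status <- stats::setNames(rep(NA_character_, length(ids)), ids)
  new_ids <- stats::setNames(vector("list", length(ids)), ids)
  bsr <- stats::setNames(rep(NA_real_, length(ids)), ids)
  qcov <- stats::setNames(rep(NA_real_, length(ids)), ids)
  scov <- stats::setNames(rep(NA_real_, length(ids)), ids)
  nsupp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ties <- list()          # old_id -> tied candidate data frame
  merge_winner <- character(0)

  for (id in ids) {
    cands <- cand_map[[id]]
    if (is.null(cands) || !nrow(cands)) {
      status[id] <- "missing"; new_ids[[id]] <- character(0)
      next
    }
    top_bit <- cands$bit_score[1]
    band <- cands[cands$bit_score >= opts$tie_band * top_bit, , drop = FALSE]
    full_band <- band[!is.na(band$q_cov) & !is.na(band$s_cov) &
                        band$q_cov >= opts$cov_high &
                        band$s_cov >= opts$cov_high, , drop = FALSE]
    if (nrow(full_band) == 1L) {
      status[id] <- "one_to_one"
      new_ids[[id]] <- full_band$subject_id
      bsr[id] <- full_band$bsr; qcov[id] <- full_band$q_cov; scov[id] <- full_band$s_cov
      next
    }
    if (nrow(full_band) > 1L) {
      ties[[id]] <- full_band
      next
    }
    pieces <- cands[!is.na(cands$s_cov) & cands$s_cov >= opts$cov_min &
                      (is.na(cands$q_cov) | cands$q_cov < opts$cov_high), ,
                    drop = FALSE]
    qlens <- attr(cand_map, "query_lengths")
    qlen <- if (!is.null(qlens)) as.numeric(qlens[id]) else NA_real_
    if (nrow(pieces) >= 2L) {
      joint <- interval_union_fraction(pieces$q_start, pieces$q_end, qlen)
      adjacent <- FALSE
      lms <- oi_new$landmark[pieces$subject_id]
      if (!anyNA(lms) && length(unique(lms)) == 1L) {
        idxs <- oi_new$index[pieces$subject_id]
        adjacent <- (max(idxs) - min(idxs)) <= opts$window
      }
      if (!is.na(joint) && joint >= opts$cov_high && adjacent) {
        ord <- order(oi_new$index[pieces$subject_id])
        status[id] <- "split"
        new_ids[[id]] <- pieces$subject_id[ord]
        bsr[id] <- max(pieces$bsr)
        qcov[id] <- joint
        scov[id] <- min(pieces$s_cov)
        next
      }
    }
    top <- cands[1, ]
    if (!is.na(top$q_cov) && top$q_cov >= opts$cov_min) {
      merge_winner[id] <- top$subject_id
      next
    }
    status[id] <- "ambiguous"; new_ids[[id]] <- character(0)
  }

  # anchors for synteny: unambiguous one-to-one winners
  winners <- vapply(names(status)[!is.na(status) & status == "one_to_one"],
                    function(id) new_ids[[id]][1], character(1))
  for (id in names(ties)) {
    tied <- ties[[id]]
    supp <- synteny_support(id, tied$subject_id, winners, oi_old, oi_new,
                            opts$window)
    top <- max(supp)
    best <- names(supp)[supp == top]
    if (length(best) == 1L) {
      j <- match(best, tied$subject_id)
      status[id] <- "one_to_one"
      new_ids[[id]] <- best
      bsr[id] <- tied$bsr[j]; qcov[id] <- tied$q_cov[j]; scov[id] <- tied$s_cov[j]
      nsupp[id] <- top
    } else {
      status[id] <- "ambiguous"
      new_ids[[id]] <- sort(tied$subject_id)
      nsupp[id] <- top
    }
  }

  # merge grouping: several old genes electing the same partial new gene
  if (length(merge_winner)) {
    for (w in unique(merge_winner)) {
      members <- names(merge_winner)[merge_winner == w]
      st <- if (length(members) >= 2L) "merge" else "ambiguous"
      for (id in members) {
        cands <- cand_map[[id]]
        j <- match(w, cands$subject_id)
        status[id] <- st
        new_ids[[id]] <- if (st == "merge") w else character(0)
        bsr[id] <- cands$bsr[j]; qcov[id] <- cands$q_cov[j]; scov[id] <- cands$s_cov[j]
      }
    }
  }

  out <- data.frame(old_id = ids, status = unname(status[ids]),
                    stringsAsFactors = FALSE)
  out$new_ids <- unname(new_ids[ids])
  out$bsr <- unname(bsr[ids])
  out$q_cov <- unname(qcov[ids])
  out$s_cov <- unname(scov[ids])
  out$neighbor_support <- unname(nsupp[ids])
  class(out) <- c("translation_calls", class(out))
  out
}

#' Translate a gene list between annotation versions
#'
#' The end-to-end translation query: given the old and new annotation in
#' graphs, an old-vs-new all-vs-all similarity table and a list of old
#' gene ids, returns one call per id (in input order) and writes
#' `TRANSLATES_TO` edges (attribute `status`) into `graph_old`. When the
#' two versions live in separate graphs, new-version targets are upserted
#' into `graph_old` as stub `Gene` nodes so the edges have endpoints.
#' Unknown ids produce per-id `error` rows; the run continues.
#'
#' @inheritParams disambiguate_by_synteny
#' @param hits Old-vs-new similarity table ([parse_blast_tab()]).
#' @param ids Old gene ids to translate.
#' @param self_scores Named vector of old-gene self bit scores for BSR.
#' @param opts Threshold list; see `default_translation_opts()`.
#' @param write_edges Write `TRANSLATES_TO` edges (default `TRUE`).
#' @return A `translation_calls` data frame (see [classify_calls()]).
#' @export
translate_gene_list <- function(graph_old, graph_new, hits, ids,
                                self_scores = NULL,
                                species_old = NULL, species_new = NULL,
                                opts = default_translation_opts(),
                                write_edges = TRUE) {
  sp_old <- single_species(graph_old, species_old)
  sp_new <- single_species(graph_new, species_new)
  oi_old <- order_index(graph_old, sp_old)
  oi_new <- order_index(graph_new, sp_new)
  known <- !is.na(oi_old$landmark[ids])
  names(known) <- ids

  old_ids_all <- names(oi_old$landmark)
  new_ids_all <- names(oi_new$landmark)
  qlen <- vapply(old_ids_all, function(g)
    as.numeric(node_attr(graph_old, g, "length", NA_real_)), numeric(1))
  slen <- vapply(new_ids_all, function(g)
    as.numeric(node_attr(graph_new, g, "length", NA_real_)), numeric(1))
  cand_map <- candidate_matches(hits, qlen, slen, self_scores, opts$bsr_floor)
  attr(cand_map, "query_lengths") <- qlen

  calls <- classify_calls(cand_map, ids[known], oi_old, oi_new, opts)
  if (any(!known)) {
    err <- data.frame(old_id = ids[!known], status = "error",
                      stringsAsFactors = FALSE)
    err$new_ids <- replicate(sum(!known), character(0), simplify = FALSE)
    err$bsr <- NA_real_; err$q_cov <- NA_real_; err$s_cov <- NA_real_
    err$neighbor_support <- NA_integer_
    calls <- rbind(calls, err)
    calls <- calls[match(ids, calls$old_id), , drop = FALSE]
    rownames(calls) <- NULL
    class(calls) <- c("translation_calls", "data.frame")
  }
  if (write_edges) {
    for (i in seq_len(nrow(calls))) {
      if (!calls$status[i] %in% c("one_to_one", "split", "merge")) next
      for (nid in calls$new_ids[[i]]) {
        if (!has_node(graph_old, nid)) {
          upsert_node(graph_old, nid, "Gene",
                      list(species = sp_new, stub = TRUE))
        }
        upsert_edge(graph_old, calls$old_id[i], nid, "TRANSLATES_TO",
                    list(status = calls$status[i]))
      }
    }
  }
  calls
}

#' @export
print.translation_calls <- function(x, ...) {
  cat(sprintf("translation calls for %d gene(s)\n", nrow(x)))
  tab <- table(x$status)
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  df <- data.frame(old_id = x$old_id, status = x$status,
                   new_ids = vapply(x$new_ids, paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat(sprintf("  ... %d more rows\n", nrow(df) - 20))
  invisible(x)
}

#' Write translation calls as a TSV report
#'
#' Columns: `old_id`, `status`, `new_ids` (comma-joined), `bsr`,
#' `neighbor_support`, `query_coverage`, `subject_coverage`.
#'
#' @param calls A `translation_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_translation_report <- function(calls, path) {
  df <- data.frame(old_id = calls$old_id, status = calls$status,
                   new_ids = vapply(calls$new_ids, paste, character(1), collapse = ","),
                   bsr = calls$bsr, neighbor_support = calls$neighbor_support,
                   query_coverage = calls$q_cov, subject_coverage = calls$s_cov,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
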