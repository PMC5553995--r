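#' @title Synthetic fixtures with planted ground truth
#' @description
#' Deterministic generators for every input the pipeline consumes —
#' GFF3, FASTA, similarity tables, InterProScan TSV, OBO, expression
#' matrices, SNP tables, generic relationship TSVs — with a truth bundle
#' recording every planted event, so each algorithmic module can be
#' checked against known answers without downloading anything.
#'
#' Similarity tables are produced by an exact-substring surrogate scorer
#' (a hit exists iff one sequence contains the other; bit score is twice
#' the matched base count, self scores are consistent), which preserves
#' the rank and ratio structure that BSR, best-hit and coverage logic
#' consume. Real BLAST+ outfmt-6 files remain fully supported through the
#' ordinary readers. The generator makes no attempt to mimic real genome
#' statistics (GC content, intron structure).
#' @name fixtures
NULL

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exact-substring surrogate similarity search: queries x subjects
substring_similarity <- function(queries, subjects) {
  rows <- list()
  for (q in names(queries)) {
    sq <- queries[[q]]
    for (s in names(subjects)) {
      ss <- subjects[[s]]
      if (nchar(sq) <= nchar(ss)) {
        pos <- regexpr(sq, ss, fixed = TRUE)
        if (pos < 0) next
        aln <- nchar(sq)
        qs <- 1L; qe <- aln; s1 <- as.integer(pos); s2 <- s1 + aln - 1L
      } else {
        pos <- regexpr(ss, sq, fixed = TRUE)
        if (pos < 0) next
        aln <- nchar(ss)
        qs <- as.integer(pos); qe <- qs + aln - 1L; s1 <- 1L; s2 <- aln
      }
      rows[[length(rows) + 1L]] <- list(
        query_id = q, subject_id = s, pct_identity = 100, aln_length = aln,
        mismatches = 0L, gap_opens = 0L, q_start = qs, q_end = qe,
        s_start = s1, s_end = s2, evalue = 2^(-aln / 2), bit_score = 2 * aln)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), aln_length = integer(0),
                      mismatches = integer(0), gap_opens = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      evalue = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# lay genes on a landmark: sequential intervals with a fixed gap
layout_features <- function(ids, lengths, landmark, gap = 200L) {
  start <- integer(length(ids)); end <- integer(length(ids))
  pos <- 0L
  for (i in seq_along(ids)) {
    start[i] <- pos
    end[i] <- pos + lengths[i]
    pos <- end[i] + gap
  }
  out <- data.frame(feature_id = ids, landmark = landmark, start = start,
                    end = end, strand = "+", ftype = "gene",
                    parent_id = NA_character_, stringsAsFactors = FALSE)
  out$attributes <- replicate(length(ids), list(), simplify = FALSE)
  out
}

write_blast_tab <- function(hits, path) {
  df <- hits[, c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end", "s_start",
                 "s_end", "evalue", "bit_score")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Generate a pair of annotation versions with planted translation events
#'
#' Builds an "old" genome of random nucleotide gene models and derives a
#' "new" annotation version from it by renaming survivors, splitting
#' chosen genes into two adjacent halves, merging chosen adjacent pairs,
#' deleting chosen genes, inserting novel genes, and duplicating chosen
#' genes (one copy at the original locus, one dispersed) so the duplicate
#' tie is resolvable only by gene-order context. One additional family
#' (per `n_ambiguous`) has *both* copies dispersed among novel genes, so
#' neighbor support is equal and the correct call is `ambiguous`. The
#' similarity table is computed by the exact-substring surrogate scorer
#' over all (old, new) sequence pairs — planting bookkeeping never feeds
#' the hit table directly.
#'
#' @param seed Integer seed; the whole output is a deterministic function
#'   of it and the counts.
#' @param n_genes Old-genome gene count.
#' @param n_splits,n_merges,n_missing Planted event counts.
#' @param n_dup_families Synteny-resolvable duplicate families.
#' @param n_ambiguous Equal-support duplicate families (expected call:
#'   `ambiguous`).
#' @param n_insertions Novel genes inserted into the new version.
#' @param out_dir When given, writes `old.gff3`, `new.gff3`, `old.fasta`,
#'   `new.fasta`, `old__vs__new.tsv`, `truth_translation.tsv` there.
#' @return List with `features_old`, `features_new` (GFF3-shaped data
#'   frames), `sequences_old`, `sequences_new`, `hits`, `self_scores`,
#'   and `truth` (`old_id`, `status`, list-column `new_ids`).
#' @export
generate_genome_version_pair <- function(seed, n_genes = 40L, n_splits = 3L,
                                         n_merges = 2L, n_missing = 3L,
                                         n_dup_families = 1L, n_ambiguous = 1L,
                                         n_insertions = 3L, out_dir = NULL) {
  n_events <- n_splits + 2L * n_merges + n_missing + n_dup_families + n_ambiguous
  n_renames <- n_genes - n_events
  n_blocks <- n_splits + n_merges + n_missing + n_dup_families + n_ambiguous
  if (n_renames < n_blocks + 1L) {
    stop(sprintf("infeasible counts: %d genes leave %d renames for %d event blocks",
                 n_genes, n_renames, n_blocks), call. = FALSE)
  }
  set.seed(seed)
  # event slot sequence along the old chromosome: event blocks separated by
  # at least one rename so every event has one-to-one synteny context
  blocks <- c(rep(list("split"), n_splits),
              rep(list(c("merge", "merge")), n_merges),
              rep(list("missing"), n_missing),
              rep(list("dup"), n_dup_families),
              rep(list("amb"), n_ambiguous))
  blocks <- blocks[sample.int(length(blocks))]
  slots <- character(0)
  spare <- n_renames - (n_blocks + 1L)
  for (b in seq_along(blocks)) {
    slots <- c(slots, rep("rename", 1L + if (spare > 0) {
      extra <- sample.int(min(spare, 3L), 1L); spare <- spare - extra; extra
    } else 0L), blocks[[b]])
  }
  slots <- c(slots, rep("rename", n_renames - sum(slots == "rename")))
  stopifnot(length(slots) == n_genes)

  lengths <- sample(150:450, n_genes, replace = TRUE) * 2L
  old_ids <- sprintf("oldg%03d", seq_len(n_genes))
  seqs_old <- stats::setNames(vapply(lengths, random_dna, character(1)), old_ids)
  features_old <- layout_features(old_ids, lengths, "chr1")

  # derive the new version
  new_chr1 <- list()   # list of (id, seq)
  truth <- list()
  new_counter <- 0L
  new_id <- function() { new_counter <<- new_counter + 1L; sprintf("newg%03d", new_counter) }
  dispersed <- list()  # genes destined for chr2
  i <- 1L
  while (i <= n_genes) {
    slot <- slots[i]
    oid <- old_ids[i]
    if (slot == "rename") {
      nid <- new_id()
      new_chr1[[length(new_chr1) + 1L]] <- list(id = nid, seq = seqs_old[[oid]])
      truth[[length(truth) + 1L]] <- list(old_id = oid, status = "one_to_one",
                                          new_ids = nid)
    } else if (slot == "split") {
      L <- nchar(seqs_old[[oid]])
      half <- L %/% 2L
      a <- new_id(); b <- new_id()
      new_chr1[[length(new_chr1) + 1L]] <- list(id = a, seq = substr(seqs_old[[oid]], 1, half))
      new_chr1[[length(new_chr1) + 1L]] <- list(id = b, seq = substr(seqs_old[[oid]], half + 1L, L))
      truth[[length(truth) + 1L]] <- list(old_id = oid, status = "split",
                                          new_ids = c(a, b))
    } else if (slot == "merge") {
      oid2 <- old_ids[i + 1L]
      m <- new_id()
      new_chr1[[length(new_chr1) + 1L]] <- list(
        id = m, seq = paste0(seqs_old[[oid]], seqs_old[[oid2]]))
      truth[[length(truth) + 1L]] <- list(old_id = oid, status = "merge", new_ids = m)
      truth[[length(truth) + 1L]] <- list(old_id = oid2, status = "merge", new_ids = m)
      i <- i + 1L
    } else if (slot == "missing") {
      truth[[length(truth) + 1L]] <- list(old_id = oid, status = "missing",
                                          new_ids = character(0))
    } else if (slot == "dup") {
      y1 <- new_id(); y2 <- new_id()
      new_chr1[[length(new_chr1) + 1L]] <- list(id = y1, seq = seqs_old[[oid]])
      dispersed[[length(dispersed) + 1L]] <- list(id = y2, seq = seqs_old[[oid]])
      truth[[length(truth) + 1L]] <- list(old_id = oid, status = "one_to_one",
                                          new_ids = y1)
    } else if (slot == "amb") {
      z1 <- new_id(); z2 <- new_id()
      dispersed[[length(dispersed) + 1L]] <- list(id = z1, seq = seqs_old[[oid]])
      dispersed[[length(dispersed) + 1L]] <- list(id = z2, seq = seqs_old[[oid]])
      truth[[length(truth) + 1L]] <- list(old_id = oid, status = "ambiguous",
                                          new_ids = sort(c(z1, z2)))
    }
    i <- i + 1L
  }
  # novel insertions into chr1
  for (j in seq_len(n_insertions)) {
    at <- sample.int(length(new_chr1) + 1L, 1L)
    nid <- new_id()
    novel <- list(id = nid, seq = random_dna(sample(150:450, 1L) * 2L))
    new_chr1 <- append(new_chr1, list(novel), after = at - 1L)
  }
  # chr2: novel padding around each dispersed copy so no old neighborhood
  # maps near it (window-sized separation)
  new_chr2 <- list()
  pad <- function() list(id = new_id(), seq = random_dna(sample(150:450, 1L) * 2L))
  for (d in dispersed) {
    for (p in 1:6) new_chr2[[length(new_chr2) + 1L]] <- pad()
    new_chr2[[length(new_chr2) + 1L]] <- d
  }
  for (p in 1:6) new_chr2[[length(new_chr2) + 1L]] <- pad()

  ids1 <- vapply(new_chr1, `[[`, character(1), "id")
  ids2 <- vapply(new_chr2, `[[`, character(1), "id")
  seqs_new <- stats::setNames(
    c(vapply(new_chr1, `[[`, character(1), "seq"),
      vapply(new_chr2, `[[`, character(1), "seq")),
    c(ids1, ids2))
  features_new <- rbind(
    layout_features(ids1, nchar(seqs_new[ids1]), "chr1"),
    layout_features(ids2, nchar(seqs_new[ids2]), "chr2"))

  hits <- substring_similarity(seqs_old, seqs_new)
  self_scores <- stats::setNames(2 * nchar(seqs_old), names(seqs_old))
  truth_df <- data.frame(
    old_id = vapply(truth, `[[`, character(1), "old_id"),
    status = vapply(truth, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  truth_df$new_ids <- lapply(truth, `[[`, "new_ids")

  out <- list(features_old = features_old, features_new = features_new,
              sequences_old = seqs_old, sequences_new = seqs_new,
              hits = hits, self_scores = self_scores, truth = truth_df)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(features_old, file.path(out_dir, "old.gff3"))
    write_gff3(features_new, file.path(out_dir, "new.gff3"))
    write_fasta(seqs_old, file.path(out_dir, "old.fasta"))
    write_fasta(seqs_new, file.path(out_dir, "new.fasta"))
    write_blast_tab(hits, file.path(out_dir, "old__vs__new.tsv"))
    tt <- data.frame(old_id = truth_df$old_id, status = truth_df$status,
                     new_ids = vapply(truth_df$new_ids, paste, character(1),
                                      collapse = ","),
                     stringsAsFactors = FALSE)
    utils::write.table(tt, file.path(out_dir, "truth_translation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a three-species toy dataset with planted truth in every layer
#'
#' Three toy species (`spA`, `spB`, `spC`, ~30 genes each on one
#' chromosome) with: planted one-to-one orthologs (identical sequences;
#' the reciprocal-best-hit truth), a three-gene syntenic block present in
#' all species with one unrelated gene inserted inside it in `spC`, a
#' shared protein domain on two `spA` genes and one `spB` gene whose GO
#' annotation points at the leaf of a seven-term mini ontology `is_a`
#' chain, an expression matrix for `spA` (six conditions) with one
#' planted six-gene co-expression module, ten SNPs with known nearest
#' genes, and gene-to-pathway / gene-to-EC tables.
#'
#' @param seed Integer seed.
#' @param out_dir When given, writes the complete input tree (GFF3/FASTA
#'   per species, similarity tables for all directed species pairs,
#'   InterProScan TSVs, `mini.obo`, expression TSV, SNP TSV, pathway and
#'   EC TSVs, `config.yaml`) plus `truth/` TSVs.
#' @return List with `species` (per-species features + sequences),
#'   `hits` (named list `A__vs__B`), `self_scores` (per species),
#'   `domains` (InterProScan-shaped data frame per species),
#'   `ontology` (OBO-shaped data frame), `expression` (matrix),
#'   `snps`, `pathways`, `ec` (data frames), and `truth` (orthologs,
#'   syntenic block ids per species, module genes, domain-query gene set
#'   and parent term, SNP nearest-gene table).
#' @export
generate_multi_species_fixture <- function(seed, out_dir = NULL) {
  set.seed(seed)
  sps <- c("spA", "spB", "spC")
  n_shared <- 24L
  n_specific <- 6L
  shared_len <- sample(150:450, n_shared, replace = TRUE) * 2L
  shared_seq <- vapply(shared_len, random_dna, character(1))

  species <- list()
  block_groups <- 10:12   # ortholog groups forming the syntenic block
  for (sp in sps) {
    ids <- sprintf("%s_g%02d", sp, seq_len(n_shared))
    seqs <- stats::setNames(shared_seq, ids)
    for (j in seq_len(n_specific)) {
      sid <- sprintf("%s_s%02d", sp, j)
      seqs[sid] <- random_dna(sample(150:450, 1L) * 2L)
      ids <- c(ids, sid)
    }
    if (sp == "spC") {
      # unrelated gene inserted inside the syntenic block (between the
      # block's 2nd and 3rd genes)
      ins_id <- sprintf("%s_ins1", sp)
      ins_seq <- random_dna(sample(150:450, 1L) * 2L)
      at <- match(sprintf("%s_g%02d", sp, block_groups[3]), ids)
      ids <- append(ids, ins_id, after = at - 1L)
      seqs <- c(seqs, stats::setNames(ins_seq, ins_id))
    }
    seqs <- seqs[ids]
    species[[sp]] <- list(
      features = layout_features(ids, nchar(seqs), "chr1"),
      sequences = seqs)
  }

  # similarity tables for all directed pairs incl. self (identity scoring
  # via the substring surrogate: only identical sequences hit)
  hits <- list()
  for (a in sps) for (b in sps) {
    hits[[paste0(a, "__vs__", b)]] <-
      substring_similarity(species[[a]]$sequences, species[[b]]$sequences)
  }
  self_scores <- lapply(species, function(s)
    stats::setNames(2 * nchar(s$sequences), names(s$sequences)))

  ortho_truth <- do.call(rbind, lapply(utils::combn(sps, 2, simplify = FALSE),
    function(pr) data.frame(
      species_a = pr[1], species_b = pr[2],
      a_id = sprintf("%s_g%02d", pr[1], seq_len(n_shared)),
      b_id = sprintf("%s_g%02d", pr[2], seq_len(n_shared)),
      stringsAsFactors = FALSE)))

  # mini ontology: 7 terms, 6 is_a edges, one chain of interest
  ontology <- data.frame(
    term_id = sprintf("GO:%07d", 1:7),
    name = c("biological process root", "cell differentiation",
             "specialized cell differentiation", "metabolic process",
             "transport", "ion transport", "sodium ion transport"),
    namespace = "biological_process",
    obsolete = FALSE, stringsAsFactors = FALSE)
  ontology$is_a_parents <- list(character(0), "GO:0000001", "GO:0000002",
                                "GO:0000001", "GO:0000001", "GO:0000005",
                                "GO:0000006")

  # shared domain on 2 spA genes and 1 spB gene, annotated to the leaf of
  # the differentiation chain; a second domain drives enrichment truth
  ipr_row <- function(pid, acc, desc, go) {
    data.frame(protein_id = pid, analysis = "Pfam", signature_acc = acc,
               signature_desc = desc, start = 1L, stop = 50L, score = 1e-10,
               interpro_acc = NA_character_, go_terms = I(list(go)),
               stringsAsFactors = FALSE)
  }
  domains <- list(
    spA = rbind(ipr_row("spA_g05", "PF00001", "shared differentiation domain",
                        "GO:0000003"),
                ipr_row("spA_g06", "PF00001", "shared differentiation domain",
                        "GO:0000003"),
                ipr_row("spA_g01", "PF00002", "sodium transporter",
                        "GO:0000007"),
                ipr_row("spA_g02", "PF00002", "sodium transporter",
                        "GO:0000007"),
                ipr_row("spA_g03", "PF00002", "sodium transporter",
                        "GO:0000007"),
                ipr_row("spA_g04", "PF00003", "metabolic enzyme",
                        "GO:0000004")),
    spB = ipr_row("spB_g05", "PF00001", "shared differentiation domain",
                  "GO:0000003"))

  # expression for spA: planted 6-gene module on a latent profile
  conditions <- sprintf("c%d", 1:6)
  module_genes <- sprintf("spA_g%02d", 13:18)
  latent <- c(2, 4, 8, 16, 12, 6)
  ids_a <- names(species$spA$sequences)
  expr <- matrix(0, nrow = length(ids_a), ncol = length(conditions),
                 dimnames = list(ids_a, conditions))
  for (g in ids_a) {
    if (g %in% module_genes) {
      gain <- stats::runif(1, 0.5, 2)
      expr[g, ] <- latent * gain * (1 + stats::rnorm(6, 0, 0.02))
    } else {
      expr[g, ] <- stats::runif(6, 0, 20)
    }
  }
  expr <- round(pmax(expr, 0), 3)

  # SNPs on spA chr1 with nearest gene known by construction: the
  # inter-gene gap is 200, so end+49 is 50 bases from the left gene and
  # 151 from the right one
  fa <- species$spA$features
  snp_rows <- list()
  for (j in 1:10) {
    g <- fa[j, ]
    if (j %% 2 == 1) {
      pos <- g$start + 10L; dist <- 0L; genic <- TRUE
    } else {
      pos <- g$end + 49L; dist <- 50L; genic <- FALSE
    }
    snp_rows[[j]] <- data.frame(snp_id = sprintf("snp%02d", j),
                                landmark = "spA:chr1", position = pos,
                                nearest = g$feature_id, distance = dist,
                                genic = genic, stringsAsFactors = FALSE)
  }
  snp_truth <- do.call(rbind, snp_rows)
  snps <- snp_truth[, c("snp_id", "landmark", "position")]

  pathways <- data.frame(
    source_id = sprintf("spA_g%02d", 1:10),
    rel_type = "IN_PATHWAY",
    target_id = rep(c("PWY-0001", "PWY-0002"), each = 5),
    stringsAsFactors = FALSE)
  pathways$attributes <- replicate(nrow(pathways), list(), simplify = FALSE)
  ec <- data.frame(
    source_id = sprintf("spA_g%02d", 1:4),
    rel_type = "HAS_EC",
    target_id = c("EC:1.1.1.1", "EC:1.1.1.1", "EC:2.7.7.6", "EC:3.2.1.4"),
    stringsAsFactors = FALSE)
  ec$attributes <- replicate(nrow(ec), list(), simplify = FALSE)

  truth <- list(
    orthologs = ortho_truth,
    block = list(spA = sprintf("spA_g%02d", block_groups),
                 spB = sprintf("spB_g%02d", block_groups),
                 spC = sprintf("spC_g%02d", block_groups)),
    block_insertion_species = "spC",
    module_genes = module_genes,
    fig_domain_genes = c("spA_g05", "spA_g06", "spB_g05"),
    domain_parent_term = "GO:0000002",
    snp_truth = snp_truth)

  out <- list(species = species, hits = hits, self_scores = self_scores,
              domains = domains, ontology = ontology, expression = expr,
              snps = snps, pathways = pathways, ec = ec, truth = truth)
  if (!is.null(out_dir)) write_fixture_tree(out, out_dir)
  out
}

write_obo <- function(ontology, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology))) {
    writeLines("[Term]", con)
    writeLines(sprintf("id: %s", ontology$term_id[i]), con)
    writeLines(sprintf("name: %s", ontology$name[i]), con)
    writeLines(sprintf("namespace: %s", ontology$namespace[i]), con)
    for (p in ontology$is_a_parents[[i]]) {
      writeLines(sprintf("is_a: %s ! %s", p,
                         ontology$name[match(p, ontology$term_id)]), con)
    }
    if (ontology$obsolete[i]) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  invisible(path)
}

write_interproscan_tsv <- function(domains, path) {
  lines <- vapply(seq_len(nrow(domains)), function(i) {
    paste(c(domains$protein_id[i], "md5", "999", domains$analysis[i],
            domains$signature_acc[i], domains$signature_desc[i],
            domains$start[i], domains$stop[i],
            format(domains$score[i], scientific = TRUE), "T", "01-01-2020",
            "-", "-", paste(domains$go_terms[[i]], collapse = "|")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_expression_tsv <- function(expr, path) {
  lines <- c(paste(c("gene_id", colnames(expr)), collapse = "\t"),
             vapply(rownames(expr), function(g)
               paste(c(g, format(expr[g, ], trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

write_fixture_tree <- function(fx, out_dir) {
  dir.create(file.path(out_dir, "homology"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  for (sp in names(fx$species)) {
    write_gff3(fx$species[[sp]]$features, file.path(out_dir, paste0(sp, ".gff3")))
    write_fasta(fx$species[[sp]]$sequences, file.path(out_dir, paste0(sp, ".fasta")))
  }
  for (nm in names(fx$hits)) {
    write_blast_tab(fx$hits[[nm]], file.path(out_dir, "homology", paste0(nm, ".tsv")))
  }
  for (sp in names(fx$domains)) {
    write_interproscan_tsv(fx$domains[[sp]],
                           file.path(out_dir, paste0(sp, ".ipr.tsv")))
  }
  write_obo(fx$ontology, file.path(out_dir, "mini.obo"))
  write_expression_tsv(fx$expression, file.path(out_dir, "spA.expr.tsv"))
  snps_out <- fx$snps
  snps_out$position <- snps_out$position + 1L  # SNP TSVs are 1-based
  utils::write.table(snps_out, file.path(out_dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(gene = fx$pathways$source_id, pathway = fx$pathways$target_id),
    file.path(out_dir, "pathways.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene = fx$ec$source_id, ec = fx$ec$target_id),
    file.path(out_dir, "ec.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth$orthologs,
                     file.path(out_dir, "truth", "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth$snp_truth,
                     file.path(out_dir, "truth", "snp_nearest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(
    species = lapply(names(fx$species), function(sp) {
      s <- list(name = sp, gff3 = paste0(sp, ".gff3"),
                fasta = paste0(sp, ".fasta"))
      if (sp %in% names(fx$domains)) s$interproscan <- paste0(sp, ".ipr.tsv")
      if (sp == "spA") s$expression <- "spA.expr.tsv"
      s
    }),
    ontology = "mini.obo",
    homology_dir = "homology",
    snps = "snps.tsv",
    generic = list(
      list(file = "pathways.tsv", source = "gene", target = "pathway",
           rel_type = "IN_PATHWAY", target_label = "Pathway"),
      list(file = "ec.tsv", source = "gene", target = "ec",
           rel_type = "HAS_EC", target_label = "ECNumber")),
    thresholds = list(min_abs_r = 0.8))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
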