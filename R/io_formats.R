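#' Parse a GFF3 annotation file
#'
#' Reads 9-column GFF3. Coordinates are converted from GFF3's 1-based
#' inclusive convention to the package-internal 0-based half-open
#' convention at this boundary (so `start = col4 - 1`, `end = col5`);
#' all interval arithmetic downstream assumes half-open intervals.
#' Comment and directive lines are skipped (an inline `##FASTA` section
#' terminates parsing); attribute keys are matched case-insensitively for
#' `ID` and `Parent`. Records with `end < start` are skipped with a warning
#' naming the line; a wrong column count is a hard parse error.
#'
#' @param path GFF3 file.
#' @return A data frame of features in file order with columns `feature_id`,
#'   `landmark`, `start`, `end` (0-based half-open), `strand` (`+`/`-`/`.`),
#'   `ftype`, `parent_id` (`NA` when absent) and list-column `attributes`.
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "##FASTA")) break
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop(sprintf("GFF3 parse error at line %d of %s: expected 9 columns, found %d",
                   i, path, length(f)), call. = FALSE)
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) {
      stop(sprintf("GFF3 parse error at line %d of %s: non-numeric coordinates",
                   i, path), call. = FALSE)
    }
    if (end1 < start1) {
      warning(sprintf("GFF3 line %d of %s: end < start, record skipped", i, path),
              call. = FALSE)
      next
    }
    if (!f[7] %in% c("+", "-", ".")) {
      stop(sprintf("GFF3 parse error at line %d of %s: bad strand '%s'",
                   i, path, f[7]), call. = FALSE)
    }
    attrs <- parse_gff3_attributes(f[9])
    keys_lc <- tolower(names(attrs))
    id_idx <- match("id", keys_lc)
    fid <- if (!is.na(id_idx)) attrs[[id_idx]] else sprintf("%s:%s:%d-%d", f[3], f[1], start1, end1)
    parent_idx <- match("parent", keys_lc)
    parent <- if (!is.na(parent_idx)) attrs[[parent_idx]] else NA_character_
    # a feature may list several parents; the first is kept
    if (!is.na(parent)) parent <- strsplit(parent, ",", fixed = TRUE)[[1]][1]
    n <- n + 1L
    rows[[n]] <- list(feature_id = fid, landmark = f[1],
                      start = start1 - 1L, end = end1,
                      strand = f[7], ftype = f[3], parent_id = parent,
                      attributes = attrs)
  }
  rows <- rows[seq_len(n)]
  out <- data.frame(
    feature_id = vapply(rows, `[[`, character(1), "feature_id"),
    landmark = vapply(rows, `[[`, character(1), "landmark"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    ftype = vapply(rows, `[[`, character(1), "ftype"),
    parent_id = vapply(rows, `[[`, character(1), "parent_id"),
    stringsAsFactors = FALSE
  )
  out$attributes <- lapply(rows, `[[`, "attributes")
  out
}

parse_gff3_attributes <- function(s) {
  if (!nzchar(s) || s == ".") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  out <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1]]
    if (length(kv) >= 2) out[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  out
}

#' Write features back to GFF3
#'
#' Inverse of [parse_gff3()] for the fixed columns: internal 0-based
#' half-open coordinates are converted back to 1-based inclusive.
#'
#' @param features Data frame as returned by [parse_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    attrs <- sprintf("ID=%s", features$feature_id[i])
    if (!is.na(features$parent_id[i])) {
      attrs <- paste0(attrs, ";Parent=", features$parent_id[i])
    }
    writeLines(paste(features$landmark[i], ".", features$ftype[i],
                     features$start[i] + 1L, features$end[i], ".",
                     features$strand[i], ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Parse a FASTA file
#'
#' The id is the header token before the first whitespace; sequences are
#' uppercased and multi-line records joined. Duplicate ids are an error.
#'
#' @param path FASTA file.
#' @return Named character vector id -> sequence (empty for an empty file).
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(c(paste0(">", id), gsub("(.{70})", "\\1\n", sequences[[id]])), con)
  }
  invisible(path)
}

#' Parse BLAST+ tabular output (outfmt 6, 12 columns)
#'
#' The fixed 12-column dialect (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`) is the only one
#' accepted; other widths are rejected with the offending line number.
#' Alignment coordinates are kept 1-based as printed.
#'
#' @param path Tab-separated hit table.
#' @return Data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bit_score`, one row per hit in file order.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
            "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue",
            "bit_score")
  numeric_cols <- cols[3:12]
  rows <- matrix(NA_character_, nrow = length(keep), ncol = 12)
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L) {
      stop(sprintf("BLAST tabular parse error at line %d of %s: expected 12 columns, found %d",
                   i, path, length(f)), call. = FALSE)
    }
    rows[j, ] <- f
  }
  out <- data.frame(query_id = rows[, 1], subject_id = rows[, 2],
                    stringsAsFactors = FALSE)
  for (k in 3:12) {
    v <- suppressWarnings(as.numeric(rows[, k]))
    bad <- which(is.na(v) & !is.na(rows[, k]))
    if (length(bad)) {
      stop(sprintf("BLAST tabular parse error at line %d of %s: non-numeric '%s' in column %d",
                   keep[bad[1]], path, rows[bad[1], k], k), call. = FALSE)
    }
    out[[cols[k]]] <- v
  }
  for (k in c("aln_length", "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end")) {
    out[[k]] <- as.integer(out[[k]])
  }
  out
}

#' Parse an InterProScan TSV
#'
#' Accepts the standard InterProScan tab-separated dialect: at least 11
#' columns, with columns 12-14 (InterPro accession/description,
#' pipe-separated GO list) optional. `-` marks an absent value. GO ids not
#' matching `GO:` followed by 7 digits are dropped with a warning.
#'
#' @param path InterProScan TSV.
#' @return Data frame with columns `protein_id`, `analysis`,
#'   `signature_acc`, `signature_desc`, `start`, `stop` (1-based residues),
#'   `score` (`NA` when absent), `interpro_acc` (`NA` when absent) and
#'   list-column `go_terms`.
#' @export
parse_interproscan_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      stop(sprintf("InterProScan parse error at line %d of %s: expected >= 11 columns, found %d",
                   i, path, length(f)), call. = FALSE)
    }
    absent <- function(x) is.na(x) || !nzchar(x) || x == "-"
    go_raw <- if (length(f) >= 14 && !absent(f[14])) strsplit(f[14], "|", fixed = TRUE)[[1]] else character(0)
    go_raw <- sub("\\(.*\\)$", "", go_raw)  # tolerate GO:0000001(InterPro) style
    ok <- grepl("^GO:\\d{7}$", go_raw)
    if (any(!ok)) {
      warning(sprintf("line %d of %s: dropping malformed GO ids: %s", i, path,
                      paste(go_raw[!ok], collapse = ", ")), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[7]))
    stop_ <- suppressWarnings(as.integer(f[8]))
    if (is.na(start) || is.na(stop_) || start > stop_) {
      stop(sprintf("InterProScan parse error at line %d of %s: bad coordinates '%s'-'%s'",
                   i, path, f[7], f[8]), call. = FALSE)
    }
    rows[[j]] <- list(
      protein_id = f[1], analysis = f[4], signature_acc = f[5],
      signature_desc = f[6], start = start, stop = stop_,
      score = if (absent(f[9])) NA_real_ else as.numeric(f[9]),
      interpro_acc = if (length(f) >= 12 && !absent(f[12])) f[12] else NA_character_,
      go_terms = go_raw[ok]
    )
  }
  out <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), "protein_id"),
    analysis = vapply(rows, `[[`, character(1), "analysis"),
    signature_acc = vapply(rows, `[[`, character(1), "signature_acc"),
    signature_desc = vapply(rows, `[[`, character(1), "signature_desc"),
    start = vapply(rows, `[[`, integer(1), "start"),
    stop = vapply(rows, `[[`, integer(1), "stop"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    interpro_acc = vapply(rows, `[[`, character(1), "interpro_acc"),
    stringsAsFactors = FALSE
  )
  out$go_terms <- lapply(rows, `[[`, "go_terms")
  out
}

#' Parse an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas only. `is_a` targets are taken as the id before
#' the `!` comment; `is_obsolete: true` is honored. `part_of` relationship
#' lines can optionally be treated as parent edges.
#'
#' @param path OBO file.
#' @param include_part_of Also collect `relationship: part_of` targets as
#'   parents (default `FALSE`; the default parent semantics are `is_a` only).
#' @return Data frame with `term_id`, `name`, `namespace`, `obsolete` and
#'   list-column `is_a_parents`. Parents referencing terms absent from the
#'   same document are kept and left to the importer to report.
#' @export
parse_obo <- function(path, include_part_of = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur)) return(invisible(NULL))
    if (is.null(cur$term_id)) {
      stop(sprintf("OBO parse error in %s: [Term] stanza without an id", path),
           call. = FALSE)
    }
    terms[[length(terms) + 1L]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      if (in_term) flush(cur)
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(term_id = NULL, name = "", namespace = "",
                               obsolete = FALSE, is_a_parents = character(0))
      next
    }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexpr("^[^:]+", ln))
    val <- trimws(sub("^[^:]+:", "", ln))
    if (kv == "id") cur$term_id <- val
    else if (kv == "name") cur$name <- val
    else if (kv == "namespace") cur$namespace <- val
    else if (kv == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (kv == "is_a") {
      cur$is_a_parents <- c(cur$is_a_parents, trimws(sub("!.*$", "", val)))
    } else if (include_part_of && kv == "relationship" &&
               startsWith(val, "part_of")) {
      tgt <- trimws(sub("!.*$", "", sub("^part_of", "", val)))
      cur$is_a_parents <- c(cur$is_a_parents, tgt)
    }
  }
  if (in_term) flush(cur)
  out <- data.frame(
    term_id = vapply(terms, `[[`, character(1), "term_id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$term_id)) {
    stop(sprintf("OBO parse error in %s: duplicate term id %s", path,
                 out$term_id[duplicated(out$term_id)][1]), call. = FALSE)
  }
  out$is_a_parents <- lapply(terms, `[[`, "is_a_parents")
  out
}

#' Parse a gene-by-condition expression table
#'
#' Plain TSV: header row of condition names, first column gene ids,
#' remaining cells FPKM values. Ragged rows and negative values are
#' rejected, naming the gene.
#'
#' @param path Expression TSV.
#' @return Numeric matrix, genes as rows (rownames), conditions as columns.
#' @export
parse_expression_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("expression table is empty", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  conditions <- header[-1]
  if (length(conditions) == 0) stop("expression table has no condition columns", call. = FALSE)
  n <- length(lines) - 1L
  mat <- matrix(NA_real_, nrow = n, ncol = length(conditions),
                dimnames = list(NULL, conditions))
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    gid <- f[1]
    if (length(f) != length(header)) {
      stop(sprintf("expression table row for gene '%s' has %d cells, expected %d",
                   gid, length(f) - 1L, length(conditions)), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      stop(sprintf("expression table row for gene '%s' has a non-numeric cell", gid),
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop(sprintf("negative FPKM for gene '%s'", gid), call. = FALSE)
    }
    ids[i] <- gid
    mat[i, ] <- v
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene id in expression table: %s",
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  rownames(mat) <- ids
  mat
}

#' Parse a generic relationship TSV
#'
#' The escape hatch for data without a dedicated parser (pathways, EC
#' numbers, gene interactions, ...): any TSV with a header row can be
#' mapped to relationship tuples by naming its columns.
#'
#' @param path TSV with header row.
#' @param spec Named list: `source` and `target` (column names), and either
#'   `rel_type` (a fixed relationship string) or `rel_type_col` (column
#'   holding it); optional `attributes` (character vector of columns carried
#'   onto the edge, numeric-looking values typed as numbers).
#' @return Data frame `source_id`, `rel_type`, `target_id` plus list-column
#'   `attributes`, one row per input row.
#' @export
parse_generic_tsv <- function(path, spec) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  for (k in c("source", "target")) {
    if (is.null(spec[[k]])) {
      stop(sprintf("generic TSV configuration error: spec is missing '%s'", k),
           call. = FALSE)
    }
  }
  if (is.null(spec$rel_type) && is.null(spec$rel_type_col)) {
    stop("generic TSV configuration error: spec needs 'rel_type' or 'rel_type_col'",
         call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(spec$source, spec$target, spec$rel_type_col, spec$attributes)
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols)) {
    stop(sprintf("generic TSV configuration error: column(s) %s absent from header of %s",
                 paste(sprintf("'%s'", missing_cols), collapse = ", "), path),
         call. = FALSE)
  }
  rel <- if (!is.null(spec$rel_type_col)) as.character(tab[[spec$rel_type_col]])
         else rep(spec$rel_type, nrow(tab))
  out <- data.frame(source_id = as.character(tab[[spec$source]]),
                    rel_type = rel,
                    target_id = as.character(tab[[spec$target]]),
                    stringsAsFactors = FALSE)
  attr_cols <- spec$attributes
  out$attributes <- lapply(seq_len(nrow(tab)), function(i) {
    a <- list()
    for (col in attr_cols) {
      v <- tab[[col]][i]
      num <- suppressWarnings(as.numeric(v))
      a[[col]] <- if (!is.na(num) && !is.logical(v)) num else v
    }
    a
  })
  out
}

#' Parse a SNP coordinate table (TSV or BED)
#'
#' TSV dialect: 3 columns `snp_id`, `landmark`, `position` with positions
#' 1-based (converted to the internal 0-based convention). BED dialect
#' (`*.bed`): `chrom start end [name]` with the 0-based `start` taken as
#' the SNP position.
#'
#' @param path Input file; format chosen by extension (`.bed` vs anything else).
#' @return Data frame `snp_id`, `landmark`, `position` (0-based).
#' @export
parse_snp_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (is_bed) {
      if (length(f) < 3L) {
        stop(sprintf("BED parse error at line %d of %s: expected >= 3 columns", i, path),
             call. = FALSE)
      }
      pos <- suppressWarnings(as.integer(f[2]))
      id <- if (length(f) >= 4L) f[4] else sprintf("snp_%d", i)
      list(snp_id = id, landmark = f[1], position = pos)
    } else {
      if (length(f) < 3L) {
        stop(sprintf("SNP TSV parse error at line %d of %s: expected 3 columns", i, path),
             call. = FALSE)
      }
      pos <- suppressWarnings(as.integer(f[3]))
      list(snp_id = f[1], landmark = f[2],
           position = if (is.na(pos)) NA_integer_ else pos - 1L)
    }
  })
  # a TSV header row (non-numeric position in row 1) is tolerated and dropped
  bad <- vapply(rows, function(r) is.na(r$position), logical(1))
  if (length(bad) && any(bad[-1])) {
    i <- which(bad[-1])[1] + 1L
    stop(sprintf("SNP table parse error at line %d of %s: non-numeric position",
                 i, path), call. = FALSE)
  }
  rows <- rows[!bad]
  data.frame(snp_id = vapply(rows, `[[`, character(1), "snp_id"),
             landmark = vapply(rows, `[[`, character(1), "landmark"),
             position = vapply(rows, `[[`, integer(1), "position"),
             stringsAsFactors = FALSE)
}
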