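#' Load and validate a build configuration
#'
#' The declarative YAML configuration drives database generation and is
#' meant to be kept and re-edited between builds. Recognized top-level
#' keys:
#' \describe{
#' \item{species}{list of maps with `name`, `gff3`, `fasta` and optional
#'   `interproscan`, `expression` paths}
#' \item{ontology}{OBO file path (optional)}
#' \item{homology_dir}{directory of similarity tables named
#'   `<A>__vs__<B>.tsv` for all directed pairs, self pairs included
#'   (their self scores are the BSR denominators) (optional)}
#' \item{snps}{SNP table path (optional)}
#' \item{generic}{list of generic-TSV import specs (`file` plus the
#'   column mapping of [parse_generic_tsv()] and optional
#'   `source_label`/`target_label`)}
#' \item{thresholds}{`evalue_max` (default 1e-5), `bsr_floor` (0.4),
#'   `min_abs_r` (0.9), `min_conditions` (4)}
#' }
#' Relative paths are resolved against the config file's directory. All
#' referenced files are checked and every missing path is reported in one
#' aggregated error; unknown keys are an error naming them.
#'
#' @param path YAML config file.
#' @return A validated list of class `omicsgraph_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  known <- c("species", "ontology", "homology_dir", "snps", "generic",
             "thresholds")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(cfg$species) || !length(cfg$species)) {
    stop("configuration needs at least one species", call. = FALSE)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  missing_paths <- character(0)
  check <- function(p) {
    if (!is.null(p) && !file.exists(p)) missing_paths <<- c(missing_paths, p)
    p
  }
  for (i in seq_along(cfg$species)) {
    sp <- cfg$species[[i]]
    if (is.null(sp$name) || !nzchar(sp$name)) {
      stop(sprintf("species entry %d has no name", i), call. = FALSE)
    }
    for (k in c("gff3", "fasta", "interproscan", "expression")) {
      cfg$species[[i]][[k]] <- check(resolve(sp[[k]]))
    }
    if (is.null(cfg$species[[i]]$gff3)) {
      stop(sprintf("species '%s' has no gff3 path", sp$name), call. = FALSE)
    }
  }
  cfg$ontology <- check(resolve(cfg$ontology))
  cfg$homology_dir <- check(resolve(cfg$homology_dir))
  cfg$snps <- check(resolve(cfg$snps))
  for (i in seq_along(cfg$generic)) {
    cfg$generic[[i]]$file <- check(resolve(cfg$generic[[i]]$file))
  }
  if (length(missing_paths)) {
    stop(sprintf("configuration references missing file(s):\n%s",
                 paste(" ", missing_paths, collapse = "\n")), call. = FALSE)
  }
  defaults <- list(evalue_max = 1e-5, bsr_floor = 0.4, min_abs_r = 0.9,
                   min_conditions = 4L)
  th <- cfg$thresholds
  unknown_th <- setdiff(names(th), names(defaults))
  if (length(unknown_th)) {
    stop(sprintf("unknown threshold key(s): %s",
                 paste(unknown_th, collapse = ", ")), call. = FALSE)
  }
  for (k in names(defaults)) if (is.null(th[[k]])) th[[k]] <- defaults[[k]]
  cfg$thresholds <- th
  structure(cfg, class = "omicsgraph_config")
}

#' Build the full graph from a configuration
#'
#' Runs every import layer present in the configuration, in dependency
#' order: genomes (gene-order backbone), functional annotation, ontology,
#' homology (best hits, reciprocal best hits, BSR), expression
#' (co-expression edges), generic relationships. Layers absent from the
#' config are simply skipped — downstream queries over them return empty
#' results rather than failing. Re-running over an existing graph is a
#' no-op on counts (importer idempotence).
#'
#' @param config A validated `omicsgraph_config` (see [load_config()]).
#' @param graph Optional existing [property_graph()] to extend.
#' @param quiet Suppress per-stage messages.
#' @return The populated [property_graph()].
#' @export
build_graph <- function(config, graph = property_graph(), quiet = FALSE) {
  stopifnot(inherits(config, "omicsgraph_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  for (sp in config$species) {
    say("[genome] importing %s", sp$name)
    feats <- parse_gff3(sp$gff3)
    seqs <- if (!is.null(sp$fasta)) parse_fasta(sp$fasta) else NULL
    import_genome(graph, sp$name, feats, seqs)
  }
  for (sp in config$species) {
    if (is.null(sp$interproscan)) next
    say("[annotation] importing InterProScan for %s", sp$name)
    import_functional_annotations(graph, parse_interproscan_tsv(sp$interproscan))
  }
  if (!is.null(config$ontology)) {
    say("[ontology] importing %s", config$ontology)
    import_ontology(graph, parse_obo(config$ontology))
  }
  if (!is.null(config$homology_dir)) {
    th <- config$thresholds
    names_sp <- vapply(config$species, `[[`, character(1), "name")
    selfs <- list()
    for (sp in names_sp) {
      f <- file.path(config$homology_dir, sprintf("%s__vs__%s.tsv", sp, sp))
      if (file.exists(f)) selfs[[sp]] <- self_scores_from_hits(parse_blast_tab(f))
    }
    if (length(names_sp) > 1) {
      for (pr in utils::combn(names_sp, 2, simplify = FALSE)) {
        fab <- file.path(config$homology_dir,
                         sprintf("%s__vs__%s.tsv", pr[1], pr[2]))
        fba <- file.path(config$homology_dir,
                         sprintf("%s__vs__%s.tsv", pr[2], pr[1]))
        if (!file.exists(fab) || !file.exists(fba)) next
        say("[homology] %s <-> %s", pr[1], pr[2])
        write_homology_edges(graph, parse_blast_tab(fab), parse_blast_tab(fba),
                             selfs[[pr[1]]], selfs[[pr[2]]],
                             evalue_max = th$evalue_max)
      }
    }
  }
  for (sp in config$species) {
    if (is.null(sp$expression)) next
    say("[expression] importing %s", sp$name)
    th <- config$thresholds
    build_coexpression(graph, parse_expression_table(sp$expression),
                       min_abs_r = th$min_abs_r,
                       min_conditions = th$min_conditions)
  }
  for (gen in config$generic) {
    say("[generic] importing %s", gen$file)
    tuples <- parse_generic_tsv(gen$file, gen)
    import_relationship_tuples(graph, tuples,
                               source_label = gen$source_label %||% "Gene",
                               target_label = gen$target_label %||% "Entity")
  }
  graph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate BLAST+ driver scripts
#'
#' Writes one shell script per directed species comparison (self
#' comparisons included — their self hits supply the BSR denominators),
#' each running `makeblastdb` on the subject and `blastp` with
#' `-outfmt 6`, writing `<A>__vs__<B>.tsv` so the output file names match
#' what the homology import step expects.
#'
#' @param config A validated `omicsgraph_config`.
#' @param out_dir Directory for the scripts (created if needed).
#' @return Character vector of script paths (n-squared of the species
#'   count).
#' @export
generate_blast_scripts <- function(config, out_dir) {
  stopifnot(inherits(config, "omicsgraph_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sps <- config$species
  paths <- character(0)
  for (a in sps) for (b in sps) {
    if (is.null(a$fasta) || is.null(b$fasta)) next
    nm <- sprintf("%s__vs__%s", a$name, b$name)
    p <- file.path(out_dir, paste0(nm, ".sh"))
    writeLines(c(
      "#!/bin/sh",
      "set -e",
      sprintf("makeblastdb -in '%s' -dbtype prot -out '%s_db'", b$fasta, b$name),
      sprintf("blastp -query '%s' -db '%s_db' -outfmt 6 -evalue 1e-3 -out '%s.tsv'",
              a$fasta, b$name, nm)), p)
    Sys.chmod(p, "755")
    paths <- c(paths, p)
  }
  paths
}
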