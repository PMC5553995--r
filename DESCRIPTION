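Package: omicsgraph
Title: Property-Graph Integration and Comparative Queries for Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an embedded property graph from standard-format omics files
    (GFF3 annotations, FASTA sequences, BLAST+ tabular similarity searches,
    InterProScan domain scans, OBO ontologies, FPKM expression matrices, SNP
    tables and generic relationship TSVs) and runs comparative queries over it:
    reciprocal-best-hit orthology with BLAST Score Ratios, synteny-aware
    annotation translation between genome versions with gene split/merge
    detection, gap-tolerant syntenic-region search across species,
    co-expression network construction, ontology term propagation, inferred
    annotation transfer across homology edges, GO term enrichment, and
    nearest-gene/GWAS annotation. A deterministic synthetic-fixture generator
    produces every input format with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
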