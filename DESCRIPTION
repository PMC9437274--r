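Package: varlit
Title: Keyword Association Networks from Variant-Centred Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds single-nucleotide polymorphism (SNP) interpretation
    summaries from entity-annotated biomedical literature. Reads
    PubTator-format annotated abstracts and variant-to-document (rsID to
    PMID) mappings, normalizes disease, gene and chemical mentions into
    canonical keywords, computes per-SNP keyword document frequencies and
    same-document co-occurrence counts, derives a reverse keyword-to-SNP
    ranked index, constructs filterable weighted keyword graphs (per-SNP
    and global) with GraphML, node-link JSON and TSV export, and compares
    pipeline-derived keyword sets against external per-SNP term lists.
    Includes a seeded synthetic-corpus generator with planted association
    strengths for offline validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
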