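Package: metastore
Title: Schema-Validated Linked JSON Document Store with Incremental Indexing
Version: 0.1.0
Authors@R:
    person("Metastore", "Developers", email = "devnull@example.org", role = c("aut", "cre"))
Description: A desk-scale hybrid object database for genomics metadata
    curation: a transactional JSON document store whose documents are
    validated against per-type JSON schemas extended with typed links,
    reverse links, calculated properties and versioned upgrade steps; a
    frame-based renderer that denormalises linked documents and records
    the dependency sets (embedded and linked identifiers) of every
    rendering; an incremental indexer that uses those dependency sets and
    the write-ahead transaction log to invalidate exactly the stale index
    records; cross-object audit rules with severity flags; a permissioned
    REST-style request handler with faceted search; an ENCODE-style
    demonstration schema set with a seeded synthetic metadata-graph
    generator; and an RDF (N-Triples/Turtle) exporter for the object
    graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
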