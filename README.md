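# metastore

A desk-scale hybrid object database for genomics metadata curation, written
in R. It is built for the situation data coordination centres live in:
metadata arrives as linked JSON documents (donors, biosamples, libraries,
replicates, experiments, files, antibody lots), schemas evolve continually,
curators need relational-grade integrity, and consumers need fast faceted
search over denormalised views.

The package provides, as separately usable pieces wired together by
`encode_app()`:

- a **transactional document store** (one SQLite row per JSON document, plus
  unique-key and write-ahead transaction-log tables) with schema validation,
  typed-link referential integrity, accession minting and atomic writes;
- a **schema registry** for per-type JSON schemas extended with `linkTo`,
  `uniqueKey`, reverse-link, calculated-property and facet declarations, and
  versioned upgrade chains applied on read and persisted on the next write;
- a **frame renderer** (`raw` / `object` / `embedded` / `page`) that
  computes calculated properties and reverse links while recording every
  rendering's dependency sets (`embedded_uuids`, `linked_uuids`);
- an **incremental indexer**: with U the union of `updated_uuids` and R the
  union of `renamed_uuids` since its last pass, it reindexes
  `U ∪ {r : r.embedded ∩ U ≠ ∅} ∪ {r : r.linked ∩ R ≠ ∅}` — property
  changes invalidate consumers, renames invalidate referrers — plus faceted
  search over the index;
- a **cross-object audit engine** with four severity flags and three
  shipped rules (missing donor, inconsistent biosample ontology across
  replicates, low alignment read depth);
- a **REST-style request handler** with the four-tier permission model
  (admin / submitter / consortium / base), 200/422 write semantics,
  bare-accession URL aliasing and content negotiation;
- a seeded **synthetic fixture generator** with a ground-truth manifest of
  planted audit violations; and an **RDF exporter** (N-Triples, Turtle)
  over the object-frame graph.

## Worked example

```r
library(metastore)

app <- encode_app()                       # ten demo schemas, in-memory SQLite
res <- load_fixture(fixture_config(seed = 42, n_experiments = 20), app)
str(res$counts)
#> List of 10
#>  $ antibody_lot: int 4
#>  $ award       : int 3
#>  $ biosample   : int 38
#>  $ donor       : int 32
#>  $ experiment  : int 20
#>  $ file        : int 41
#>  $ lab         : int 3
#>  $ library     : int 38
#>  $ replicate   : int 38
#>  $ user        : int 3

head(res$manifest, 3)                     # planted, ground-truth violations
#>         category                      path
#> 1  missing donor  /biosamples/TSTBS003AAA/
#> 2  missing donor  /biosamples/TSTBS007AAA/
#> 3 low read depth /experiments/TSTSR003AAA/

app$indexer$run_index_pass()              # page-frame records for all 220 docs
#> [1] 220

sr <- app$indexer$search(type = "experiment")
sr$total
#> [1] 20
str(sr$facets$assay_term_name$terms)      # facet aggregation
#> List of 3
#>  $ ChIP-seq : int 13
#>  $ DNase-seq: int 2
#>  $ RNA-seq  : int 5

# REST-style surface: invalid POSTs are 422 with the violation named
bad <- handle_request(app, "POST", "/biosamples/",
                      body = list(lifestage = "adult"),
                      prin = principal_admin(), query = list(format = "json"))
bad$status
#> [1] 422
unlist(bad$body$errors)
#> [1] "additional property 'lifestage' is not allowed"

# bare-accession alias, page frame, calculated properties
pg <- handle_request(app, "GET", "/TSTBS008AAA", prin = principal_admin(),
                     query = list(format = "json"))
c(pg$status, pg$body$summary)
#> [1] "200"  "human GM12878"
```

The numbers mean: the seed-42 graph contains 220 documents (38 biosamples
across 20 experiments, etc.); 8 audit violations were planted and their
manifest is returned with the load; one index pass renders all 220 page
frames; the experiment collection facets into 13 ChIP-seq / 5 RNA-seq /
2 DNase-seq; a schema-invalid POST is rejected with HTTP 422 naming the
offending property; and `TSTBS008AAA` resolves without its collection path
to a page whose calculated `summary` ("human GM12878") was computed at
render time, never stored.

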