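---
title: "Methods: a hybrid object store for genomics metadata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid object store for genomics metadata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomics data coordination centres curate experiments whose metadata is a
densely linked graph: donors give rise to biosamples, biosamples to
libraries, libraries are bound to experiments through replicates, and data
files point back at their home experiment. Two pressures pull such a
database in opposite directions. Curation wants flexibility — schemas that
evolve weekly, permissive required-field lists so metadata can be registered
early — while data integrity wants relational rigour: typed foreign keys,
validation, cross-object consistency checks. `metastore` resolves the
tension the way production biocuration systems do: JSON documents validated
against per-type schemas, typed links checked at write time, and a
denormalising indexer that keeps fast, query-ready copies of each document
consistent with the normalised store.

## The model

**Documents and schemas.** Every object is a JSON document with an immutable
`uuid`, an item type, a schema version and a property mapping. One schema
file per type controls the allowed fields (`additionalProperties` is always
treated as false) using a deliberately small JSON-Schema vocabulary —
`type`, `enum`, `pattern`, `required`, `properties`, `items`,
`format: "date"` — extended with custom keywords: `linkTo` (typed link,
checked for referential integrity at write time), `uniqueKey` (global
unique-key registration, e.g. accessions of the shape `TSTBS012AAB`), `rev`
(reverse-link declarations), `calculatedProperties`, and `facets`. Link
values are normalised to target uuids when stored; any unique key, accession
or canonical path is accepted on input.

**Frames.** A document renders at four depths. `raw` is the stored
(upgraded) property mapping. `object` adds `@id`/`@type`/`uuid` metadata,
converts links to canonical paths, and attaches calculated properties —
including reverse links such as an experiment's `files`, computed from the
file documents' own `dataset` pointers. `embedded` substitutes selected
links with copies of the targets' object frames, along per-type embed paths
(e.g. `replicates.library.biosample`). `page` is `embedded` plus audit
results grouped by severity.

**Dependency recording and invalidation.** Every rendering records two
sets: `embedded_uuids` — documents copied into the body or whose properties
were consulted (always including the document itself and reverse-link
children) — and `linked_uuids` — documents referenced only by canonical
path. Each write appends a transaction carrying `updated_uuids` and
`renamed_uuids` (a *rename* is a change to the key from which the canonical
path is minted: the accession, or a type's name key). An index pass takes
U = ∪ updated and R = ∪ renamed since its last pass and reindexes

> U ∪ { records r : r.embedded_uuids ∩ U ≠ ∅ } ∪
> { records r : r.linked_uuids ∩ R ≠ ∅ }

so a property change invalidates exactly the records that consulted the
document, while documents referenced only by path invalidate their
referrers only when their path changes.

One augmentation closes a gap the intersection rule alone cannot: when a
write adds, removes or retargets a link, the old and new targets are added
to that transaction's `updated_uuids`. Without it, a *newly created* file
could never invalidate its home experiment — the experiment's previous
rendering never consulted a child that did not exist.

**Audits.** Cross-object integrity rules run against the embedded rendering
whenever a document is indexed. Because a predicate may read only the
embedded body, everything it consults is by construction inside
`embedded_uuids`, so stored findings can never go stale under the rubric
above. Three rules ship: a human biosample without a donor (ERROR),
replicates of one experiment deriving from biosamples with different
ontology terms (ERROR), and an alignment file below a per-assay minimum of
uniquely mapped reads (WARNING). The four severity flags are ERROR,
WARNING, NOT_COMPLIANT and INTERNAL_ACTION; a crashing rule is reported as
an INTERNAL_ACTION finding rather than failing the pass.

**Permissions.** Four tiers: *admin* edits everything; *submitter* edits
unreleased objects of labs they submit for; *consortium* views unreleased
data within their project; *base* (and anonymous) sees released data only.
Submitters of one project (e.g. ENCODE vs GGR) can neither view nor edit
another project's unreleased data; a document's project is resolved through
its award. Reads of invisible objects return 404 rather than 403 so the
existence of unreleased accessions is not leaked; forbidden writes on
visible objects return 403.

**Schema upgrades.** Each type carries a chain of pure upgrade steps
(v → v+1). Reads upgrade on the fly without touching the stored row; the
upgraded form is persisted only when the document is next written. The
shipped chains coerce a legacy string `starting_amount` to a number
(biosample 1→2) and rename `assay_name` to `assay_term_name`
(experiment 1→2).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `read_depth_min` | ChIP-seq 2e7, RNA-seq 3e7, DNase-seq 2e7 reads | per-assay audit thresholds; configuration, standing in for consortium-set standards |
| `fixture_config(n_experiments)` | 20 | experiments in a generated graph |
| `fixture_config(assays)` | ChIP-seq .5 / RNA-seq .3 / DNase-seq .2 | assay sampling weights |
| `fixture_config(replicate_rate, file_rate)` | 2, 2 | expected replicates/files per experiment (min 1, 1 + Poisson) |
| `fixture_config(released_fraction)` | 0.7 | probability an object is released |
| `fixture_config(violation_rates)` | 0.1 per category | probability of planting each audit violation |

## What the synthetic generator does and does not emulate

`generate_fixture()` emits a referentially closed graph in dependency order
— awards, labs and submitters, then per experiment a donor → biosample →
library → replicate chain, data files, and an antibody lot for ChIP-seq —
with accessions minted in the real systems' shape (`TST` + type code +
3 digits + 3 letters, visually distinct from any real accession). Violations
are planted per category at configurable rates, with a ground-truth manifest;
outside the manifest the graph is guaranteed audit-clean, which is what lets
the audit acceptance test demand *exact* recovery. Defaults were chosen once
as a realistic small submission (three labs, mixed assays, ~30% unreleased
objects, ~10% curation errors) and are not tuned to test outcomes.

The generator does **not** emulate: real controlled vocabularies (five
hard-coded biosample terms and three assays suffice to exercise enums,
facets and mismatch audits), skewed lab sizes, attachment documents, file
hierarchies (derived-from chains), or the long-tail type diversity of a
production deployment (ten types rather than ~75). A green suite therefore
establishes the *mechanisms* — validation, invalidation, permissions,
audits — not fidelity to any real corpus.

## Numerical and procedural choices

- **Determinism.** Generation saves and restores the session RNG state and
  is a pure function of its config; uuids are minted from the RNG so a seed
  reproduces the byte-identical document set. Reverse links order children
  by accession then uuid; audit findings order by category then path; a
  store whose RNG stream collides with bulk-loaded uuids re-mints.
- **Cycles.** When an embed path revisits a document already on the
  embedding stack it is emitted as a canonical path (left linked), which
  guarantees termination without a global depth limit.
- **`indexed_tid`.** An untouched record keeps the tid of the pass that
  rendered it; a from-scratch rebuild stamps everything at head. The
  rebuild oracle therefore compares record *content* (body plus dependency
  sets), which is the consistency the rubric promises.
- **Patch semantics.** PATCH merges top-level keys; a JSON `null` removes a
  key; PUT replaces the body (releasing keys omitted from it, which counts
  as a rename if the path key changed).
- **Empty patches** still log a transaction: callers that touch a document
  expect it to reindex.

## Design choices where the design was open

- **POST vs PUT.** The operational contract is POST-to-collection creates,
  PATCH merges, PUT replaces an existing item; write success is 200.
- **Pull indexing.** The indexer drains the transaction log on demand
  rather than subscribing to notifications — the same rubric, deterministic
  for testing, and a thin adapter boundary for a server-grade engine.
- **Index contents.** Only the page frame is indexed; other frames are
  served by live render, since only the embedded/page frame participates in
  invalidation. Deleted documents leave the index entirely (visibility
  rules make them unreachable, and facet counts stay meaningful).
- **Live visibility.** Search results are permission-trimmed by consulting
  the store at query time rather than a snapshot stored in the index, so a
  project or status change never serves stale permissions at the cost of a
  per-result lookup.
- **Audit severities.** The missing-donor rule ships as ERROR (an
  assumption: the flag is not stated for it anywhere authoritative), the
  ontology-mismatch rule as ERROR by analogy with data-inconsistency flags,
  and low read depth as WARNING. The third flag is spelled NOT_COMPLIANT.
- **RDF export** operates on object frames only: triples reference linked
  resources by IRI instead of duplicating embedded copies, and nested
  value mappings flatten to dotted predicate names rather than blank nodes,
  keeping serializations deterministic and diffable.

## Known limitations

- The request handler is an in-process surface with the HTTP contract
  (methods, status codes, content negotiation) but no socket transport;
  principals arrive as arguments, standing in for an authentication layer.
- A change to an award's `project` does not reindex documents that resolve
  their project through it (visibility is computed live, so permissions are
  still correct; only the stored bodies are untouched, as they do not
  contain the project).
- Embedded sub-objects are permission-trimmed to their `@id` at serve time;
  field-level trimming (hiding individual properties) is not implemented.
- Validation covers the schema subset the shipped schemas use, not an
  arbitrary JSON-Schema draft.
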