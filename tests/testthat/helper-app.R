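# Shared builders and oracles for the suite. Everything is generated in
# code at test time; no stored fixtures.

make_app <- function(...) encode_app(...)

# app preloaded with a seeded synthetic graph
make_fixture_app <- function(seed = 7, n_experiments = 5, ...) {
  app <- make_app()
  fx <- generate_fixture(fixture_config(seed = seed, n_experiments = n_experiments, ...))
  load_fixture(fx, app)
  attr(app, "fixture") <- fx
  app
}

# canonical serialization of one index record (order-stable). indexed_tid is
# excluded: an untouched record keeps the tid of the pass that rendered it,
# while a from-scratch rebuild stamps everything at head; content equality is
# what the oracle asserts.
record_json <- function(r) {
  metastore:::to_json_chr(list(uuid = r$uuid, item_type = r$item_type,
                               body = r$body,
                               embedded_uuids = as.list(r$embedded_uuids),
                               linked_uuids = as.list(r$linked_uuids)))
}

index_snapshot <- function(indexer) {
  vapply(indexer$all_records(), record_json, character(1))
}

# from-scratch rebuild oracle: a fresh index over the same store must equal
# the incrementally maintained one record-for-record
expect_index_equals_rebuild <- function(app) {
  fresh <- Indexer$new(app$renderer, app$auditor)
  fresh$run_index_pass()
  expect_identical(index_snapshot(app$indexer), index_snapshot(fresh))
}

# a schema-valid patch for any fixture type (non-path properties only)
patch_for_type <- function(type, tag) {
  switch(type,
    biosample = list(description = tag),
    experiment = list(description = tag),
    donor = list(age = "99"),
    lab = list(institute = tag),
    award = list(title = tag),
    user = list(first_name = tag),
    library = list(nucleic_acid_term_name = "DNA"),
    replicate = list(technical_replicate_number = 2L),
    file = list(mapped_read_count = 98765432L),
    antibody_lot = list(lot_id = tag),
    stop("no patch for type ", type))
}

# a fresh, non-colliding path-key value for rename tests
.rename_counter <- new.env(parent = emptyenv())
fresh_key_value <- function(type) {
  n <- (.rename_counter$n %||% 0L) + 1L
  .rename_counter$n <- n
  code <- unname(c(donor = "DO", biosample = "BS", library = "LB",
                   experiment = "SR", file = "FF", antibody_lot = "AB")[type])
  if (!is.na(code)) metastore:::mint_accession(code, 17000L + n)
  else paste0("renamed-", type, "-", n)   # lab/award/user name keys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one random mixed write (create / patch / rename / delete) against an app
# loaded with the synthetic graph; draws from the session RNG
random_write <- function(app) {
  store <- app$store
  op <- sample(c("create_file", "create_biosample", "patch", "rename", "delete"),
               1, prob = c(0.2, 0.1, 0.4, 0.15, 0.15))
  pick <- function(types) {
    pool <- unlist(lapply(types, store$uuids_of_type))
    if (!length(pool)) return(NULL)
    sample(pool, 1)
  }
  switch(op,
    create_file = {
      exp <- pick("experiment")
      if (is.null(exp)) return(invisible(NULL))
      store$create_item("file", list(
        dataset = exp, file_format = "bam", output_type = "alignments",
        mapped_read_count = as.integer(3e7 + sample.int(1e6, 1))))
    },
    create_biosample = store$create_item("biosample", list(
      organism = "mouse", biosample_term_name = "hepatocyte",
      biosample_term_id = "CL:0000182")),
    patch = {
      u <- pick(c("biosample", "experiment", "lab", "file", "donor"))
      store$update_item(u, patch_for_type(store$get_item(u)$item_type,
                                          paste0("tag-", sample.int(1e6, 1))))
    },
    rename = {
      u <- pick(c("biosample", "experiment", "file", "lab"))
      doc <- store$get_item(u)
      key <- app$registry$path_key_field(doc$item_type)
      store$update_item(u, stats::setNames(list(fresh_key_value(doc$item_type)), key))
    },
    delete = {
      u <- pick(c("file", "replicate", "biosample"))
      store$update_item(u, list(status = "deleted"))
    })
  invisible(NULL)
}
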