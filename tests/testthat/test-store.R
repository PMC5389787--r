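test_that("create_item persists, mints server fields, and logs one transaction", {
  app <- make_app()
  lab <- app$store$create_item("lab", list(name = "some-lab", title = "Some Lab"))
  bs <- app$store$create_item("biosample", list(
    organism = "mouse", biosample_term_name = "hepatocyte", lab = "some-lab"))
  expect_match(bs$uuid, metastore:::UUID_RE)
  expect_match(bs$properties$accession, "^TSTBS[0-9]{3}[A-Z]{3}$")
  expect_identical(bs$properties$status, "in progress")      # schema default
  expect_identical(bs$properties$lab, lab$uuid)              # link stored as uuid
  txns <- app$store$transactions_since(0)
  expect_length(txns, 2)
  expect_true(bs$uuid %in% txns[[2]]$updated_uuids)
  expect_true(lab$uuid %in% txns[[2]]$updated_uuids)         # link-delta target
})

test_that("empty properties against a permissive schema create a document", {
  app <- make_app()
  doc <- app$store$create_item("biosample", list())
  expect_match(doc$properties$accession, "^TSTBS")
  expect_identical(doc$properties$status, "in progress")
})

test_that("rejected writes leave the store byte-identical (atomicity)", {
  app <- make_app()
  app$store$create_item("biosample", list(accession = "TSTBS000AAA"))
  before <- app$store$dump_json()
  log_before <- length(app$store$log_records())
  expect_error(app$store$create_item("biosample", list(accession = "TSTBS000AAA")),
               class = "duplicate_unique_key")
  expect_error(app$store$create_item("biosample", list(flavour = "grape")),
               class = "validation_failure")
  expect_error(app$store$create_item("biosample", list(donor = "no-such-donor")),
               class = "dangling_link")
  expect_error(app$store$create_item("nonsense", list()), class = "unknown_type")
  expect_identical(app$store$dump_json(), before)
  expect_length(app$store$log_records(), log_before)
})

test_that("update_item patches, logs, and records renames", {
  app <- make_app()
  exp <- app$store$create_item("experiment", list(
    accession = "TSTSR000AAA", assay_term_name = "ChIP-seq",
    assay_term_id = "OBI:0000716"))
  upd <- app$store$update_item(exp$uuid, list(
    assay_term_name = "RNA-seq", assay_term_id = "OBI:0001271"))
  expect_identical(upd$properties$assay_term_name, "RNA-seq")
  expect_identical(upd$properties$assay_term_id, "OBI:0001271")

  # empty patch: document unchanged, transaction still logged
  n0 <- length(app$store$log_records())
  same <- app$store$update_item(exp$uuid, list())
  expect_identical(same$properties, upd$properties)
  txns <- app$store$log_records()
  expect_length(txns, n0 + 1)
  expect_true(exp$uuid %in% txns[[length(txns)]]$updated_uuids)
  expect_length(txns[[length(txns)]]$renamed_uuids, 0)

  # accession change appears in both updated and renamed
  app$store$update_item(exp$uuid, list(accession = "TSTSR000AAB"))
  last <- app$store$log_records()[[length(app$store$log_records())]]
  expect_true(exp$uuid %in% last$updated_uuids)
  expect_identical(last$renamed_uuids, exp$uuid)
  expect_identical(app$store$resolve_identifier("TSTSR000AAB")$uuid, exp$uuid)
  expect_error(app$store$resolve_identifier("TSTSR000AAA"),
               class = "unresolvable_token")
})

test_that("patch null removes a property; replace substitutes the body", {
  app <- make_app()
  bs <- app$store$create_item("biosample", list(description = "old",
                                                organism = "mouse"))
  patched <- app$store$update_item(bs$uuid,
                                   metastore:::from_json('{"description": null}'))
  expect_null(patched$properties$description)
  replaced <- app$store$update_item(bs$uuid,
    list(accession = bs$properties$accession, biosample_term_name = "K562"),
    mode = "replace")
  expect_null(replaced$properties$organism)
  expect_identical(replaced$properties$biosample_term_name, "K562")
})

test_that("get_item by uuid and by unique keys returns the same document", {
  app <- make_app()
  bs <- app$store$create_item("biosample", list(
    aliases = list("some-lab:my-sample")))
  by_uuid <- app$store$get_item(bs$uuid)
  by_acc <- app$store$get_item(bs$properties$accession)
  by_alias <- app$store$get_item("some-lab:my-sample")
  by_path <- app$store$get_item(paste0("/biosamples/", bs$properties$accession, "/"))
  for (other in list(by_acc, by_alias, by_path)) {
    expect_identical(other$uuid, by_uuid$uuid)
    expect_identical(other$properties, by_uuid$properties)
  }
})

test_that("the store is status-agnostic: deleted documents are returned", {
  app <- make_app()
  bs <- app$store$create_item("biosample", list())
  app$store$update_item(bs$uuid, list(status = "deleted"))
  expect_identical(app$store$get_item(bs$uuid)$properties$status, "deleted")
})

test_that("resolve_identifier handles uuids, keys and misses", {
  app <- make_app()
  exp <- app$store$create_item("experiment", list())
  hit <- app$store$resolve_identifier(exp$uuid)
  expect_identical(hit, list(item_type = "experiment", uuid = exp$uuid))
  expect_identical(app$store$resolve_identifier(exp$properties$accession)$uuid,
                   exp$uuid)
  expect_error(app$store$resolve_identifier("XXXX"), class = "unresolvable_token")
})

test_that("transactions_since returns strictly ordered suffixes of the log", {
  app <- make_app()
  expect_length(app$store$transactions_since(0), 0)
  for (i in 1:3) app$store$create_item("biosample", list())
  txns <- app$store$transactions_since(0)
  expect_length(txns, 3)
  tids <- vapply(txns, `[[`, 0, "tid")
  expect_true(all(diff(tids) > 0))
  expect_length(app$store$transactions_since(app$store$head_tid()), 0)
  expect_length(app$store$transactions_since(tids[[2]]), 1)
})

test_that("key bijectivity and log replay hold over a randomized workload", {
  set.seed(101)
  app <- make_fixture_app(seed = 11, n_experiments = 3)
  for (i in 1:60) random_write(app)

  # each (key_name, key_value) resolves to exactly one uuid whose own keys
  # round-trip (resolve . mint = identity)
  for (u in app$store$all_uuids()) {
    doc <- app$store$get_item(u)
    uk <- app$registry$unique_key_fields(doc$item_type)
    for (nm in names(uk)) {
      for (v in unlist(doc$properties[[nm]])) {
        expect_identical(app$store$resolve_identifier(v)$uuid, u)
      }
    }
  }

  # replaying the write-ahead log into an empty store reproduces the state
  replica <- DocumentStore$new(app$registry)
  replica$replay(app$store$log_records())
  expect_identical(replica$dump_json(), app$store$dump_json())
})

test_that("documents are not duplicated across distinct unique keys", {
  app <- make_app()
  app$store$create_item("experiment", list(aliases = list("lab:alpha")))
  expect_error(
    app$store$create_item("experiment", list(aliases = list("lab:alpha"))),
    class = "duplicate_unique_key")
})
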