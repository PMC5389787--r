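# two labs (L, M) with one document in each status, for ACL enumerations
acl_app <- function() {
  app <- make_app()
  s <- app$store
  labL <- s$create_item("lab", list(name = "lab-l", status = "released"))
  labM <- s$create_item("lab", list(name = "lab-m", status = "released"))
  docs <- list()
  for (lab in c(labL$uuid, labM$uuid)) {
    for (st in c("released", "in progress")) {
      d <- s$create_item("biosample", list(lab = lab, status = st,
                                           organism = "mouse"))
      docs[[paste(lab, st)]] <- d
    }
  }
  list(app = app, labL = labL$uuid, labM = labM$uuid, docs = docs)
}

test_that("authorize: admin always; base sees released only", {
  x <- acl_app()
  adm <- principal_admin(); anon <- principal_anonymous()
  for (d in x$docs) {
    for (act in c("view", "edit", "create")) {
      expect_true(authorize(adm, d$properties$status, d$properties$lab,
                            action = act)$allowed)
    }
    dec <- authorize(anon, d$properties$status, d$properties$lab, action = "view")
    expect_identical(dec$allowed, identical(d$properties$status, "released"))
    expect_false(authorize(anon, d$properties$status, d$properties$lab,
                           action = "edit")$allowed)
  }
})

test_that("submitter edit truth table over lab x status", {
  x <- acl_app()
  sub <- principal("u1", "submitter", lab_groups = x$labL)
  truth <- list(                       # (lab, status) -> may edit
    list(lab = x$labL, status = "released", edit = FALSE),
    list(lab = x$labL, status = "in progress", edit = TRUE),
    list(lab = x$labM, status = "released", edit = FALSE),
    list(lab = x$labM, status = "in progress", edit = FALSE))
  for (case in truth) {
    dec <- authorize(sub, case$status, case$lab, action = "edit")
    expect_identical(dec$allowed, case$edit)
  }
})

test_that("visibility is monotone: base <= consortium (same project) <= admin", {
  app <- make_fixture_app(seed = 41, n_experiments = 6)
  app$indexer$run_index_pass()
  seen <- function(prin) {
    vapply(app$indexer$search(principal = prin)$results, `[[`, "", "@id")
  }
  v_base <- seen(principal_anonymous())
  v_cons <- seen(principal("c", "consortium", project_scope = "ENCODE"))
  v_admin <- seen(principal_admin())
  expect_true(all(v_base %in% v_cons))
  expect_true(all(v_cons %in% v_admin))
})

test_that("cross-project unreleased data is hidden from the other project", {
  app <- make_app()
  s <- app$store
  aw_e <- s$create_item("award", list(name = "aw-encode", project = "ENCODE"))
  aw_g <- s$create_item("award", list(name = "aw-ggr", project = "GGR"))
  b_e <- s$create_item("biosample", list(award = aw_e$uuid, status = "in progress"))
  b_g <- s$create_item("biosample", list(award = aw_g$uuid, status = "in progress"))
  enc <- principal("e", "consortium", project_scope = "ENCODE")
  res_e <- handle_request(app, "GET", paste0("/biosamples/", b_e$properties$accession, "/"),
                          prin = enc)
  res_g <- handle_request(app, "GET", paste0("/biosamples/", b_g$properties$accession, "/"),
                          prin = enc)
  expect_identical(res_e$status, 200L)
  expect_identical(res_g$status, 404L)        # existence not leaked
})

test_that("POST returns 200 for valid and 422 for invalid bodies", {
  app <- make_app()
  ok <- handle_request(app, "POST", "/biosamples/",
                       body = list(organism = "human",
                                   biosample_term_name = "K562"),
                       prin = principal_admin())
  expect_identical(ok$status, 200L)
  expect_match(ok$body$`@graph`[[1]]$accession, "^TSTBS")

  bad <- handle_request(app, "POST", "/biosamples/",
                        body = list(lifestage = "adult"),
                        prin = principal_admin())
  expect_identical(bad$status, 422L)
  expect_match(paste(unlist(bad$body$errors), collapse = " "), "lifestage")
  # rejected write left no document behind
  expect_length(app$store$uuids_of_type("biosample"), 1)
})

test_that("PATCH/PUT update through the handler; malformed JSON is a 400", {
  app <- make_app()
  exp <- app$store$create_item("experiment", list(assay_term_name = "ChIP-seq",
                                                  assay_term_id = "OBI:0000716"))
  res <- handle_request(app, "PATCH",
                        paste0("/experiments/", exp$properties$accession, "/"),
                        body = '{"assay_term_name": "RNA-seq", "assay_term_id": "OBI:0001271"}',
                        prin = principal_admin())
  expect_identical(res$status, 200L)
  expect_identical(res$body$`@graph`[[1]]$assay_term_name, "RNA-seq")
  res <- handle_request(app, "PATCH",
                        paste0("/experiments/", exp$properties$accession, "/"),
                        body = "{not json", prin = principal_admin())
  expect_identical(res$status, 400L)
})

test_that("edit attempts on visible objects are 403, invisible ones 404", {
  x <- acl_app()
  sub <- principal("u1", "submitter", lab_groups = x$labL)
  released_L <- x$docs[[paste(x$labL, "released")]]
  res <- handle_request(x$app, "PATCH",
                        paste0("/biosamples/", released_L$properties$accession, "/"),
                        body = list(description = "nope"), prin = sub)
  expect_identical(res$status, 403L)
  unreleased_M <- x$docs[[paste(x$labM, "in progress")]]
  res <- handle_request(x$app, "GET",
                        paste0("/biosamples/", unreleased_M$properties$accession, "/"),
                        prin = principal_anonymous())
  expect_identical(res$status, 404L)
})

test_that("URL stability: uuid path, accession path and bare alias agree", {
  app <- make_fixture_app(seed = 42, n_experiments = 3)
  adm <- principal_admin()
  for (u in app$store$uuids_of_type("experiment")) {
    acc <- app$store$get_item(u)$properties$accession
    b1 <- handle_request(app, "GET", paste0("/experiments/", u, "/"),
                         query = list(frame = "object"), prin = adm)$body
    b2 <- handle_request(app, "GET", paste0("/experiments/", acc, "/"),
                         query = list(frame = "object"), prin = adm)$body
    b3 <- handle_request(app, "GET", paste0("/", acc),
                         query = list(frame = "object"), prin = adm)$body
    expect_identical(metastore:::to_json_chr(b1), metastore:::to_json_chr(b2))
    expect_identical(metastore:::to_json_chr(b1), metastore:::to_json_chr(b3))
  }
})

test_that("collection listings are visibility-trimmed and type-pure", {
  app <- make_app()
  expect_identical(
    handle_request(app, "GET", "/experiments/", prin = principal_admin())$body$total,
    0L)                                                  # empty store
  app$store$create_item("experiment", list(status = "released"))
  app$store$create_item("experiment", list(status = "in progress"))
  app$store$create_item("biosample", list(status = "released"))
  base <- handle_request(app, "GET", "/experiments/")$body
  adm <- handle_request(app, "GET", "/experiments/", prin = principal_admin())$body
  expect_identical(base$total, 1L)
  expect_identical(adm$total, 2L)
  types <- unlist(lapply(adm$`@graph`, function(b) b$`@type`[[1]]))
  expect_true(all(types == "Experiment"))                # no biosamples leak in
  expect_identical(handle_request(app, "GET", "/nonsense-collection/")$status, 404L)
})

test_that("no write path bypasses validation (randomized invalid posts)", {
  app <- make_fixture_app(seed = 43, n_experiments = 2)
  set.seed(77)
  before <- app$store$dump_json()
  for (i in 1:25) {
    type <- sample(app$registry$types(), 1)
    bad <- sample(list(
      list(zz_bogus_property = "x"),
      list(status = "not-a-status"),
      list(accession = "WRONG-SHAPE")), 1)[[1]]
    res <- handle_request(app, "POST",
                          paste0("/", app$registry$collection(type), "/"),
                          body = bad, prin = principal_admin())
    expect_identical(res$status, 422L)
  }
  expect_identical(app$store$dump_json(), before)
})

test_that("frames are selectable and profiles are served", {
  app <- make_fixture_app(seed = 44, n_experiments = 2)
  adm <- principal_admin()
  exp <- app$store$uuids_of_type("experiment")[[1]]
  raw <- handle_request(app, "GET", paste0("/experiments/", exp, "/"),
                        query = list(frame = "raw"), prin = adm)$body
  page <- handle_request(app, "GET", paste0("/experiments/", exp, "/"),
                         prin = adm)$body                  # default frame=page
  expect_null(raw$`@id`)
  expect_false(is.null(page$`@id`))
  expect_true("audit" %in% names(page))
  expect_true(is.list(page$replicates[[1]]))               # embedded

  prof <- handle_request(app, "GET", "/profiles/")
  expect_identical(prof$status, 200L)
  expect_length(prof$body, length(app$registry$types()))
  one <- handle_request(app, "GET", "/profiles/experiment.json")
  expect_identical(one$body$title, "Experiment")
  expect_identical(handle_request(app, "GET", "/profiles/nope.json")$status, 404L)
})

test_that("content negotiation wraps non-JSON requests in an HTML envelope", {
  app <- make_app()
  app$store$create_item("award", list(name = "fmt-award", status = "released"))
  html <- handle_request(app, "GET", "/awards/fmt-award/", accept = "text/html")
  expect_true(is.character(html$body) && grepl("^<!DOCTYPE html>", html$body))
  json_q <- handle_request(app, "GET", "/awards/fmt-award/",
                           query = list(format = "json"), accept = "text/html")
  expect_true(is.list(json_q$body))                        # same URL, JSON body
  expect_identical(json_q$body$name, "fmt-award")
})

test_that("search endpoint applies filters and facets over the index", {
  app <- make_fixture_app(seed = 45, n_experiments = 6)
  app$indexer$run_index_pass()
  res <- handle_request(app, "GET", "/search/",
                        query = list(type = "experiment", format = "json"),
                        prin = principal_admin())
  expect_identical(res$status, 200L)
  expect_identical(res$body$total, length(app$store$uuids_of_type("experiment")))
  expect_true("assay_term_name" %in% names(res$body$facets))
})

test_that("principal_for_user derives tiers from stored users", {
  app <- make_fixture_app(seed = 46, n_experiments = 1)
  u <- app$store$uuids_of_type("user")[[1]]
  p <- principal_for_user(app, u)
  expect_identical(p$tier, "submitter")
  expect_length(p$lab_groups, 1)
  adm_doc <- app$store$create_item("user", list(email = "root@dcc.test",
                                                groups = list("admin")))
  expect_identical(principal_for_user(app, adm_doc$uuid)$tier, "admin")
})
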