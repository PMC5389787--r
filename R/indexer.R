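#' Incremental invalidation indexer and faceted search
#'
#' Maintains one page-frame index record per live document. Consistency with
#' the store follows the invalidation rubric: let U be the union of
#' `updated_uuids` and R the union of `renamed_uuids` over all transactions
#' since the indexer's last pass; the records to reindex are U together with
#' every record whose `embedded_uuids` intersect U or whose `linked_uuids`
#' intersect R. Reverse dependency maps make that computation O(|U| + |R|).
#'
#' The backend is an in-process structure behind a thin interface; a
#' server-grade search engine could be substituted without changing the
#' rubric. Indexing is pull-based: a pass drains `transactions_since` up to
#' the log head.
#'
#' @export
Indexer <- R6::R6Class("Indexer",
  public = list(
    #' @field renderer the [Renderer] producing page frames
    renderer = NULL,
    #' @field auditor optional [AuditEngine] (already wired into the page
    #'   frame via the renderer's audit hook)
    auditor = NULL,
    #' @field last_tid transaction id up to which the index is current
    last_tid = 0,

    #' @description Create an (empty) index over a renderer.
    initialize = function(renderer, auditor = NULL) {
      self$renderer <- renderer
      self$auditor <- auditor
      private$records <- new.env(parent = emptyenv())
      private$emb_rev <- new.env(parent = emptyenv())
      private$lnk_rev <- new.env(parent = emptyenv())
    },

    #' @description The invalidation report for transactions after
    #'   `last_tid`: list(updated, renamed, invalidated).
    invalidated_since = function(last_tid = self$last_tid) {
      txns <- self$renderer$store$transactions_since(last_tid)
      U <- unique(unlist(lapply(txns, `[[`, "updated_uuids"))) %||% character(0)
      R <- unique(unlist(lapply(txns, `[[`, "renamed_uuids"))) %||% character(0)
      inv <- U
      for (u in U) inv <- c(inv, mm_get(private$emb_rev, u))
      for (r in R) inv <- c(inv, mm_get(private$lnk_rev, r))
      list(updated = sort(U), renamed = sort(R), invalidated = sort(unique(inv)))
    },

    #' @description Render and replace every invalidated record (deleted or
    #'   vanished documents are dropped from the index), then advance
    #'   `last_tid` to the log head. Render failures are warned about and
    #'   skipped; the pass continues.
    #' @return count of records reindexed (0 when caught up).
    run_index_pass = function() {
      store <- self$renderer$store
      head <- store$head_tid()
      report <- self$invalidated_since(self$last_tid)
      n <- 0L
      for (uuid in report$invalidated) {
        doc <- store$get_or_null(uuid)
        if (is.null(doc) || identical(doc$properties$status %||% "", "deleted")) {
          if (private$drop_record(uuid)) n <- n + 1L
          next
        }
        rv <- tryCatch(self$renderer$render(uuid, "page"), error = function(e) {
          warning(sprintf("render failed for %s: %s", uuid, conditionMessage(e)),
                  call. = FALSE)
          NULL
        })
        if (is.null(rv)) next
        private$put_record(list(
          uuid = uuid, item_type = doc$item_type, body = rv$body,
          embedded_uuids = rv$embedded_uuids, linked_uuids = rv$linked_uuids,
          audit = rv$body$audit %||% empty_object(), indexed_tid = head))
        n <- n + 1L
      }
      self$last_tid <- head
      n
    },

    #' @description All index records, sorted by uuid.
    all_records = function() {
      lapply(sort(ls(private$records)), function(u) get(u, envir = private$records))
    },

    #' @description One record or NULL.
    get_record = function(uuid) private$records[[uuid]],

    #' @description Faceted search over the index.
    #' @param filters named list: dotted property path -> value (exact match
    #'   for scalars, membership for list fields).
    #' @param type item type filter (optional).
    #' @param principal viewing principal; visibility is computed live from
    #'   the store so permissions are never stale.
    #' @param limit row cap or "all".
    #' @return list(results, facets, total).
    search = function(filters = list(), type = NULL, principal = principal_admin(),
                      limit = "all") {
      store <- self$renderer$store
      recs <- self$all_records()
      if (!is.null(type)) {
        recs <- recs[vapply(recs, function(r) identical(r$item_type, type), logical(1))]
      }
      visible <- vapply(recs, function(r) {
        doc <- store$get_or_null(r$uuid)
        if (is.null(doc)) return(FALSE)
        authorize(principal, status = doc$properties$status %||% "in progress",
                  lab = doc$properties$lab,
                  project = store$project_of_document(r$uuid),
                  action = "view")$allowed
      }, logical(1))
      recs <- recs[visible]
      for (f in names(filters)) {
        want <- filters[[f]]
        recs <- recs[vapply(recs, function(r) {
          v <- get_path(r$body, f)
          if (is.null(v)) return(FALSE)
          if (is_json_array(v)) want %in% unlist(v) else identical(as.character(v),
                                                                   as.character(want))
        }, logical(1))]
      }
      facets <- private$aggregate_facets(recs, type)
      total <- length(recs)
      if (!identical(limit, "all")) recs <- utils::head(recs, as.integer(limit))
      list(results = lapply(recs, `[[`, "body"), facets = facets, total = total)
    }
  ),

  private = list(
    records = NULL, emb_rev = NULL, lnk_rev = NULL,

    put_record = function(rec) {
      private$drop_record(rec$uuid)
      assign(rec$uuid, rec, envir = private$records)
      for (u in rec$embedded_uuids) mm_add(private$emb_rev, u, rec$uuid)
      for (u in rec$linked_uuids) mm_add(private$lnk_rev, u, rec$uuid)
    },

    drop_record = function(uuid) {
      old <- private$records[[uuid]]
      if (is.null(old)) return(FALSE)
      for (u in old$embedded_uuids) mm_del(private$emb_rev, u, uuid)
      for (u in old$linked_uuids) mm_del(private$lnk_rev, u, uuid)
      rm(list = uuid, envir = private$records)
      TRUE
    },

    aggregate_facets = function(recs, type) {
      reg <- self$renderer$store$registry
      types <- if (!is.null(type)) type else
        unique(vapply(recs, `[[`, "", "item_type"))
      config <- list()
      for (t in types) {
        fc <- tryCatch(reg$facet_config(t), error = function(e) list())
        for (nm in names(fc)) if (is.null(config[[nm]])) config[[nm]] <- fc[[nm]]
      }
      out <- list()
      for (field in names(config)) {
        vals <- unlist(lapply(recs, function(r) {
          v <- get_path(r$body, field)
          if (is.null(v)) NULL else as.character(unlist(v))
        }))
        if (is.null(vals)) {
          known <- any(vapply(types, function(t) {
            field %in% names(reg$get(t)$properties %||% list())
          }, logical(1)))
          if (!known && length(recs)) {
            warning(sprintf("unknown facet field: %s", field), call. = FALSE)
            next
          }
          vals <- character(0)
        }
        counts <- table(vals)
        terms <- as.list(as.integer(counts))
        names(terms) <- names(counts)
        out[[field]] <- list(title = config[[field]], terms = terms)
      }
      out
    }
  )
)
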