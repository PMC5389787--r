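#' Audit severity flags
#' @export
AUDIT_SEVERITIES <- c("ERROR", "WARNING", "NOT_COMPLIANT", "INTERNAL_ACTION")

#' Cross-object audit engine
#'
#' Audits are small predicates evaluated against a document's *embedded*
#' rendering whenever it is (re)indexed; because a predicate may read only
#' the embedded body, everything it consults is already part of the
#' rendering's `embedded_uuids`, so stored audit results can never go stale
#' under the invalidation rubric. Findings carry one of four severity flags
#' (ERROR, WARNING, NOT_COMPLIANT, INTERNAL_ACTION), a machine-readable
#' category, a human-readable detail and the canonical path of the audited
#' object.
#'
#' @export
AuditEngine <- R6::R6Class("AuditEngine",
  public = list(
    #' @field renderer the [Renderer] supplying embedded bodies
    renderer = NULL,

    #' @description Create an engine over a renderer.
    initialize = function(renderer) {
      self$renderer <- renderer
      private$rules <- new.env(parent = emptyenv())
    },

    #' @description Register (or replace, keyed by type + category) a rule.
    #' @param item_type audited type (must be registered in the schema
    #'   registry).
    #' @param category short machine-readable string.
    #' @param severity one of `AUDIT_SEVERITIES`.
    #' @param predicate function(embedded_body) returning a character vector
    #'   of details (zero-length = no finding).
    #' @return the registration handle (its key), invisibly.
    register_rule = function(item_type, category, severity, predicate) {
      self$renderer$store$registry$get(item_type)
      stopifnot(severity %in% AUDIT_SEVERITIES, is.function(predicate))
      key <- paste0(item_type, "\r", category)
      assign(key, list(item_type = item_type, category = category,
                       severity = severity, predicate = predicate),
             envir = private$rules)
      invisible(key)
    },

    #' @description Rules registered for a type, ordered by category.
    rules_for = function(item_type) {
      keys <- sort(ls(private$rules))
      keys <- keys[startsWith(keys, paste0(item_type, "\r"))]
      lapply(keys, function(k) get(k, envir = private$rules))
    },

    #' @description Run every rule for a document, rendering it embedded.
    run_audits = function(identifier) {
      rv <- self$renderer$render(identifier, "embedded")
      self$run_audits_on(rv$uuid, rv$body)
    },

    #' @description Run rules against an already-rendered embedded body.
    #'   A predicate error is reported as an INTERNAL_ACTION finding naming
    #'   the rule, never a fatal error.
    run_audits_on = function(uuid, embedded_body) {
      doc <- self$renderer$store$get_item(uuid)
      path <- embedded_body[["@id"]] %||% self$renderer$store$canonical_path(uuid)
      out <- list()
      for (rule in self$rules_for(doc$item_type)) {
        details <- tryCatch(rule$predicate(embedded_body), error = function(e) {
          structure(sprintf("audit rule '%s' failed: %s",
                            rule$category, conditionMessage(e)),
                    failed = TRUE)
        })
        failed <- isTRUE(attr(details, "failed"))
        for (d in as.character(details %||% character(0))) {
          out[[length(out) + 1L]] <- list(
            severity = if (failed) "INTERNAL_ACTION" else rule$severity,
            category = rule$category, detail = d, path = path)
        }
      }
      ord <- order(vapply(out, `[[`, "", "category"), vapply(out, `[[`, "", "path"))
      out[ord]
    }
  ),
  private = list(rules = NULL)
)
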