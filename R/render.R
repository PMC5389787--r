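#' Frame-based document renderer
#'
#' Produces the four frames of a document:
#' * `raw` — the stored (upgraded) properties verbatim, links as uuids;
#' * `object` — raw plus `@id`/`@type`/`uuid` metadata, link values replaced
#'   by canonical paths, and calculated properties (reverse links included);
#' * `embedded` — object frame with each per-type embed path's link replaced
#'   by a copy of the target's object-frame rendering;
#' * `page` — embedded plus audit results under an `audit` key.
#'
#' While rendering, two dependency sets are recorded: `embedded_uuids`
#' (documents copied into the body or whose properties were consulted —
#' always including the document itself and any reverse-link children) and
#' `linked_uuids` (documents referenced only by canonical path). These sets
#' drive the indexer's invalidation rubric: property changes invalidate
#' through `embedded_uuids`; only renames invalidate through `linked_uuids`.
#'
#' @export
Renderer <- R6::R6Class("Renderer",
  public = list(
    #' @field store the backing [DocumentStore]
    store = NULL,

    #' @description Create a renderer over a store.
    #' @param store a [DocumentStore].
    initialize = function(store) {
      self$store <- store
      private$embeds <- new.env(parent = emptyenv())
      private$audit_hook <- function(uuid, body) list()
    },

    #' @description Declare the embed paths for a type (dot-separated link
    #'   or reverse-link paths, e.g. `"replicates.library.biosample"`).
    set_embed = function(item_type, paths) {
      reg <- self$store$registry
      for (p in paths) {       # verify each segment names a link/rev field
        type <- item_type
        for (seg in strsplit(p, ".", fixed = TRUE)[[1]]) {
          lf <- reg$link_fields(type); rf <- reg$rev_fields(type)
          if (!is.null(lf[[seg]])) type <- lf[[seg]]
          else if (!is.null(rf[[seg]])) type <- rf[[seg]][[1]]
          else abort_ms("schema_definition_error",
                        sprintf("embed path '%s': '%s' is not a link of '%s'", p, seg, type))
        }
      }
      assign(item_type, paths, envir = private$embeds)
      invisible(self)
    },

    #' @description Embed paths declared for a type.
    embed_paths = function(item_type) private$embeds[[item_type]] %||% character(0),

    #' @description Install the audit callback used by the page frame
    #'   (wired by the application to avoid a hard module cycle).
    set_audit_hook = function(fn) { private$audit_hook <- fn; invisible(self) },

    #' @description Render one document at a frame.
    #' @return a RenderedView: list(uuid, frame, body, embedded_uuids,
    #'   linked_uuids).
    render = function(identifier, frame = c("page", "embedded", "object", "raw")) {
      if (!is_scalar_chr(frame) || !frame %in% c("page", "embedded", "object", "raw")) {
        abort_ms("unknown_frame", paste0("unknown frame: ", frame))
      }
      hit <- self$store$resolve_identifier(identifier)
      uuid <- hit$uuid
      ctx <- private$new_ctx()
      body <- switch(frame,
        raw = {
          set_add(ctx$embedded, uuid)
          self$store$get_item(uuid)$properties
        },
        object = private$object_body(uuid, ctx),
        embedded = private$embedded_body(uuid, ctx),
        page = {
          b <- private$embedded_body(uuid, ctx)
          b$audit <- private$grouped_audits(uuid, b)
          b
        })
      emb <- set_members(ctx$embedded)
      lnk <- setdiff(set_members(ctx$linked), emb)
      list(uuid = uuid, frame = frame, body = body,
           embedded_uuids = emb, linked_uuids = lnk)
    },

    #' @description uuids of non-deleted documents of `child_type` whose
    #'   `child_link_field` targets `parent_uuid`, ordered by accession then
    #'   uuid. The declaration must exist in some type's `rev` block.
    rev_links = function(parent_uuid, child_type, child_link_field) {
      reg <- self$store$registry
      declared <- FALSE
      for (t in reg$types()) {
        for (rf in reg$rev_fields(t)) {
          if (identical(rf[[1]], child_type) && identical(rf[[2]], child_link_field)) {
            declared <- TRUE
          }
        }
      }
      if (!declared) {
        abort_ms("unknown_rev_declaration",
                 sprintf("no rev declaration for %s.%s", child_type, child_link_field))
      }
      cands <- self$store$referrers(parent_uuid)
      hits <- character(0); sort_keys <- character(0)
      pk <- reg$path_key_field(child_type)
      for (u in cands) {
        doc <- self$store$get_or_null(u)
        if (is.null(doc) || !identical(doc$item_type, child_type)) next
        if (identical(doc$properties$status %||% "in progress", "deleted")) next
        v <- doc$properties[[child_link_field]]
        if (parent_uuid %in% unlist(v)) {
          hits <- c(hits, u)
          acc <- if (!is.null(pk)) doc$properties[[pk]] %||% "" else ""
          sort_keys <- c(sort_keys, paste0(acc, "\r", u))
        }
      }
      hits[order(sort_keys)]
    },

    #' @description Add calculated properties (reverse links and registered
    #'   hooks) to an object-frame body. Calculated values never persist.
    compute_calculated = function(item_type, object_body, ctx = NULL) {
      reg <- self$store$registry
      uuid <- object_body$uuid
      for (nm in names(reg$rev_fields(item_type))) {
        rf <- reg$rev_fields(item_type)[[nm]]
        kids <- self$rev_links(uuid, rf[[1]], rf[[2]])
        if (!is.null(ctx)) set_add(ctx$embedded, kids)  # children consulted
        object_body[[nm]] <- lapply(kids, self$store$canonical_path)
      }
      hooks <- reg$hooks_for(item_type)
      for (nm in names(hooks)) {
        val <- tryCatch(hooks[[nm]](object_body),
                        error = function(e) {
                          abort_ms("hook_failure",
                                   sprintf("calculated property '%s' failed: %s",
                                           nm, conditionMessage(e)))
                        })
        if (!is.null(val)) object_body[[nm]] <- val
      }
      object_body
    }
  ),

  private = list(
    embeds = NULL, audit_hook = NULL,

    new_ctx = function() {
      ctx <- new.env(parent = emptyenv())
      ctx$embedded <- set_new()
      ctx$linked <- set_new()
      ctx
    },

    # object frame of one document, recording into ctx
    object_body = function(uuid, ctx) {
      set_add(ctx$embedded, uuid)
      doc <- self$store$get_item(uuid)
      type <- doc$item_type
      reg <- self$store$registry
      body <- doc$properties
      lf <- reg$link_fields(type)
      for (nm in intersect(names(lf), names(body))) {
        pathify <- function(u) {
          if (!set_has(ctx$embedded, u)) set_add(ctx$linked, u)
          self$store$canonical_path(u)
        }
        v <- body[[nm]]
        body[[nm]] <- if (is_json_array(v)) lapply(v, pathify) else pathify(v)
      }
      body[["@id"]] <- self$store$canonical_path(uuid)
      body[["@type"]] <- list(reg$get(type)$title %||% type, "Item")
      body$uuid <- uuid
      self$compute_calculated(type, body, ctx)
    },

    embedded_body = function(uuid, ctx) {
      doc <- self$store$get_item(uuid)
      body <- private$object_body(uuid, ctx)
      tree <- private$embed_tree(self$embed_paths(doc$item_type))
      private$embed_apply(body, doc$item_type, tree, ctx, stack = uuid)
    },

    embed_tree = function(paths) {
      tree <- list()
      for (p in paths) {
        segs <- strsplit(p, ".", fixed = TRUE)[[1]]
        node <- tree
        # insert path into nested named list
        insert <- function(node, segs) {
          if (length(segs) == 0) return(node)
          head <- segs[[1]]
          node[[head]] <- insert(node[[head]] %||% list(), segs[-1])
          node
        }
        tree <- insert(tree, segs)
      }
      tree
    },

    embed_apply = function(body, item_type, tree, ctx, stack) {
      if (length(tree) == 0) return(body)
      reg <- self$store$registry
      lf <- reg$link_fields(item_type)
      rf <- reg$rev_fields(item_type)
      for (nm in names(tree)) {
        v <- body[[nm]]
        if (is.null(v)) next
        child_type <- if (!is.null(lf[[nm]])) lf[[nm]] else rf[[nm]][[1]]
        embed1 <- function(path) {
          hit <- tryCatch(self$store$resolve_identifier(path),
                          metastore_error = function(e) NULL)
          if (is.null(hit)) return(path)
          cu <- hit$uuid
          if (cu %in% stack) return(path)  # cycle: leave as canonical path
          child <- private$object_body(cu, ctx)
          set_del(ctx$linked, cu)
          private$embed_apply(child, child_type, tree[[nm]], ctx, c(stack, cu))
        }
        body[[nm]] <- if (is_json_array(v)) lapply(v, embed1) else embed1(v)
      }
      body
    },

    grouped_audits = function(uuid, embedded_body) {
      findings <- private$audit_hook(uuid, embedded_body)
      out <- empty_object()
      for (f in findings) out[[f$severity]] <- c(out[[f$severity]] %||% list(), list(f))
      out
    }
  )
)
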