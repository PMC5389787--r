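#' Schema registry: per-type JSON schemas with link extensions
#'
#' Each item type is described by one JSON-Schema file extended with the
#' custom keywords `linkTo` (typed link to another item type), `uniqueKey`
#' (global unique-key registration, e.g. accessions), `rev` (reverse-link
#' declarations `name -> [child_type, child_link_field]`),
#' `calculatedProperties` (names of hook-computed display fields), `facets`
#' (search aggregation config) and a top-level `schema_version`.
#' `additionalProperties` is always treated as false: schemas control the
#' allowed fields of every document.
#'
#' Validation covers the subset of JSON-Schema the shipped schemas use:
#' `type`, `enum`, `pattern`, `required`, `properties`, `items`, and
#' `format: "date"`. Custom keywords are stripped before structural checks
#' and enforced by registry/store code instead.
#'
#' @param schema_dir directory holding one `<type>.json` file per item type.
#' @export
SchemaRegistry <- R6::R6Class("SchemaRegistry",
  public = list(
    #' @field schemas environment mapping item type -> parsed schema
    schemas = NULL,

    #' @description Load every `*.json` schema in `schema_dir` (optional).
    initialize = function(schema_dir = NULL) {
      self$schemas <- new.env(parent = emptyenv())
      private$upgrades <- new.env(parent = emptyenv())
      private$hooks <- new.env(parent = emptyenv())
      if (!is.null(schema_dir)) {
        files <- sort(list.files(schema_dir, pattern = "\\.json$", full.names = TRUE))
        for (f in files) {
          schema <- from_json(paste(readLines(f, warn = FALSE), collapse = "\n"))
          type <- sub("\\.json$", "", basename(f))
          self$register_schema(type, schema)
        }
        private$check_cross_refs()
      }
    },

    #' @description Register one schema under an item type name.
    register_schema = function(item_type, schema) {
      stopifnot(is_json_object(schema))
      schema$schema_version <- as.integer(schema$schema_version %||% 1L)
      # pairwise disjointness of stored, rev and calculated names
      revs <- names(schema$rev %||% list())
      calc <- unlist(schema$calculatedProperties %||% list())
      stored <- names(schema$properties %||% list())
      clash <- c(intersect(revs, stored), intersect(calc, stored), intersect(revs, calc))
      if (length(clash)) {
        abort_ms("schema_definition_error",
                 paste0("rev/calculated/stored name collision in '", item_type,
                        "': ", paste(unique(clash), collapse = ", ")))
      }
      assign(item_type, schema, envir = self$schemas)
      invisible(self)
    },

    #' @description All registered item type names, sorted.
    types = function() sort(ls(self$schemas)),

    #' @description The parsed schema for one type (errors on unknown type).
    get = function(item_type) {
      if (!is_scalar_chr(item_type) || !exists(item_type, envir = self$schemas, inherits = FALSE)) {
        abort_unknown_type(item_type)
      }
      get(item_type, envir = self$schemas)
    },

    #' @description Collection (plural URL segment) for a type.
    collection = function(item_type) {
      sch <- self$get(item_type)
      sch$collection %||% paste0(item_type, "s")
    },

    #' @description Item type for a collection segment, or NULL.
    type_from_collection = function(collection) {
      for (t in self$types()) if (identical(self$collection(t), collection)) return(t)
      NULL
    },

    #' @description Current schema version of a type.
    current_version = function(item_type) self$get(item_type)$schema_version,

    #' @description Link fields: property name -> target item type.
    link_fields = function(item_type) {
      sch <- self$get(item_type)
      out <- list()
      for (nm in names(sch$properties)) {
        p <- sch$properties[[nm]]
        if (!is.null(p$linkTo)) out[[nm]] <- p$linkTo
        else if (!is.null(p$items$linkTo)) out[[nm]] <- p$items$linkTo
      }
      out
    },

    #' @description Reverse-link declarations: name -> c(child_type, child_field).
    rev_fields = function(item_type) {
      sch <- self$get(item_type)
      lapply(sch$rev %||% empty_object(), function(x) unlist(x))
    },

    #' @description Hook-calculated field names declared for a type.
    calculated_names = function(item_type) {
      as.character(unlist(self$get(item_type)$calculatedProperties %||% list()))
    },

    #' @description Unique-key property names -> key names (e.g. accession).
    unique_key_fields = function(item_type) {
      sch <- self$get(item_type)
      out <- list()
      for (nm in names(sch$properties)) {
        k <- sch$properties[[nm]]$uniqueKey %||% sch$properties[[nm]]$items$uniqueKey
        if (!is.null(k)) out[[nm]] <- k
      }
      out
    },

    #' @description All unique key names registered across schemas.
    key_names = function() {
      out <- character(0)
      for (t in self$types()) out <- c(out, unlist(self$unique_key_fields(t)))
      unique(out)
    },

    #' @description The property from which the canonical path is minted:
    #' the accession if the type has one, else the type's name key, else NULL
    #' (uuid paths).
    path_key_field = function(item_type) {
      uk <- self$unique_key_fields(item_type)
      acc <- names(uk)[vapply(uk, identical, logical(1), "accession")]
      if (length(acc)) return(acc[[1]])
      named <- names(uk)[vapply(uk, function(k) grepl(":", k, fixed = TRUE), logical(1))]
      if (length(named)) return(named[[1]])
      NULL
    },

    #' @description Facet configuration: ordered mapping path -> title.
    facet_config = function(item_type) {
      fc <- self$get(item_type)$facets %||% empty_object()
      lapply(fc, function(x) x$title %||% x)
    },

    #' @description Register an upgrade step `from_version -> from_version+1`.
    #' @param transform pure function properties -> properties.
    add_upgrade = function(item_type, from_version, transform) {
      self$get(item_type)
      key <- paste0(item_type, "\r", from_version)
      assign(key, transform, envir = private$upgrades)
      invisible(self)
    },

    #' @description Register a calculated-property hook.
    #' @param fn function(object_body, document) -> JSON value or NULL.
    add_calculated = function(item_type, name, fn) {
      self$get(item_type)
      assign(paste0(item_type, "\r", name), fn, envir = private$hooks)
      invisible(self)
    },

    #' @description Calculated hooks for a type as name -> function.
    hooks_for = function(item_type) {
      out <- list()
      for (nm in self$calculated_names(item_type)) {
        key <- paste0(item_type, "\r", nm)
        if (exists(key, envir = private$hooks, inherits = FALSE)) {
          out[[nm]] <- get(key, envir = private$hooks)
        }
      }
      out
    },

    #' @description Validate properties against a type's schema.
    #' @return character vector of violation descriptions; empty iff valid.
    validate = function(item_type, properties) {
      sch <- self$get(item_type)
      props <- normalize_props(properties)
      spec <- sch$properties %||% empty_object()
      out <- character(0)
      extra <- setdiff(names(props), names(spec))
      for (nm in extra) {
        out <- c(out, sprintf("additional property '%s' is not allowed", nm))
      }
      for (nm in unlist(sch$required %||% list())) {
        if (is.null(props[[nm]])) out <- c(out, sprintf("required property '%s' is missing", nm))
      }
      for (nm in intersect(names(props), names(spec))) {
        out <- c(out, private$check_value(spec[[nm]], props[[nm]], nm))
      }
      out
    },

    #' @description Upgrade a document to the current schema version by
    #' applying the registered chain of steps. Pure: the store copy is not
    #' touched; persistence happens on the next write.
    upgrade = function(document) {
      type <- document$item_type
      cur <- self$current_version(type)
      v <- as.integer(document$schema_version %||% 1L)
      if (is.na(v) || v < 1L) v <- 1L
      props <- document$properties
      changed <- v < cur
      while (v < cur) {
        key <- paste0(type, "\r", v)
        if (!exists(key, envir = private$upgrades, inherits = FALSE)) {
          abort_ms("missing_upgrade_step",
                   sprintf("no upgrade step %d->%d for type '%s'", v, v + 1L, type))
        }
        props <- normalize_props(get(key, envir = private$upgrades)(props))
        v <- v + 1L
      }
      # documents already at head were validated when written; re-validate
      # only when an upgrade step actually ran
      viol <- if (changed) self$validate(type, props) else character(0)
      if (length(viol)) {
        abort_ms("post_upgrade_validation_failure",
                 paste0("upgraded document is invalid: ", paste(viol, collapse = "; ")),
                 violations = viol)
      }
      document$properties <- props
      document$schema_version <- cur
      document
    },

    #' @description Serve schema content (/profiles/): all schemas, or one.
    profiles = function(item_type = NULL) {
      if (is.null(item_type)) {
        out <- list()
        for (t in self$types()) out[[t]] <- self$get(t)
        return(out)
      }
      self$get(item_type)
    }
  ),

  private = list(
    upgrades = NULL,
    hooks = NULL,

    check_cross_refs = function() {
      for (t in self$types()) {
        for (target in unlist(self$link_fields(t))) {
          if (!exists(target, envir = self$schemas, inherits = FALSE)) {
            abort_ms("schema_definition_error",
                     sprintf("linkTo target '%s' of type '%s' is not registered", target, t))
          }
        }
        revs <- self$rev_fields(t)
        for (nm in names(revs)) {
          child <- revs[[nm]][[1]]; field <- revs[[nm]][[2]]
          lf <- tryCatch(self$link_fields(child), error = function(e) NULL)
          if (is.null(lf) || is.null(lf[[field]])) {
            abort_ms("schema_definition_error",
                     sprintf("rev '%s' of '%s' names missing link %s.%s", nm, t, child, field))
          }
        }
      }
    },

    check_value = function(spec, value, name) {
      out <- character(0)
      type <- spec$type %||% if (!is.null(spec$linkTo)) "string" else NULL
      ok_type <- switch(type %||% "any",
        string  = is_scalar_chr(value),
        number  = is.numeric(value) && length(value) == 1L,
        integer = is.numeric(value) && length(value) == 1L &&
                  !is.na(value) && value == as.integer(value),
        boolean = is.logical(value) && length(value) == 1L && !is.na(value),
        array   = is_json_array(value),
        object  = is_json_object(value),
        any     = TRUE)
      if (!ok_type) {
        return(sprintf("property '%s' is not of type %s", name, type))
      }
      if (!is.null(spec$enum)) {
        allowed <- unlist(spec$enum)
        if (!(value %in% allowed)) {
          out <- c(out, sprintf("property '%s' value '%s' is not one of [%s]",
                                name, value, paste(allowed, collapse = ", ")))
        }
      }
      if (!is.null(spec$pattern) && is_scalar_chr(value) &&
          !grepl(spec$pattern, value, perl = TRUE)) {
        out <- c(out, sprintf("property '%s' does not match pattern %s", name, spec$pattern))
      }
      if (identical(spec$format, "date") && is_scalar_chr(value) &&
          !grepl("^\\d{4}-\\d{2}-\\d{2}$", value)) {
        out <- c(out, sprintf("property '%s' is not a date (YYYY-MM-DD)", name))
      }
      if (identical(type, "array") && !is.null(spec$items)) {
        for (i in seq_along(value)) {
          out <- c(out, private$check_value(spec$items, value[[i]],
                                            sprintf("%s[%d]", name, i)))
        }
      }
      out
    }
  )
)
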