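#' Transactional document store
#'
#' Stores typed JSON documents one row per document in an embedded relational
#' database (SQLite), alongside a unique-key table and a write-ahead
#' transaction log. Every successful write appends one transaction record
#' carrying `updated_uuids` (the written document plus, when a link-valued
#' property was added, removed or retargeted, the old and new link targets)
#' and `renamed_uuids` (documents whose path-determining key changed). The
#' log is the contract consumed by [Indexer].
#'
#' Writes are atomic: all validation, link resolution, permission and key
#' checks happen before any mutation, and the mutation itself runs in one
#' database transaction. An in-memory read-through cache fronts the database;
#' the database remains the dump/replay source of truth.
#'
#' @export
DocumentStore <- R6::R6Class("DocumentStore",
  public = list(
    #' @field registry the [SchemaRegistry] documents are validated against
    registry = NULL,

    #' @description Open a store.
    #' @param registry a [SchemaRegistry].
    #' @param db SQLite path or ":memory:".
    initialize = function(registry, db = ":memory:") {
      self$registry <- registry
      private$con <- DBI::dbConnect(RSQLite::SQLite(), db)
      DBI::dbExecute(private$con, "
        CREATE TABLE IF NOT EXISTS docs (
          uuid TEXT PRIMARY KEY, item_type TEXT NOT NULL,
          schema_version INTEGER NOT NULL, properties TEXT NOT NULL)")
      DBI::dbExecute(private$con, "
        CREATE TABLE IF NOT EXISTS keys (
          key_name TEXT NOT NULL, key_value TEXT NOT NULL, uuid TEXT NOT NULL,
          UNIQUE(key_name, key_value))")
      DBI::dbExecute(private$con, "
        CREATE TABLE IF NOT EXISTS txn_log (
          tid INTEGER PRIMARY KEY AUTOINCREMENT,
          updated TEXT NOT NULL, renamed TEXT NOT NULL,
          ops TEXT NOT NULL, timestamp REAL NOT NULL)")
      private$cache <- new.env(parent = emptyenv())
      private$key_env <- new.env(parent = emptyenv())
      private$type_env <- new.env(parent = emptyenv())
      private$backlinks <- new.env(parent = emptyenv())
      private$acc_counters <- new.env(parent = emptyenv())
      private$log_mirror <- list()
      private$warm_from_db()
    },

    #' @description Create a new document (the POST-to-collection semantics).
    #' @param item_type registered type name.
    #' @param properties named property mapping; links may be given as uuids,
    #'   accessions, unique keys or canonical paths.
    #' @param principal acting user (NULL = trusted internal caller).
    #' @param uuid optional caller-supplied identifier.
    #' @return the stored document (list with uuid, item_type, schema_version,
    #'   properties, status).
    create_item = function(item_type, properties, principal = NULL, uuid = NULL) {
      sch <- self$registry$get(item_type)
      props <- normalize_props(properties)
      props <- private$apply_defaults(item_type, props)
      props <- private$maybe_mint_accession(item_type, props)
      props <- private$resolve_link_values(item_type, props)
      viol <- self$registry$validate(item_type, props)
      if (length(viol)) abort_validation(viol)
      private$check_permission(principal, "create", props$status %||% "in progress",
                               props$lab, private$project_of(item_type, props))
      if (is.null(uuid)) {
        repeat {   # RNG streams can collide with bulk-loaded uuids
          uuid <- mint_uuid()
          if (is.null(private$cache[[uuid]])) break
        }
      } else if (!is.null(private$cache[[uuid]])) abort_duplicate_key("uuid", uuid)
      keys <- private$keys_of(item_type, props)
      for (i in seq_len(nrow(keys))) {
        if (!is.null(private$key_lookup(keys$key_name[i], keys$key_value[i]))) {
          abort_duplicate_key(keys$key_name[i], keys$key_value[i])
        }
      }
      targets <- private$link_targets(item_type, props)
      op <- list(op = "create", uuid = uuid, item_type = item_type,
                 schema_version = self$registry$current_version(item_type),
                 properties = props)
      private$commit(updated = unique(c(uuid, targets)), renamed = character(0),
                     ops = list(op))
      self$get_item(uuid)
    },

    #' @description Update an existing document (PATCH merges top-level keys,
    #'   a JSON null deletes a key; PUT/replace substitutes the whole body).
    #'   The stored copy is first upgraded to the current schema version, so
    #'   writes persist upgrades permanently.
    update_item = function(identifier, delta, mode = c("patch", "replace"),
                           principal = NULL) {
      mode <- match.arg(mode)
      hit <- self$resolve_identifier(identifier)
      old <- self$registry$upgrade(private$cache[[hit$uuid]])
      type <- old$item_type
      delta <- if (mode == "patch") {
        if (is.null(delta) || length(delta) == 0) empty_object()
        else {
          if (!is.list(delta) || is.null(names(delta))) {
            abort_ms("malformed_body", "patch body must be a named mapping")
          }
          delta
        }
      } else normalize_props(delta)
      new_props <- if (mode == "patch") {
        merged <- old$properties
        for (nm in names(delta)) merged[nm] <- delta[nm]  # NULL removes
        merged[!vapply(merged, is.null, logical(1))]
      } else delta
      new_props <- normalize_props(new_props)
      new_props <- private$apply_defaults(type, new_props)
      new_props <- private$resolve_link_values(type, new_props)
      viol <- self$registry$validate(type, new_props)
      if (length(viol)) abort_validation(viol)
      private$check_permission(principal, "edit", old$properties$status %||% "in progress",
                               old$properties$lab, private$project_of(type, old$properties))

      old_keys <- private$keys_of(type, old$properties)
      new_keys <- private$keys_of(type, new_props)
      for (i in seq_len(nrow(new_keys))) {
        owner <- private$key_lookup(new_keys$key_name[i], new_keys$key_value[i])
        if (!is.null(owner) && !identical(owner, hit$uuid)) {
          abort_duplicate_key(new_keys$key_name[i], new_keys$key_value[i])
        }
      }
      renamed <- character(0)
      pk <- self$registry$path_key_field(type)
      if (!is.null(pk) &&
          !identical(old$properties[[pk]] %||% "", new_props[[pk]] %||% "")) {
        renamed <- hit$uuid
      }
      # link-delta augmentation: old+new targets of changed link fields
      deltas <- character(0)
      lf <- self$registry$link_fields(type)
      for (nm in names(lf)) {
        ov <- old$properties[[nm]]; nv <- new_props[[nm]]
        if (!identical(ov, nv)) deltas <- c(deltas, unlist(ov), unlist(nv))
      }
      op <- list(op = "update", uuid = hit$uuid, item_type = type,
                 schema_version = self$registry$current_version(type),
                 properties = new_props)
      private$commit(updated = unique(c(hit$uuid, deltas)), renamed = renamed,
                     ops = list(op))
      self$get_item(hit$uuid)
    },

    #' @description Fetch a document by uuid or unique key, upgraded to the
    #'   current schema version. Reads never modify the store; the store is
    #'   status-agnostic (deleted documents are returned with their status).
    get_item = function(identifier) {
      hit <- self$resolve_identifier(identifier)
      self$registry$upgrade(private$cache[[hit$uuid]])
    },

    #' @description Like `get_item` but returns NULL instead of erroring.
    get_or_null = function(identifier) {
      tryCatch(self$get_item(identifier), metastore_error = function(e) NULL)
    },

    #' @description Resolve a uuid literal, unique key value, or canonical
    #'   path to `(item_type, uuid)`.
    resolve_identifier = function(token) {
      if (!is_scalar_chr(token)) abort_unresolvable(paste(token, collapse = "/"))
      m <- regmatches(token, regexec("^/([^/]+)/([^/]+)/?$", token))[[1]]
      if (length(m) == 3) {
        hit <- self$resolve_identifier(m[[3]])
        type <- self$registry$type_from_collection(m[[2]])
        if (is.null(type) || !identical(type, hit$item_type)) abort_unresolvable(token)
        return(hit)
      }
      if (grepl(UUID_RE, token)) {
        doc <- private$cache[[token]]
        if (!is.null(doc)) return(list(item_type = doc$item_type, uuid = token))
        abort_unresolvable(token)
      }
      for (kn in c("accession", "alias",
                   setdiff(self$registry$key_names(), c("accession", "alias")))) {
        u <- private$key_lookup(kn, token)
        if (!is.null(u)) return(list(item_type = private$cache[[u]]$item_type, uuid = u))
      }
      abort_unresolvable(token)
    },

    #' @description All transaction records with tid greater than `tid`, in
    #'   log order. Each record: list(tid, updated_uuids, renamed_uuids,
    #'   timestamp).
    transactions_since = function(tid = 0) {
      recs <- private$log_mirror
      recs[vapply(recs, function(r) r$tid > tid, logical(1))]
    },

    #' @description The tid at the head of the log (0 when empty).
    head_tid = function() {
      n <- length(private$log_mirror)
      if (n == 0) 0 else private$log_mirror[[n]]$tid
    },

    #' @description uuids of all stored documents of one type (sorted).
    uuids_of_type = function(item_type) sort(private$type_env[[item_type]] %||% character(0)),

    #' @description uuids of every stored document (sorted).
    all_uuids = function() set_members(private$cache_index()),

    #' @description uuids of documents whose stored properties reference the
    #'   given uuid through any link field (the backlink index behind reverse
    #'   links).
    referrers = function(uuid) mm_get(private$backlinks, uuid),

    #' @description Canonical resource path `/collection/key-or-uuid/`.
    canonical_path = function(uuid) {
      doc <- private$cache[[uuid]]
      if (is.null(doc)) abort_not_found(uuid)
      pk <- self$registry$path_key_field(doc$item_type)
      id <- if (!is.null(pk)) doc$properties[[pk]] %||% uuid else uuid
      paste0("/", self$registry$collection(doc$item_type), "/", id, "/")
    },

    #' @description Resolve the project tag governing cross-project
    #'   visibility for a document (its award's project, default "ENCODE").
    project_of_document = function(uuid) {
      doc <- private$cache[[uuid]]
      if (is.null(doc)) return("ENCODE")
      private$project_of(doc$item_type, doc$properties)
    },

    #' @description Byte-stable JSON dump of documents + key table, for
    #'   atomicity comparisons and `store dump`.
    dump_json = function() {
      docs <- list()
      for (u in self$all_uuids()) {
        d <- private$cache[[u]]
        docs[[u]] <- list(uuid = u, item_type = d$item_type,
                          schema_version = d$schema_version,
                          properties = d$properties)
      }
      keys <- sort(ls(private$key_env))
      ktab <- lapply(keys, function(k) {
        parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
        list(key_name = parts[[1]], key_value = parts[[2]],
             uuid = get(k, envir = private$key_env))
      })
      to_json_chr(list(documents = docs, keys = ktab))
    },

    #' @description Replay the ops recorded in transaction records (as read
    #'   from another store's log) into this store, reproducing its state.
    replay = function(records) {
      for (r in records) {
        for (op in r$ops %||% list()) private$apply_op(op)
      }
      invisible(self)
    },

    #' @description Raw transaction records including replayable ops.
    log_records = function() private$log_mirror,

    #' @description Close the database connection.
    close = function() {
      if (!is.null(private$con) && DBI::dbIsValid(private$con)) {
        DBI::dbDisconnect(private$con)
      }
      invisible(NULL)
    },

    #' @description Finalizer: release the connection at garbage collection.
    finalize = function() self$close()
  ),

  private = list(
    con = NULL, cache = NULL, key_env = NULL, type_env = NULL,
    backlinks = NULL, acc_counters = NULL, log_mirror = NULL,

    cache_index = function() {
      s <- set_new()
      set_add(s, ls(private$cache))
      s
    },

    warm_from_db = function() {
      rows <- DBI::dbGetQuery(private$con, "SELECT * FROM docs")
      for (i in seq_len(nrow(rows))) {
        doc <- list(uuid = rows$uuid[i], item_type = rows$item_type[i],
                    schema_version = rows$schema_version[i],
                    properties = from_json(rows$properties[i]))
        private$cache_put(doc)
      }
      krows <- DBI::dbGetQuery(private$con, "SELECT * FROM keys")
      for (i in seq_len(nrow(krows))) {
        assign(paste0(krows$key_name[i], "\r", krows$key_value[i]),
               krows$uuid[i], envir = private$key_env)
      }
      lrows <- DBI::dbGetQuery(private$con, "SELECT * FROM txn_log ORDER BY tid")
      private$log_mirror <- lapply(seq_len(nrow(lrows)), function(i) {
        list(tid = lrows$tid[i],
             updated_uuids = as.character(unlist(from_json(lrows$updated[i]))),
             renamed_uuids = as.character(unlist(from_json(lrows$renamed[i]))),
             ops = from_json(lrows$ops[i]), timestamp = lrows$timestamp[i])
      })
    },

    cache_put = function(doc) {
      old <- private$cache[[doc$uuid]]
      if (!is.null(old)) {
        for (t in private$link_targets(old$item_type, old$properties)) {
          mm_del(private$backlinks, t, doc$uuid)
        }
      } else {
        private$type_env[[doc$item_type]] <-
          c(private$type_env[[doc$item_type]], doc$uuid)
      }
      doc$status <- doc$properties$status %||% "in progress"
      assign(doc$uuid, doc, envir = private$cache)
      for (t in private$link_targets(doc$item_type, doc$properties)) {
        mm_add(private$backlinks, t, doc$uuid)
      }
    },

    key_lookup = function(key_name, key_value) {
      k <- paste0(key_name, "\r", key_value)
      if (exists(k, envir = private$key_env, inherits = FALSE)) {
        get(k, envir = private$key_env)
      } else NULL
    },

    keys_of = function(item_type, props) {
      uk <- self$registry$unique_key_fields(item_type)
      kn <- character(0); kv <- character(0)
      for (nm in names(uk)) {
        v <- props[[nm]]
        if (is.null(v)) next
        for (x in unlist(v)) { kn <- c(kn, uk[[nm]]); kv <- c(kv, x) }
      }
      data.frame(key_name = kn, key_value = kv, stringsAsFactors = FALSE)
    },

    apply_defaults = function(item_type, props) {
      sch <- self$registry$get(item_type)
      for (nm in names(sch$properties)) {
        d <- sch$properties[[nm]]$default
        if (!is.null(d) && is.null(props[[nm]])) props[[nm]] <- d
      }
      props
    },

    maybe_mint_accession = function(item_type, props) {
      sch <- self$registry$get(item_type)
      for (nm in names(sch$properties)) {
        code <- sch$properties[[nm]]$accessionType
        if (!is.null(code) && is.null(props[[nm]])) {
          repeat {
            n <- private$acc_counters[[item_type]] %||% 0L
            private$acc_counters[[item_type]] <- n + 1L
            acc <- mint_accession(code, n)
            if (is.null(private$key_lookup("accession", acc))) break
          }
          props[[nm]] <- acc
        }
      }
      props
    },

    resolve_link_values = function(item_type, props) {
      lf <- self$registry$link_fields(item_type)
      for (nm in intersect(names(lf), names(props))) {
        resolve1 <- function(tok) {
          hit <- tryCatch(self$resolve_identifier(tok),
                          metastore_error = function(e) NULL)
          if (is.null(hit) || !identical(hit$item_type, lf[[nm]])) {
            abort_dangling_link(nm, tok)
          }
          hit$uuid
        }
        v <- props[[nm]]
        props[[nm]] <- if (is_json_array(v)) lapply(v, resolve1) else resolve1(v)
      }
      props
    },

    link_targets = function(item_type, props) {
      lf <- tryCatch(self$registry$link_fields(item_type), error = function(e) list())
      out <- character(0)
      for (nm in intersect(names(lf), names(props))) {
        out <- c(out, unlist(props[[nm]]))
      }
      unique(out)
    },

    project_of = function(item_type, props) {
      if (identical(item_type, "award")) return(props$project %||% "ENCODE")
      aw <- props$award
      if (is_scalar_chr(aw)) {
        doc <- private$cache[[aw]]
        if (is.null(doc)) {
          hit <- tryCatch(self$resolve_identifier(aw), metastore_error = function(e) NULL)
          if (!is.null(hit)) doc <- private$cache[[hit$uuid]]
        }
        if (!is.null(doc)) return(doc$properties$project %||% "ENCODE")
      }
      "ENCODE"
    },

    check_permission = function(principal, action, status, lab, project) {
      if (is.null(principal)) return(invisible(TRUE))
      dec <- authorize(principal, status = status, lab = lab, project = project,
                      action = action)
      if (!dec$allowed) abort_permission(dec$reason)
      invisible(TRUE)
    },

    # The only mutation point: one SQLite transaction for doc rows, key rows
    # and the log append, then the mirrors.
    commit = function(updated, renamed, ops) {
      con <- private$con
      DBI::dbWithTransaction(con, {
        for (op in ops) private$write_op_rows(op)
        DBI::dbExecute(con,
          "INSERT INTO txn_log (updated, renamed, ops, timestamp) VALUES (?, ?, ?, ?)",
          params = list(to_json_chr(as.list(updated)),
                        to_json_chr(as.list(renamed)),
                        to_json_chr(ops),
                        as.numeric(Sys.time())))
      })
      tid <- DBI::dbGetQuery(con, "SELECT MAX(tid) AS t FROM txn_log")$t
      private$log_mirror[[length(private$log_mirror) + 1L]] <-
        list(tid = tid, updated_uuids = updated, renamed_uuids = renamed,
             ops = ops, timestamp = as.numeric(Sys.time()))
      for (op in ops) private$mirror_op(op)
      invisible(tid)
    },

    write_op_rows = function(op) {
      con <- private$con
      if (identical(op$op, "update")) {
        old <- private$cache[[op$uuid]]
        okeys <- private$keys_of(old$item_type, old$properties)
        for (i in seq_len(nrow(okeys))) {
          DBI::dbExecute(con, "DELETE FROM keys WHERE key_name = ? AND key_value = ?",
                         params = list(okeys$key_name[i], okeys$key_value[i]))
        }
        DBI::dbExecute(con,
          "UPDATE docs SET schema_version = ?, properties = ? WHERE uuid = ?",
          params = list(op$schema_version, to_json_chr(op$properties), op$uuid))
      } else {
        DBI::dbExecute(con,
          "INSERT INTO docs (uuid, item_type, schema_version, properties) VALUES (?, ?, ?, ?)",
          params = list(op$uuid, op$item_type, op$schema_version,
                        to_json_chr(op$properties)))
      }
      nkeys <- private$keys_of(op$item_type, op$properties)
      for (i in seq_len(nrow(nkeys))) {
        DBI::dbExecute(con, "INSERT INTO keys (key_name, key_value, uuid) VALUES (?, ?, ?)",
                       params = list(nkeys$key_name[i], nkeys$key_value[i], op$uuid))
      }
    },

    mirror_op = function(op) {
      old <- private$cache[[op$uuid]]
      if (!is.null(old)) {
        okeys <- private$keys_of(old$item_type, old$properties)
        for (i in seq_len(nrow(okeys))) {
          rm(list = paste0(okeys$key_name[i], "\r", okeys$key_value[i]),
             envir = private$key_env)
        }
      }
      doc <- list(uuid = op$uuid, item_type = op$item_type,
                  schema_version = op$schema_version,
                  properties = normalize_props(op$properties))
      private$cache_put(doc)
      nkeys <- private$keys_of(op$item_type, doc$properties)
      for (i in seq_len(nrow(nkeys))) {
        assign(paste0(nkeys$key_name[i], "\r", nkeys$key_value[i]), op$uuid,
               envir = private$key_env)
      }
    },

    # Replay path used by `replay()`: bypasses validation/permissions (the
    # log records post-validation states) but re-derives keys and backlinks.
    apply_op = function(op) {
      op$properties <- normalize_props(op$properties)
      op$schema_version <- as.integer(op$schema_version)
      private$commit(updated = op$uuid, renamed = character(0), ops = list(op))
    }
  )
)
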