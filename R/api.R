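#' Principals and the four-tier access model
#'
#' Four tiers govern access: `admin` (data wranglers; edit everything,
#' regardless of release status), `submitter` (may edit unreleased objects
#' belonging to a lab they submit for), `consortium` (may view unreleased
#' data within their project), and `base` (anonymous or logged-out; sees
#' released data only). Submitters also carry a project scope (e.g. ENCODE
#' vs GGR): members of one project may neither view nor edit another
#' project's unreleased data.
#'
#' @param user_id identifier or NULL for anonymous.
#' @param tier one of "admin", "submitter", "consortium", "base".
#' @param lab_groups lab uuids the user may submit for.
#' @param project_scope project tag governing unreleased-data visibility.
#' @export
principal <- function(user_id = NULL, tier = c("base", "admin", "submitter", "consortium"),
                      lab_groups = character(0), project_scope = "ENCODE") {
  tier <- match.arg(tier)
  if (is.null(user_id)) {
    tier <- "base"
    lab_groups <- character(0)
  }
  structure(list(user_id = user_id, tier = tier,
                 lab_groups = as.character(lab_groups),
                 project_scope = project_scope),
            class = "metastore_principal")
}

#' @rdname principal
#' @export
principal_anonymous <- function() principal(NULL)

#' @rdname principal
#' @export
principal_admin <- function() principal("admin", "admin")

#' Authorization decision for one (principal, document, action)
#'
#' A pure function of the principal and the document's release status, lab
#' and project. Returns an AccessDecision, never an error.
#'
#' @param prin a [principal()].
#' @param status document lifecycle status ("released", "in progress",
#'   "deleted", ...).
#' @param lab lab uuid of the document (or NULL).
#' @param project project tag of the document.
#' @param action one of "view", "edit", "create".
#' @return list(action, allowed, reason).
#' @export
authorize <- function(prin, status, lab = NULL, project = "ENCODE",
                      action = c("view", "edit", "create")) {
  action <- match.arg(action)
  status <- status %||% "in progress"
  project <- project %||% "ENCODE"
  decide <- function(allowed, reason) list(action = action, allowed = allowed,
                                           reason = reason)
  if (identical(prin$tier, "admin")) return(decide(TRUE, "admin"))
  if (action == "view") {
    if (identical(status, "released")) return(decide(TRUE, "released_public"))
    if (identical(status, "deleted")) return(decide(FALSE, "deleted_admin_only"))
    if (prin$tier %in% c("submitter", "consortium")) {
      if (identical(prin$project_scope, project)) {
        return(decide(TRUE, "consortium_in_project"))
      }
      return(decide(FALSE, "other_project_unreleased"))
    }
    return(decide(FALSE, "unreleased_requires_login"))
  }
  # edit / create
  if (!identical(prin$tier, "submitter")) {
    return(decide(FALSE, "tier_cannot_edit"))
  }
  if (is.null(lab) || !(lab %in% prin$lab_groups)) {
    return(decide(FALSE, "not_submitter_for_lab"))
  }
  if (status %in% c("released", "deleted")) {
    return(decide(FALSE, "released_locked"))
  }
  if (!identical(prin$project_scope, project)) {
    return(decide(FALSE, "other_project"))
  }
  decide(TRUE, "submitter_own_lab")
}

#' Build a principal from a stored user document
#'
#' Tier is derived from the user's `groups` ("admin" > submitter-by-lab >
#' "consortium" > base); `lab_groups` from `submits_for`.
#' @param app a [metastore_app()].
#' @param identifier user uuid or key.
#' @export
principal_for_user <- function(app, identifier) {
  doc <- app$store$get_item(identifier)
  stopifnot(identical(doc$item_type, "user"))
  groups <- as.character(unlist(doc$properties$groups %||% list()))
  labs <- as.character(unlist(doc$properties$submits_for %||% list()))
  tier <- if ("admin" %in% groups) "admin"
          else if (length(labs)) "submitter"
          else if ("consortium" %in% groups) "consortium"
          else "base"
  principal(doc$uuid, tier, lab_groups = labs,
            project_scope = doc$properties$project %||% "ENCODE")
}

can_view_uuid <- function(app, prin, uuid) {
  doc <- app$store$get_or_null(uuid)
  if (is.null(doc)) return(FALSE)
  authorize(prin, status = doc$properties$status %||% "in progress",
            lab = doc$properties$lab,
            project = app$store$project_of_document(uuid),
            action = "view")$allowed
}

# Replace embedded sub-objects the principal may not view by their canonical
# path (permission trimming of denormalised bodies at serve time).
trim_body <- function(app, prin, body) {
  if (is_json_object(body)) {
    if (!is.null(body$uuid) && !is.null(body[["@id"]])) {
      if (!can_view_uuid(app, prin, body$uuid)) return(body[["@id"]])
    }
    for (nm in names(body)) {
      v <- body[[nm]]
      if (is.list(v)) body[[nm]] <- trim_body(app, prin, v)
    }
    body
  } else if (is_json_array(body)) {
    lapply(body, function(el) if (is.list(el)) trim_body(app, prin, el) else el)
  } else body
}

#' Handle one REST-style request
#'
#' Routes `GET`/`POST`/`PATCH`/`PUT` over the endpoint surface:
#' `/<collection>/`, `/<collection>/<id>/`, `/<id>` (bare accession alias),
#' `/profiles/`, `/profiles/<type>.json` and `/search/`. Successful writes
#' return 200 with the written object at frame=object; schema-invalid bodies
#' return 422 with the violation list; unreleased objects read by an
#' unauthorized principal return 404 (existence is not leaked) while edit
#' attempts on visible objects return 403; malformed JSON returns 400.
#'
#' Content negotiation: `format=json` or a JSON Accept header yields the
#' JSON body; otherwise the same JSON is wrapped in an HTML placeholder
#' envelope (the URLs are identical either way).
#'
#' @param app a [metastore_app()].
#' @param method one of GET, POST, PATCH, PUT.
#' @param path URL path.
#' @param query named list of query parameters (`frame`, `format`, `limit`,
#'   `type`, plus repeated `field=value` search filters).
#' @param body request body: named list or JSON string.
#' @param prin acting [principal()].
#' @param accept Accept header value.
#' @return list(status, body).
#' @export
handle_request <- function(app, method, path, query = list(), body = NULL,
                           prin = principal_anonymous(),
                           accept = "application/json") {
  res <- tryCatch(
    route_request(app, toupper(method), path, query, body, prin),
    validation_failure = function(e) list(
      status = 422L, body = list(status = "error", code = 422L,
                                 description = conditionMessage(e),
                                 errors = as.list(e$violations))),
    duplicate_unique_key = function(e) list(
      status = 422L, body = list(status = "error", code = 422L,
                                 description = conditionMessage(e))),
    dangling_link = function(e) list(
      status = 422L, body = list(status = "error", code = 422L,
                                 description = conditionMessage(e))),
    malformed_body = function(e) list(
      status = 400L, body = list(status = "error", code = 400L,
                                 description = conditionMessage(e))),
    unknown_frame = function(e) list(
      status = 400L, body = list(status = "error", code = 400L,
                                 description = conditionMessage(e))),
    permission_denied = function(e) list(
      status = 403L, body = list(status = "error", code = 403L,
                                 description = conditionMessage(e))),
    metastore_error = function(e) list(
      status = 404L, body = list(status = "error", code = 404L,
                                 description = conditionMessage(e))))
  json_wanted <- identical(query$format, "json") ||
    grepl("application/json", accept, fixed = TRUE)
  if (!json_wanted) {
    res$body <- paste0("<!DOCTYPE html><html><body><pre>",
                       to_json_chr(res$body), "</pre></body></html>")
  }
  res
}

route_request <- function(app, method, path, query, body, prin) {
  segs <- strsplit(sub("^/", "", sub("/$", "", path)), "/")[[1]]
  segs <- segs[nzchar(segs)]
  body <- parse_body(body)

  if (length(segs) >= 1 && segs[[1]] == "profiles") {
    if (method != "GET") abort_ms("malformed_body", "profiles is read-only")
    if (length(segs) == 1) return(list(status = 200L, body = app$registry$profiles()))
    type <- sub("\\.json$", "", segs[[2]])
    return(list(status = 200L, body = app$registry$profiles(type)))
  }
  if (length(segs) == 1 && segs[[1]] == "search") {
    reserved <- c("type", "limit", "frame", "format")
    filters <- query[setdiff(names(query), reserved)]
    sr <- app$indexer$search(filters = filters, type = query$type,
                             principal = prin, limit = query$limit %||% "all")
    return(list(status = 200L, body = list(
      `@id` = "/search/", `@graph` = sr$results, facets = sr$facets,
      total = sr$total)))
  }
  if (length(segs) == 1) {
    type <- app$registry$type_from_collection(segs[[1]])
    if (!is.null(type)) {
      if (method == "GET") {
        return(list(status = 200L,
                    body = collection_listing(app, type, prin, query)))
      }
      if (method == "POST") {
        doc <- app$store$create_item(type, body, principal = prin)
        return(write_response(app, doc$uuid))
      }
      abort_ms("malformed_body", paste0("unsupported collection method ", method))
    }
    # bare accession / unique-key alias
    return(item_request(app, method, segs[[1]], query, body, prin))
  }
  if (length(segs) == 2) {
    type <- app$registry$type_from_collection(segs[[1]])
    if (is.null(type)) abort_not_found(segs[[1]])
    res <- item_request(app, method, segs[[2]], query, body, prin)
    return(res)
  }
  abort_not_found(path)
}

item_request <- function(app, method, token, query, body, prin) {
  hit <- app$store$resolve_identifier(token)   # unresolvable -> 404
  if (!can_view_uuid(app, prin, hit$uuid)) abort_not_found(token)
  if (method == "GET") {
    frame <- query$frame %||% "page"
    rv <- app$renderer$render(hit$uuid, frame)
    out <- if (frame %in% c("embedded", "page")) trim_body(app, prin, rv$body) else rv$body
    return(list(status = 200L, body = out))
  }
  if (method %in% c("PATCH", "PUT")) {
    doc <- app$store$update_item(hit$uuid, body,
                                 mode = if (method == "PATCH") "patch" else "replace",
                                 principal = prin)
    return(write_response(app, doc$uuid))
  }
  abort_ms("malformed_body", paste0("unsupported item method ", method))
}

write_response <- function(app, uuid) {
  rv <- app$renderer$render(uuid, "object")
  list(status = 200L, body = list(status = "success", `@graph` = list(rv$body)))
}

parse_body <- function(body) {
  if (is.null(body)) return(NULL)
  if (is.character(body) && length(body) == 1) {
    out <- tryCatch(from_json(body), error = function(e) {
      abort_ms("malformed_body", paste0("malformed JSON body: ", conditionMessage(e)))
    })
    return(out)
  }
  if (!is.list(body)) abort_ms("malformed_body", "body must be JSON object or string")
  body
}

#' Collection listing
#'
#' Members of a collection visible to the principal, rendered at
#' frame=object. When filter query parameters are present, filtering and
#' facet aggregation are delegated to the index.
#'
#' @inheritParams handle_request
#' @param item_type registered type name.
#' @export
collection_listing <- function(app, item_type, prin = principal_anonymous(),
                               query = list()) {
  app$registry$get(item_type)
  reserved <- c("type", "limit", "frame", "format")
  filters <- query[setdiff(names(query), reserved)]
  if (length(filters)) {
    sr <- app$indexer$search(filters = filters, type = item_type,
                             principal = prin, limit = query$limit %||% "all")
    return(list(`@id` = paste0("/", app$registry$collection(item_type), "/"),
                `@graph` = sr$results, facets = sr$facets, total = sr$total))
  }
  uuids <- app$store$uuids_of_type(item_type)
  members <- list()
  for (u in uuids) {
    doc <- app$store$get_item(u)
    if (identical(doc$properties$status %||% "", "deleted")) next
    if (!can_view_uuid(app, prin, u)) next
    members[[length(members) + 1L]] <- app$renderer$render(u, "object")$body
  }
  limit <- query$limit %||% "all"
  total <- length(members)
  if (!identical(limit, "all")) members <- utils::head(members, as.integer(limit))
  list(`@id` = paste0("/", app$registry$collection(item_type), "/"),
       `@graph` = members, total = total)
}
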