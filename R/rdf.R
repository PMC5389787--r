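RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD <- "http://www.w3.org/2001/XMLSchema#"

#' Convert the object-frame graph to RDF triples
#'
#' Operates on the object frame only: link values become resource IRIs
#' (canonical path under `base_uri`), never duplicated sub-documents. Each
#' document yields one rdf:type triple, one triple per scalar property value
#' (typed literal), and one triple per link value; list-valued properties
#' emit one triple per element; nested value mappings are flattened with
#' dotted predicate names (no blank nodes). Calculated properties are
#' included since they exist in the object frame. Deleted documents are not
#' exported.
#'
#' @param app a [metastore_app()].
#' @param base_uri base IRI under which canonical paths live.
#' @return data.frame(subject, predicate, object, object_kind, datatype)
#'   sorted deterministically; `object_kind` is "iri" or "literal".
#' @export
graph_to_triples <- function(app, base_uri = "https://metastore.example.org") {
  base_uri <- sub("/$", "", base_uri)
  vocab <- paste0(base_uri, "/terms/")
  rows <- list()
  add <- function(s, p, o, kind, dt = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = s, predicate = p, object = o, object_kind = kind,
      datatype = dt, stringsAsFactors = FALSE)
  }
  for (u in app$store$all_uuids()) {
    doc <- app$store$get_item(u)
    if (identical(doc$properties$status %||% "", "deleted")) next
    body <- app$renderer$render(u, "object")$body
    subj <- paste0(base_uri, body[["@id"]])
    add(subj, RDF_TYPE_IRI, paste0(vocab, doc$item_type), "iri")
    link_names <- c(names(app$registry$link_fields(doc$item_type)),
                    names(app$registry$rev_fields(doc$item_type)))
    emit_value <- function(pred, v, is_link) {
      if (is.null(v)) return(invisible(NULL))
      if (is_json_array(v)) {
        for (el in v) emit_value(pred, el, is_link)
      } else if (is_json_object(v)) {
        for (nm in names(v)) emit_value(paste0(pred, ".", nm), v[[nm]], FALSE)
      } else if (is_link) {
        add(subj, paste0(vocab, pred), paste0(base_uri, v), "iri")
      } else if (is.logical(v)) {
        add(subj, paste0(vocab, pred), if (v) "true" else "false", "literal",
            paste0(XSD, "boolean"))
      } else if (is.numeric(v)) {
        if (v == as.integer(v)) {
          add(subj, paste0(vocab, pred), sprintf("%d", as.integer(v)), "literal",
              paste0(XSD, "integer"))
        } else {
          add(subj, paste0(vocab, pred), format(v, digits = 15), "literal",
              paste0(XSD, "double"))
        }
      } else {
        add(subj, paste0(vocab, pred), as.character(v), "literal",
            paste0(XSD, "string"))
      }
    }
    for (nm in setdiff(names(body), c("@id", "@type"))) {
      emit_value(nm, body[[nm]], nm %in% link_names)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(subject = character(0), predicate = character(0),
               object = character(0), object_kind = character(0),
               datatype = character(0), stringsAsFactors = FALSE)
  }
  out <- unique(out)
  out[order(out$subject, out$predicate, out$object, out$object_kind), ,
      drop = FALSE]
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

#' Serialize triples as N-Triples or Turtle
#'
#' Turtle output groups triples by subject with `;` predicate lists, uses
#' `a` for rdf:type, and declares `ns:` (the vocabulary) and `xsd:`
#' prefixes; N-Triples is one fully spelled-out triple per line. Both
#' round-trip: parsing the serialization yields an equal triple set.
#'
#' @param triples data.frame from [graph_to_triples()].
#' @param syntax "ntriples" or "turtle".
#' @return a single character scalar.
#' @export
serialize_rdf <- function(triples, syntax = c("ntriples", "turtle")) {
  if (!is_scalar_chr(syntax[[1]]) || !syntax[[1]] %in% c("ntriples", "turtle")) {
    abort_ms("unknown_syntax", paste0("unknown RDF syntax: ", syntax[[1]]))
  }
  syntax <- syntax[[1]]
  fmt_obj_nt <- function(i) {
    if (triples$object_kind[i] == "iri") paste0("<", triples$object[i], ">")
    else if (identical(triples$datatype[i], paste0(XSD, "string")) ||
             is.na(triples$datatype[i])) {
      paste0("\"", escape_literal(triples$object[i]), "\"")
    } else {
      paste0("\"", escape_literal(triples$object[i]), "\"^^<",
             triples$datatype[i], ">")
    }
  }
  if (syntax == "ntriples") {
    if (nrow(triples) == 0) return("")
    lines <- vapply(seq_len(nrow(triples)), function(i) {
      paste0("<", triples$subject[i], "> <", triples$predicate[i], "> ",
             fmt_obj_nt(i), " .")
    }, character(1))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  # turtle
  ns <- unique(sub("/terms/.*$", "/terms/", triples$predicate[
    grepl("/terms/", triples$predicate, fixed = TRUE)]))
  header <- c(
    if (length(ns) == 1) paste0("@prefix ns: <", ns, "> .") else character(0),
    paste0("@prefix xsd: <", XSD, "> ."))
  pred_tt <- function(p) {
    if (identical(p, RDF_TYPE_IRI)) "a"
    else if (length(ns) == 1 && startsWith(p, ns)) paste0("ns:", substring(p, nchar(ns) + 1))
    else paste0("<", p, ">")
  }
  obj_tt <- function(i) {
    if (triples$object_kind[i] == "iri") paste0("<", triples$object[i], ">")
    else if (identical(triples$datatype[i], paste0(XSD, "string")) ||
             is.na(triples$datatype[i])) {
      paste0("\"", escape_literal(triples$object[i]), "\"")
    } else {
      paste0("\"", escape_literal(triples$object[i]), "\"^^xsd:",
             sub(XSD, "", triples$datatype[i], fixed = TRUE))
    }
  }
  blocks <- character(0)
  for (s in unique(triples$subject)) {
    idx <- which(triples$subject == s)
    parts <- vapply(idx, function(i) paste(pred_tt(triples$predicate[i]),
                                           obj_tt(i)), character(1))
    blocks <- c(blocks, paste0("<", s, "> ", paste(parts, collapse = " ;\n    "),
                               " ."))
  }
  paste0(paste(c(header, "", blocks), collapse = "\n"), "\n")
}

#' Export the full object graph as an RDF file
#' @inheritParams graph_to_triples
#' @inheritParams serialize_rdf
#' @param out output file path.
#' @export
export_rdf <- function(app, out, syntax = "turtle",
                       base_uri = "https://metastore.example.org") {
  txt <- serialize_rdf(graph_to_triples(app, base_uri), syntax)
  writeLines(txt, out, sep = "")
  invisible(out)
}
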