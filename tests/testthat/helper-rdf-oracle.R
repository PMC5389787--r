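# Independent oracles for the RDF exporter, deliberately written against the
# serialized text (line/regex level) and the raw schema files rather than
# against any package internals.

XSD_NS <- "http://www.w3.org/2001/XMLSchema#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

.unescape_nt <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

.canon_triple <- function(s, p, kind, value, dt) {
  if (kind == "literal" && (is.na(dt) || dt == "")) dt <- paste0(XSD_NS, "string")
  if (kind == "iri") dt <- ""
  paste(s, p, kind, value, dt, sep = "\x1f")
}

.parse_object_token <- function(tok) {
  if (startsWith(tok, "<")) {
    return(list(kind = "iri", value = sub("^<(.*)>$", "\\1", tok), dt = ""))
  }
  m <- regmatches(tok, regexec('^"(.*)"(?:\\^\\^<(.*)>)?$', tok))[[1]]
  list(kind = "literal", value = .unescape_nt(m[[2]]),
       dt = if (length(m) >= 3 && nzchar(m[[3]])) m[[3]] else paste0(XSD_NS, "string"))
}

# parse N-Triples text -> sorted canonical triple strings
parse_ntriples_oracle <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- vapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^<([^>]*)> <([^>]*)> (.*) \\.$", ln))[[1]]
    stopifnot(length(m) == 4)
    o <- .parse_object_token(m[[4]])
    .canon_triple(m[[2]], m[[3]], o$kind, o$value, o$dt)
  }, character(1), USE.NAMES = FALSE)
  sort(out)
}

# parse the Turtle subset the exporter emits -> sorted canonical strings
parse_turtle_oracle <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  prefixes <- list()
  body_lines <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^@prefix ([A-Za-z0-9]*): <([^>]*)> \\.\\s*$", ln))[[1]]
    if (length(m) == 3) prefixes[[m[[2]]]] <- m[[3]] else body_lines <- c(body_lines, ln)
  }
  expand <- function(tok) {
    if (identical(tok, "a")) return(RDF_TYPE)
    if (startsWith(tok, "<")) return(sub("^<(.*)>$", "\\1", tok))
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    paste0(prefixes[[parts[[1]]]], paste(parts[-1], collapse = ":"))
  }
  text <- paste(trimws(body_lines), collapse = " ")
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  # statements end with " ." ; split conservatively on " . " boundaries
  stmts <- strsplit(paste0(text, " "), " \\. ")[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  out <- character(0)
  tok_re <- '"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^[^ ;]+)?|<[^>]*>|[^ ;]+|;'
  for (st in stmts) {
    toks <- regmatches(st, gregexpr(tok_re, st, perl = TRUE))[[1]]
    subj <- expand(toks[[1]])
    i <- 2
    while (i < length(toks) + 1) {
      if (identical(toks[[i]], ";")) { i <- i + 1; next }
      pred <- expand(toks[[i]])
      otok <- toks[[i + 1]]
      if (startsWith(otok, "\"")) {
        m <- regmatches(otok, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(.*))?$',
                                      otok, perl = TRUE))[[1]]
        dt <- if (length(m) >= 3 && nzchar(m[[3]])) expand(m[[3]]) else ""
        out <- c(out, .canon_triple(subj, pred, "literal", .unescape_nt(m[[2]]), dt))
      } else {
        out <- c(out, .canon_triple(subj, pred, "iri", expand(otok), ""))
      }
      i <- i + 2
    }
  }
  sort(out)
}

# canonical strings for the package's triple data.frame
triples_to_canon <- function(triples) {
  sort(vapply(seq_len(nrow(triples)), function(i) {
    .canon_triple(triples$subject[i], triples$predicate[i],
                  triples$object_kind[i], triples$object[i], triples$datatype[i])
  }, character(1)))
}

# Independent counting walker: expected triple count per document is
# (scalar leaves + link values + 1), computed from the object-frame JSON
# bodies and the on-disk schema files alone.
schema_link_names <- function() {
  dir <- encode_schema_dir()
  out <- list()
  for (f in list.files(dir, pattern = "\\.json$", full.names = TRUE)) {
    sch <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    type <- sub("\\.json$", "", basename(f))
    links <- character(0)
    for (nm in names(sch$properties)) {
      p <- sch$properties[[nm]]
      if (!is.null(p$linkTo) || !is.null(p$items$linkTo)) links <- c(links, nm)
    }
    out[[type]] <- c(links, names(sch$rev))
  }
  out
}

count_triples_oracle <- function(app) {
  links <- schema_link_names()
  count_value <- function(v) {
    if (is.null(v)) 0L
    else if (is.list(v) && is.null(names(v))) sum(vapply(v, count_value, integer(1)), 0L)
    else if (is.list(v)) sum(vapply(v, count_value, integer(1)), 0L)
    else 1L
  }
  total <- 0L
  for (u in app$store$all_uuids()) {
    doc <- app$store$get_item(u)
    if (identical(doc$properties$status, "deleted")) next
    body <- app$renderer$render(u, "object")$body
    n <- 1L  # type triple
    for (nm in setdiff(names(body), c("@id", "@type"))) {
      n <- n + count_value(body[[nm]])  # links are path strings: scalar leaves
    }
    total <- total + n
  }
  total
}
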