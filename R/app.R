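#' Assemble a metastore application
#'
#' Wires the five engine pieces together: a [SchemaRegistry] over a schema
#' directory, a [DocumentStore], a [Renderer], an [AuditEngine] (installed
#' as the renderer's page-frame hook) and an [Indexer].
#'
#' @param schema_dir directory of per-type JSON schema files.
#' @param db SQLite path or ":memory:".
#' @return an object of class `metastore_app` with fields `registry`,
#'   `store`, `renderer`, `auditor`, `indexer`.
#' @export
metastore_app <- function(schema_dir, db = ":memory:") {
  registry <- SchemaRegistry$new(schema_dir)
  store <- DocumentStore$new(registry, db = db)
  renderer <- Renderer$new(store)
  auditor <- AuditEngine$new(renderer)
  renderer$set_audit_hook(function(uuid, body) auditor$run_audits_on(uuid, body))
  indexer <- Indexer$new(renderer, auditor)
  structure(list(registry = registry, store = store, renderer = renderer,
                 auditor = auditor, indexer = indexer),
            class = "metastore_app")
}

#' Directory of the shipped demonstration schemas
#' @export
encode_schema_dir <- function() {
  system.file("extdata", "schemas", package = "metastore", mustWork = TRUE)
}

#' Default per-assay minimum uniquely mapped read counts
#'
#' Alignment files below their assay's minimum raise the "low read depth"
#' WARNING audit. Thresholds are configuration, standing in for standards a
#' consortium sets per experiment class.
#' @export
default_read_depth_min <- function() {
  c("ChIP-seq" = 2e7, "RNA-seq" = 3e7, "DNase-seq" = 2e7)
}

#' The ENCODE-style demonstration application
#'
#' [metastore_app()] over the ten shipped schemas (award, lab, user, donor,
#' biosample, library, replicate, experiment, file, antibody_lot), plus:
#'
#' * upgrade steps: biosample 1->2 (legacy string `starting_amount` coerced
#'   to a number), experiment 1->2 (legacy `assay_name` renamed to
#'   `assay_term_name`);
#' * calculated properties: `biosample.summary` (from its own fields only),
#'   and the reverse links `experiment.files` / `experiment.replicates`
#'   declared in the schemas;
#' * embed specs: experiment embeds replicates -> library -> biosample and
#'   its files; biosample embeds its donor; library embeds its biosample
#'   (labs, awards, antibody lots and file->dataset stay linked-only);
#' * the three built-in audit rules: "missing donor" (ERROR) on human
#'   biosamples, "inconsistent ontology" (ERROR) on experiments whose
#'   replicates derive from biosamples with different ontology terms, and
#'   "low read depth" (WARNING) on experiments with an alignment file under
#'   the per-assay minimum.
#'
#' @param db SQLite path or ":memory:".
#' @param schema_dir schema directory (defaults to the shipped set).
#' @param read_depth_min named per-assay minimum read counts.
#' @export
encode_app <- function(db = ":memory:", schema_dir = encode_schema_dir(),
                       read_depth_min = default_read_depth_min()) {
  app <- metastore_app(schema_dir, db = db)
  reg <- app$registry

  reg$add_upgrade("biosample", 1L, function(props) {
    if (!is.null(props$starting_amount) && is.character(props$starting_amount)) {
      n <- suppressWarnings(as.numeric(props$starting_amount))
      if (is.na(n)) props$starting_amount <- NULL else props$starting_amount <- n
    }
    props
  })
  reg$add_upgrade("experiment", 1L, function(props) {
    if (!is.null(props$assay_name)) {
      if (is.null(props$assay_term_name)) props$assay_term_name <- props$assay_name
      props$assay_name <- NULL
    }
    props
  })

  reg$add_calculated("biosample", "summary", function(body) {
    parts <- c(body$organism, body$biosample_term_name)
    if (is.null(parts)) NULL else paste(parts, collapse = " ")
  })

  app$renderer$set_embed("experiment",
    c("replicates", "replicates.library", "replicates.library.biosample", "files"))
  app$renderer$set_embed("biosample", "donor")
  app$renderer$set_embed("library", "biosample")

  register_builtin_audits(app, read_depth_min)
  app
}

#' Register the three shipped audit rules on an application
#' @param app a [metastore_app()] using the shipped schemas.
#' @param read_depth_min named per-assay minimum read counts.
#' @export
register_builtin_audits <- function(app, read_depth_min = default_read_depth_min()) {
  app$auditor$register_rule("biosample", "missing donor", "ERROR",
    function(body) {
      if (identical(body$organism, "human") && is.null(body$donor)) {
        "human biosample is missing its donor"
      } else character(0)
    })

  app$auditor$register_rule("experiment", "inconsistent ontology", "ERROR",
    function(body) {
      terms <- character(0)
      for (rep in body$replicates %||% list()) {
        if (!is_json_object(rep)) next
        bs <- rep$library$biosample
        if (is_json_object(bs) && !is.null(bs$biosample_term_name)) {
          terms <- c(terms, bs$biosample_term_name)
        }
      }
      terms <- unique(terms)
      if (length(terms) > 1) {
        sprintf("replicates use different biosample ontology terms: %s",
                paste(sort(terms), collapse = ", "))
      } else character(0)
    })

  app$auditor$register_rule("experiment", "low read depth", "WARNING",
    function(body) {
      minimum <- read_depth_min[[body$assay_term_name %||% ""]] %||% NULL
      if (is.null(minimum)) return(character(0))
      out <- character(0)
      for (f in body$files %||% list()) {
        if (!is_json_object(f)) next
        if (!identical(f$output_type, "alignments")) next
        n <- f$mapped_read_count
        if (!is.null(n) && n < minimum) {
          out <- c(out, sprintf(
            "alignment file %s has %d uniquely mapped reads, below the %s minimum of %d",
            f[["@id"]] %||% f$uuid, as.integer(n), body$assay_term_name,
            as.integer(minimum)))
        }
      }
      out
    })
  invisible(app)
}
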