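#' Configuration for the synthetic metadata-graph generator
#'
#' The generator emits an ENCODE-like, referentially closed linked metadata
#' graph: awards and labs with users, then per experiment a chain of
#' donor -> biosample -> library -> replicate plus data files and (for
#' ChIP-seq) an antibody lot. Defaults describe a small but realistic
#' submission: three labs, a 50/30/20 ChIP-seq/RNA-seq/DNase-seq assay mix,
#' two replicates and two files per experiment in expectation, 70% of
#' objects released, and a 10% planted-violation rate per audit category
#' (curation errors are common enough in live submissions that a clean graph
#' would be the unrealistic choice).
#'
#' @param seed random seed; identical (seed, config) gives a byte-identical
#'   document set.
#' @param n_experiments number of experiments.
#' @param assays named sampling weights over assay names.
#' @param n_labs number of labs (one award and one submitter each).
#' @param replicate_rate expected replicates per experiment (>= 1).
#' @param file_rate expected files per experiment (>= 1).
#' @param released_fraction probability an object is "released".
#' @param violation_rates named per-audit-category probabilities of planting
#'   a violation ("missing donor", "inconsistent ontology",
#'   "low read depth").
#' @param read_depth_min per-assay minimum read counts used when choosing
#'   (non-)violating alignment read counts.
#' @export
fixture_config <- function(seed = 42L,
                           n_experiments = 20L,
                           assays = c("ChIP-seq" = 0.5, "RNA-seq" = 0.3,
                                      "DNase-seq" = 0.2),
                           n_labs = 3L,
                           replicate_rate = 2,
                           file_rate = 2,
                           released_fraction = 0.7,
                           violation_rates = c("missing donor" = 0.1,
                                               "inconsistent ontology" = 0.1,
                                               "low read depth" = 0.1),
                           read_depth_min = default_read_depth_min()) {
  bad <- function(msg) abort_ms("invalid_config", msg)
  if (!is.numeric(n_experiments) || n_experiments < 0) bad("n_experiments must be >= 0")
  if (!is.numeric(n_labs) || n_labs < 1) bad("n_labs must be >= 1")
  if (is.null(names(assays)) || any(assays < 0) || sum(assays) <= 0) {
    bad("assays must be named non-negative weights")
  }
  if (replicate_rate < 1 || file_rate < 1) bad("replicate_rate and file_rate must be >= 1")
  if (released_fraction < 0 || released_fraction > 1) bad("released_fraction in [0, 1]")
  if (any(violation_rates < 0 | violation_rates > 1)) bad("violation_rates in [0, 1]")
  structure(list(seed = as.integer(seed), n_experiments = as.integer(n_experiments),
                 assays = assays, n_labs = as.integer(n_labs),
                 replicate_rate = replicate_rate, file_rate = file_rate,
                 released_fraction = released_fraction,
                 violation_rates = violation_rates,
                 read_depth_min = read_depth_min),
            class = "fixture_config")
}

BIOSAMPLE_TERMS <- list(
  list(name = "epidermal keratinocyte", id = "CL:0000312"),
  list(name = "hepatocyte", id = "CL:0000182"),
  list(name = "K562", id = "EFO:0002067"),
  list(name = "GM12878", id = "EFO:0002784"),
  list(name = "CD4-positive T cell", id = "CL:0000624"))

ASSAY_TERM_IDS <- c("ChIP-seq" = "OBI:0000716", "RNA-seq" = "OBI:0001271",
                    "DNase-seq" = "OBI:0001853")

CHIP_TARGETS <- c("CTCF", "POLR2A", "H3K27ac", "MYC")

#' Generate a seeded synthetic metadata graph
#'
#' Emits documents in dependency order together with a ground-truth manifest
#' of every planted audit violation (`category`, `path`). Outside the
#' planted violations the graph is audit-clean and every document validates
#' against the current schemas.
#'
#' @param config a [fixture_config()].
#' @return list(documents, manifest, config); each document is
#'   list(item_type, uuid, properties) with links given as uuids.
#' @export
generate_fixture <- function(config = fixture_config()) {
  if (!inherits(config, "fixture_config")) abort_ms("invalid_config", "not a fixture_config")
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  docs <- list()
  manifest_cat <- character(0); manifest_path <- character(0)
  counters <- new.env(parent = emptyenv())
  acc <- function(type, code) {
    n <- counters[[type]] %||% 0L
    counters[[type]] <- n + 1L
    mint_accession(code, n)
  }
  emit <- function(item_type, properties) {
    u <- mint_uuid()
    docs[[length(docs) + 1L]] <<- list(item_type = item_type, uuid = u,
                                       properties = properties)
    u
  }
  plant <- function(category) {
    rate <- if (category %in% names(config$violation_rates)) {
      config$violation_rates[[category]]
    } else 0
    rate > 0 && stats::runif(1) < rate
  }
  note <- function(category, path) {
    manifest_cat <<- c(manifest_cat, category)
    manifest_path <<- c(manifest_path, path)
  }
  status_of <- function() {
    if (stats::runif(1) < config$released_fraction) "released" else "in progress"
  }

  # shared scaffolding: one award, lab and submitter per lab slot
  lab_uuids <- character(0); award_uuids <- character(0); lab_names <- character(0)
  for (i in seq_len(config$n_labs)) {
    project <- if (config$n_labs > 1 && i == config$n_labs) "GGR" else "ENCODE"
    aw <- emit("award", list(name = sprintf("TST-award-%02d", i), project = project,
                             title = sprintf("Synthetic award %d", i),
                             status = "released"))
    nm <- sprintf("tst-lab-%02d", i)
    lb <- emit("lab", list(name = nm, title = sprintf("Synthetic Lab %d", i),
                           status = "released"))
    emit("user", list(email = sprintf("submitter%d@lab%d.test", i, i),
                      first_name = "Sub", last_name = sprintf("Mitter%d", i),
                      lab = lb, submits_for = list(lb), project = project,
                      status = "released"))
    lab_uuids <- c(lab_uuids, lb); award_uuids <- c(award_uuids, aw)
    lab_names <- c(lab_names, nm)
  }
  antibody_pool <- new.env(parent = emptyenv())  # target -> uuid

  for (e in seq_len(config$n_experiments)) {
    li <- sample.int(config$n_labs, 1)
    lab <- lab_uuids[[li]]; award <- award_uuids[[li]]
    assay <- sample(names(config$assays), 1, prob = config$assays)
    organism <- if (stats::runif(1) < 0.7) "human" else "mouse"
    term <- BIOSAMPLE_TERMS[[sample.int(length(BIOSAMPLE_TERMS), 1)]]
    exp_acc <- acc("experiment", "SR")
    exp_path <- paste0("/experiments/", exp_acc, "/")
    n_rep <- 1L + stats::rpois(1, config$replicate_rate - 1)

    mismatch <- n_rep >= 2 && plant("inconsistent ontology")
    if (mismatch) note("inconsistent ontology", exp_path)

    antibody <- NULL; target <- NULL
    if (identical(assay, "ChIP-seq")) {
      target <- sample(CHIP_TARGETS, 1)
      antibody <- antibody_pool[[target]]
      if (is.null(antibody)) {
        antibody <- emit("antibody_lot", list(
          accession = acc("antibody_lot", "AB"), target = target,
          host_organism = sample(c("rabbit", "mouse", "goat"), 1),
          lab = lab, award = award, status = status_of()))
        assign(target, antibody, envir = antibody_pool)
      }
    }

    rep_uuids <- character(0)
    for (r in seq_len(n_rep)) {
      bs_term <- term
      if (mismatch && r == 2L) {
        others <- BIOSAMPLE_TERMS[vapply(BIOSAMPLE_TERMS, function(t)
          !identical(t$name, term$name), logical(1))]
        bs_term <- others[[sample.int(length(others), 1)]]
      }
      donor <- NULL
      bs_acc <- acc("biosample", "BS")
      missing_donor <- identical(organism, "human") && plant("missing donor")
      if (missing_donor) {
        note("missing donor", paste0("/biosamples/", bs_acc, "/"))
      } else {
        donor <- emit("donor", list(
          accession = acc("donor", "DO"), organism = organism,
          sex = sample(c("male", "female", "unknown"), 1),
          age = as.character(sample(20:80, 1)),
          lab = lab, award = award, status = status_of()))
      }
      bs_props <- list(accession = bs_acc, biosample_term_name = bs_term$name,
                       biosample_term_id = bs_term$id, organism = organism,
                       starting_amount = round(stats::runif(1, 1, 100), 1),
                       lab = lab, award = award, status = status_of())
      if (!is.null(donor)) bs_props$donor <- donor
      if (stats::runif(1) < 0.3) {
        bs_props$aliases <- list(paste0(lab_names[[li]], ":", tolower(bs_acc)))
      }
      bs <- emit("biosample", bs_props)
      lib <- emit("library", list(
        accession = acc("library", "LB"), biosample = bs,
        nucleic_acid_term_name = if (identical(assay, "RNA-seq")) "RNA" else "DNA",
        lab = lab, award = award, status = status_of()))
      rep_uuids <- c(rep_uuids, list(c(lib = lib, n = r)))
    }

    exp_props <- list(accession = exp_acc, assay_term_name = assay,
                      assay_term_id = ASSAY_TERM_IDS[[assay]],
                      description = sprintf("Synthetic %s experiment %d", assay, e),
                      lab = lab, award = award, status = status_of())
    if (!is.null(target)) {
      exp_props$target <- target
      exp_props$antibody <- antibody
    }
    if (stats::runif(1) < 0.3) {
      exp_props$aliases <- list(paste0(lab_names[[li]], ":", tolower(exp_acc)))
    }
    exp <- emit("experiment", exp_props)

    for (r in seq_along(rep_uuids)) {
      emit("replicate", list(experiment = exp, library = rep_uuids[[r]][["lib"]],
                             biological_replicate_number = r,
                             technical_replicate_number = 1L,
                             status = status_of()))
    }

    minimum <- config$read_depth_min[[assay]] %||% 2e7
    low_depth <- plant("low read depth")
    if (low_depth) note("low read depth", exp_path)
    n_files <- 1L + stats::rpois(1, config$file_rate - 1)
    for (f in seq_len(n_files)) {
      fp <- list(accession = acc("file", "FF"), dataset = exp,
                 lab = lab, award = award, status = status_of())
      if (f == 1L) {
        fp$file_format <- "bam"; fp$output_type <- "alignments"
        fp$mapped_read_count <- if (low_depth) {
          as.integer(round(minimum * stats::runif(1, 0.1, 0.8)))
        } else {
          as.integer(round(minimum * stats::runif(1, 1.2, 3)))
        }
      } else if (f %% 2 == 0L) {
        fp$file_format <- "fastq"; fp$output_type <- "reads"
      } else {
        fp$file_format <- "bigWig"; fp$output_type <- "signal"
      }
      emit("file", fp)
    }
  }

  list(documents = docs,
       manifest = data.frame(category = manifest_cat, path = manifest_path,
                             stringsAsFactors = FALSE),
       config = config)
}

#' Load a generated fixture into an application's store
#'
#' Documents are created in dependency order through the normal write path
#' (validation, link resolution, key registration, transaction logging).
#'
#' @param fixture a [fixture_config()] or the result of [generate_fixture()].
#' @param app a [metastore_app()] (with the shipped schemas).
#' @return list(counts = per-type document counts, manifest).
#' @export
load_fixture <- function(fixture, app) {
  if (inherits(fixture, "fixture_config")) fixture <- generate_fixture(fixture)
  for (d in fixture$documents) {
    app$store$create_item(d$item_type, d$properties, uuid = d$uuid)
  }
  types <- vapply(fixture$documents, `[[`, "", "item_type")
  counts <- table(types)
  list(counts = as.list(as.integer(counts)) |> stats::setNames(names(counts)),
       manifest = fixture$manifest)
}
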