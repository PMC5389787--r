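`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical JSON serialization used throughout the store
#'
#' Scalars are length-1 atomic vectors, arrays are unnamed lists, objects are
#' named lists. `to_json_chr()` and `normalize_props()` keep every document in
#' that canonical shape so equality of documents is equality of their JSON.
#' @noRd
to_json_chr <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA))
}

from_json <- function(txt) jsonlite::fromJSON(txt, simplifyVector = FALSE)

empty_object <- function() structure(list(), names = character(0))

#' Normalise a property mapping into canonical form (round-trip through JSON).
#' Atomic vectors of length > 1 become arrays; length-1 vectors stay scalars.
#' @noRd
normalize_props <- function(x) {
  if (is.null(x) || length(x) == 0) return(empty_object())
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    abort_ms("malformed_body", "properties must be a named mapping")
  }
  from_json(to_json_chr(x))
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_json_object <- function(x) is.list(x) && !is.null(names(x)) && (length(x) == 0L || all(names(x) != ""))
is_json_array <- function(x) is.list(x) && (length(x) == 0L || is.null(names(x)))

UUID_RE <- "^[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}$"

#' Mint a random (RNG-driven, hence seed-reproducible) v4-shaped uuid.
#' @noRd
mint_uuid <- function() {
  h <- function(n) paste(sprintf("%x", sample(0L:15L, n, replace = TRUE)), collapse = "")
  paste0(h(8), "-", h(4), "-4", h(3), "-",
         sprintf("%x", sample(8L:11L, 1L)), h(3), "-", h(12))
}

#' Base-26 letter suffix for sequential accession minting: 0 -> "AAA".
#' @noRd
letters3 <- function(n) {
  stopifnot(n >= 0, n < 26^3)
  idx <- c(n %/% 676L, (n %/% 26L) %% 26L, n %% 26L) + 1L
  paste(LETTERS[idx], collapse = "")
}

mint_accession <- function(code, counter) {
  paste0("TST", code, sprintf("%03d", counter %% 1000L), letters3(counter %/% 1000L))
}

# -- small mutable string-set helpers (environments as hash sets) -----------

set_new <- function() new.env(parent = emptyenv())
set_add <- function(s, xs) { for (x in xs) assign(x, TRUE, envir = s); invisible(s) }
set_del <- function(s, xs) { for (x in xs) if (exists(x, envir = s, inherits = FALSE)) rm(list = x, envir = s); invisible(s) }
set_has <- function(s, x) exists(x, envir = s, inherits = FALSE)
set_members <- function(s) sort(ls(s, all.names = TRUE))

# multimap: key -> character set of values (used for reverse dependency maps)
mm_add <- function(m, key, value) {
  cur <- m[[key]]
  if (is.null(cur)) { cur <- set_new(); assign(key, cur, envir = m) }
  set_add(cur, value)
}
mm_del <- function(m, key, value) {
  cur <- m[[key]]
  if (!is.null(cur)) set_del(cur, value)
}
mm_get <- function(m, key) {
  cur <- m[[key]]
  if (is.null(cur)) character(0) else set_members(cur)
}

#' Fetch a dotted path out of a nested body; returns NULL when absent.
#' @noRd
get_path <- function(body, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- body
  for (p in parts) {
    if (!is_json_object(cur)) return(NULL)
    cur <- cur[[p]]
    if (is.null(cur)) return(NULL)
  }
  cur
}
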