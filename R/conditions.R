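# Structured error conditions. Every domain failure carries a condition class
# so the request handler can map it onto an HTTP status code without string
# matching.

abort_ms <- function(class, message, ...) {
  stop(structure(
    class = c(class, "metastore_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @noRd
abort_validation <- function(violations) {
  abort_ms("validation_failure",
           paste0("schema validation failed: ",
                  paste(violations, collapse = "; ")),
           violations = violations)
}

abort_not_found <- function(what) abort_ms("not_found", paste0("not found: ", what))
abort_unknown_type <- function(type) abort_ms("unknown_type", paste0("unknown item type: ", type))
abort_unresolvable <- function(token) abort_ms("unresolvable_token", paste0("unresolvable identifier: ", token))
abort_duplicate_key <- function(key_name, key_value) {
  abort_ms("duplicate_unique_key",
           sprintf("unique key already registered: (%s, %s)", key_name, key_value),
           key_name = key_name, key_value = key_value)
}
abort_dangling_link <- function(field, token) {
  abort_ms("dangling_link",
           sprintf("link field '%s' does not resolve: %s", field, token),
           field = field, token = token)
}
abort_permission <- function(reason) abort_ms("permission_denied", paste0("permission denied: ", reason))
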