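# Chapter-parameter validation against per-template JSON schemas
# (draft-07 semantics for "required", "type", "enum", "properties", "items",
# which is the scope a config-driven report needs: presence and type of
# every input parameter, with readable failure messages).

json_type <- function(x) {
  if (is.null(x)) "null"
  else if (is.list(x)) {
    if (length(x) == 0L) "array"
    else if (!is.null(names(x)) && all(names(x) != "")) "object" else "array"
  }
  else if (is.character(x)) "string"
  else if (is.logical(x)) "boolean"
  else if (is.numeric(x)) {
    if (all(x == floor(x))) "integer" else "number"
  }
  else "unknown"
}

type_matches <- function(value, type) {
  got <- json_type(value)
  any(vapply(type, function(t) {
    if (t == "number") got %in% c("number", "integer")
    else if (t == "array") got %in% c("array") ||
      (got %in% c("string", "number", "integer", "boolean") && length(value) > 1)
    else got == t
  }, logical(1)))
}

validate_node <- function(value, schema, path) {
  out <- list()
  add <- function(parameter, check, passed, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      parameter = parameter, check = check, passed = passed, message = message)
  }
  if (!is.null(schema$type) && !is.null(value)) {
    types <- unlist(schema$type)
    # scalars from YAML arrive length-1; a scalar where an array is allowed
    # wraps implicitly only if the items type matches
    ok <- type_matches(value, types)
    if (!ok && "array" %in% types && length(value) == 1L &&
        !is.null(schema$items$type))
      ok <- type_matches(value, unlist(schema$items$type))
    add(path, "type", ok,
        if (ok) "" else sprintf("parameter '%s': expected type %s, got %s (%s)",
                                path, paste(types, collapse = "|"),
                                json_type(value),
                                paste(utils::head(format(unlist(value)), 3),
                                      collapse = ", ")))
  }
  if (!is.null(schema$enum) && !is.null(value) && length(value) == 1L &&
      !is.list(value)) {
    ok <- as.character(value) %in% as.character(unlist(schema$enum))
    add(path, "enum", ok,
        if (ok) "" else sprintf("parameter '%s': value '%s' not in allowed set {%s}",
                                path, value,
                                paste(unlist(schema$enum), collapse = ", ")))
  }
  if (identical(json_type(value), "object") || (is.list(value) && !is.null(names(value)))) {
    req <- unlist(schema$required)
    for (r in req) {
      ok <- r %in% names(value) && !is.null(value[[r]])
      add(paste0(path, if (nzchar(path)) "." else "", r), "required", ok,
          if (ok) "" else sprintf("parameter '%s%s%s' is required but absent",
                                  path, if (nzchar(path)) "." else "", r))
    }
    props <- schema$properties
    for (p in names(props)) {
      if (p %in% names(value))
        out <- c(out, list(validate_node(
          value[[p]], props[[p]],
          paste0(path, if (nzchar(path)) "." else "", p))))
    }
  }
  if (!is.null(schema$items) && is.list(value) && is.null(names(value))) {
    for (i in seq_along(value))
      out <- c(out, list(validate_node(value[[i]], schema$items,
                                       sprintf("%s[%d]", path, i))))
  }
  dplyr::bind_rows(out)
}

#' Validate chapter parameters against a template's JSON schema
#'
#' Checks the presence and type of every required parameter declared in the
#' template's schema (draft-07 `required`/`type`/`enum` semantics).
#' Returns a report rather than raising: the pipeline aborts the chapter on
#' failure but keeps rendering its siblings.
#'
#' @param params Named list of chapter parameters (from the YAML config).
#' @param schema A JSON schema as an R list (see [read_template_schema()]),
#'   or a path to a schema file.
#' @return Tibble with columns `parameter`, `check`, `passed`, `message`,
#'   plus attribute `valid` (`TRUE` iff every check passed).
#' @export
validate_chapter_params <- function(params, schema) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- jsonlite::read_json(schema)
  report <- validate_node(params, schema, "")
  if (nrow(report) == 0L)
    report <- tibble::tibble(parameter = character(), check = character(),
                             passed = logical(), message = character())
  attr(report, "valid") <- all(report$passed)
  report
}

#' Read the packaged JSON schema for a report template
#'
#' @param template Template name, e.g. `"demographics"`.
#' @return The schema as an R list.
#' @export
read_template_schema <- function(template) {
  path <- system.file("schemas", paste0(template, ".json"),
                      package = "safetyreview")
  abort_if(path == "", sprintf("no schema registered for template '%s'", template))
  jsonlite::read_json(path)
}

#' List registered report templates
#' @return Character vector of template names with packaged schemas.
#' @export
list_templates <- function() {
  sort(sub("\\.json$", "",
           list.files(system.file("schemas", package = "safetyreview"),
                      pattern = "\\.json$")))
}
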