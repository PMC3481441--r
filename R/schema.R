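# Field schemas: which fields are indexed (searchable), which are stored
# (returned with results), and how values are typed.

#' Declare a field
#'
#' @param name field name.
#' @param kind `"text"` (tokenized full-text), `"keyword"` (matched as a
#'   whole, lowercased value) or `"numeric"` (totally ordered, range-queryable).
#' @param indexed can the field be used as a query filter?
#' @param stored is the field returned with search results?
#' @return a one-row field declaration (list).
#' @export
field_schema <- function(name, kind = c("text", "keyword", "numeric"),
                         indexed = TRUE, stored = TRUE) {
  kind <- match.arg(kind)
  if (!is_string(name) || !nzchar(name)) seqindex_error("bad_schema", "field name required")
  if (!indexed && !stored) {
    seqindex_error("bad_schema",
                   sprintf("field '%s' is neither indexed nor stored", name))
  }
  list(name = name, kind = kind, indexed = isTRUE(indexed), stored = isTRUE(stored))
}

#' Build a schema from field declarations
#'
#' The schema is open by default: a field that is not declared behaves as
#' `{text, indexed, stored}`, because bank formats carry unpredictable
#' qualifiers and every field is searchable unless said otherwise.
#'
#' @param ... [field_schema()] declarations (or a single list of them).
#' @return a `field_schema_set`.
#' @export
schema <- function(...) {
  decls <- list(...)
  if (length(decls) == 1L && is.list(decls[[1]]) && is.null(decls[[1]]$name)) {
    decls <- decls[[1]]
  }
  nms <- vapply(decls, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    seqindex_error("bad_schema",
                   sprintf("duplicate field declaration: %s",
                           paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  names(decls) <- nms
  structure(list(fields = decls), class = "field_schema_set")
}

#' Load a schema from a YAML or JSON config file
#'
#' The file holds a list of `{name, kind, indexed, stored}` entries;
#' `kind` defaults to `text`, `indexed` and `stored` to `true`. Extension
#' `.json` selects JSON, anything else is read as YAML (of which JSON is a
#' subset).
#'
#' @param path config file.
#' @return a `field_schema_set`.
#' @export
load_schema <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  decls <- lapply(raw, function(f) {
    field_schema(f$name, f$kind %||% "text",
                 indexed = f$indexed %||% TRUE, stored = f$stored %||% TRUE)
  })
  schema(decls)
}

# Effective declaration of a field: declared entry, or the open-schema
# default {text, indexed, stored}.
schema_field <- function(sch, name) {
  sch$fields[[name]] %||% list(name = name, kind = "text", indexed = TRUE, stored = TRUE)
}

schema_kind <- function(sch, name) schema_field(sch, name)$kind

# names of all declared + extra fields of a given kind that are indexed
schema_is_indexed <- function(sch, name) schema_field(sch, name)$indexed
schema_is_stored <- function(sch, name) schema_field(sch, name)$stored

#' The default bank schema
#'
#' Types the coordinate and length fields produced by the built-in readers
#' as numeric (so ranged queries compare numbers, not strings) and the
#' identifier-like fields as keywords; everything else falls back to the
#' open-schema text default.
#' @return a `field_schema_set`.
#' @export
default_schema <- function() {
  schema(
    field_schema("start", "numeric"),
    field_schema("end", "numeric"),
    field_schema("length", "numeric"),
    field_schema("score", "numeric"),
    field_schema("seqid", "keyword"),
    field_schema("type", "keyword"),
    field_schema("strand", "keyword"),
    field_schema("id", "keyword"),
    field_schema("accession", "keyword"),
    field_schema("content_type", "keyword")
  )
}

schema_to_list <- function(sch) unname(sch$fields)
schema_from_list <- function(x) schema(lapply(x, function(f) {
  field_schema(f$name, f$kind, f$indexed, f$stored)
}))
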