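# Document / field-schema / content-type data model shared by every module.
#
# A Document is the indexed unit: a named list of multi-valued fields plus a
# content-type tag ("biosequence/<format>") and, for records read from a
# bank file, the provenance needed to reproduce the original bytes.

#' Source location of a record inside a bank file
#'
#' Provenance of an indexed record: the file it came from and the exact byte
#' span of the record, so the original text can always be re-read (and
#' re-parsed) from the untouched bank file. Offsets are 0-based bytes;
#' `length` counts bytes.
#'
#' @param path file-system path of the original bank file.
#' @param offset 0-based byte offset of the record's first byte.
#' @param length record length in bytes (> 0).
#' @return a `source_location` object.
#' @export
source_location <- function(path, offset, length) {
  stopifnot(is_string(path))
  offset <- as.numeric(offset); length <- as.numeric(length)
  if (is.na(offset) || offset < 0) seqindex_error("bad_source", "offset must be >= 0")
  if (is.na(length) || length <= 0) seqindex_error("bad_source", "length must be > 0")
  structure(list(path = path, offset = offset, length = length),
            class = "source_location")
}

# ---- content-type registry ---------------------------------------------

new_content_type_registry <- function() {
  reg <- new.env(parent = emptyenv())
  structure(list(types = reg), class = "content_type_registry")
}

#' Register a content type
#'
#' Every document carries a content-type of the form `biosequence/<format>`
#' recorded at indexing time; it tells downstream consumers (result
#' renderers, the region driver) what the original data format was. The
#' descriptor declares a renderer tag and whether documents of this type can
#' answer region queries.
#'
#' @param registry a content-type registry (default: the package registry).
#' @param name content-type string, must match `biosequence/<token>`.
#' @param descriptor list with elements `renderer` (character tag) and
#'   `region` (logical: usable by the region driver).
#' @return the registry, invisibly.
#' @export
register_content_type <- function(name, descriptor = list(renderer = "none", region = FALSE),
                                  registry = default_registry()) {
  if (!is_string(name) || !grepl("^biosequence/[A-Za-z0-9_.-]+$", name)) {
    seqindex_error("bad_content_type",
                   sprintf("content-type '%s' must match 'biosequence/<token>'", name))
  }
  descriptor <- list(renderer = descriptor$renderer %||% "none",
                     region = isTRUE(descriptor$region))
  existing <- registry$types[[name]]
  if (!is.null(existing)) {
    if (!identical(existing, descriptor)) {
      seqindex_error("content_type_conflict",
                     sprintf("content-type '%s' already registered with a different descriptor", name))
    }
    return(invisible(registry))          # idempotent re-registration
  }
  assign(name, descriptor, envir = registry$types)
  invisible(registry)
}

#' Look up a registered content type
#' @inheritParams register_content_type
#' @return the descriptor list.
#' @export
content_type_info <- function(name, registry = default_registry()) {
  d <- registry$types[[name]]
  if (is.null(d)) {
    seqindex_error("unknown_content_type",
                   sprintf("content-type '%s' is not registered", name))
  }
  d
}

content_type_known <- function(name, registry = default_registry()) {
  !is.null(registry$types[[name]])
}

the <- new.env(parent = emptyenv())

#' The package-wide content-type registry
#'
#' Pre-populated with the built-in formats: `biosequence/fasta`,
#' `biosequence/gff` (shared by GFF3 and exploded GenBank/EMBL features,
#' region-queryable), `biosequence/genbank`, `biosequence/embl`,
#' `biosequence/pdb`.
#' @return the registry object.
#' @export
default_registry <- function() {
  if (is.null(the$registry)) {
    reg <- new_content_type_registry()
    register_content_type("biosequence/fasta", list(renderer = "sequence"), reg)
    register_content_type("biosequence/gff", list(renderer = "browser", region = TRUE), reg)
    register_content_type("biosequence/genbank", list(renderer = "sequence"), reg)
    register_content_type("biosequence/embl", list(renderer = "sequence"), reg)
    register_content_type("biosequence/pdb", list(renderer = "structure"), reg)
    the$registry <- reg
  }
  the$registry
}

# ---- documents ----------------------------------------------------------

#' Build a document
#'
#' Maps a record to key/value pairs. Fields are multi-valued: each element
#' of `fields` is an ordered vector (or list) of character/numeric values.
#' The document id comes from an `id` field when one is present, otherwise
#' from a deterministic content hash of the source path and offset, so
#' re-indexing the same bank always yields the same ids.
#'
#' @param fields named list of field values; must be non-empty.
#' @param content_type registered content-type string.
#' @param source optional [source_location()] (documents created through the
#'   online API have none).
#' @param doc_id explicit id, overriding the rules above.
#' @param registry content-type registry to validate against.
#' @return a `document` object.
#' @export
make_document <- function(fields, content_type, source = NULL, doc_id = NULL,
                          registry = default_registry()) {
  if (length(fields) == 0L) seqindex_error("empty_fields", "a document needs at least one field")
  if (is.null(names(fields)) || any(!nzchar(names(fields)))) {
    seqindex_error("bad_field", "all fields must be named")
  }
  content_type_info(content_type, registry)   # errors if unregistered
  if (!is.null(source) && !inherits(source, "source_location")) {
    seqindex_error("bad_source", "source must be a source_location")
  }
  if (is.null(doc_id)) {
    if (!is.null(fields[["id"]]) && nzchar(as.character(fields[["id"]][[1]]))) {
      doc_id <- as.character(fields[["id"]][[1]])
    } else if (!is.null(source)) {
      doc_id <- hash_hex(paste0(source$path, "\r", source$offset))
    } else {
      seqindex_error("no_doc_id", "no 'id' field and no source to derive a doc_id from")
    }
  }
  structure(list(doc_id = doc_id, content_type = content_type,
                 fields = fields, source = source),
            class = "document")
}

#' @export
print.document <- function(x, ...) {
  cat(sprintf("<document %s> [%s]\n", x$doc_id, x$content_type))
  for (nm in names(x$fields)) {
    v <- x$fields[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(utils::head(as.character(unlist(v)), 6), collapse = " | ")))
  }
  if (!is.null(x$source)) {
    cat(sprintf("  source: %s @%.0f +%.0f\n", x$source$path, x$source$offset, x$source$length))
  }
  invisible(x)
}

#' Field-for-field document equality
#'
#' Two documents are equal when ids, content types, field names and ordered
#' field values agree (numeric values compared numerically, so `100` equals
#' `100L`). Source locations are compared unless `ignore_source`.
#'
#' @param a,b documents.
#' @param ignore_source skip the provenance comparison.
#' @param ignore_id skip the doc_id comparison (hash-derived ids depend on
#'   the path a slice was read from).
#' @return logical.
#' @export
doc_equal <- function(a, b, ignore_source = FALSE, ignore_id = FALSE) {
  if (!ignore_id && !identical(a$doc_id, b$doc_id)) return(FALSE)
  if (!identical(a$content_type, b$content_type)) return(FALSE)
  if (!setequal(names(a$fields), names(b$fields))) return(FALSE)
  for (nm in names(a$fields)) {
    va <- unlist(a$fields[[nm]], use.names = FALSE)
    vb <- unlist(b$fields[[nm]], use.names = FALSE)
    if (length(va) != length(vb)) return(FALSE)
    same <- if (is.numeric(va) || is.numeric(vb)) {
      suppressWarnings(isTRUE(all(as.numeric(va) == as.numeric(vb))))
    } else {
      identical(as.character(va), as.character(vb))
    }
    if (!same) return(FALSE)
  }
  if (!ignore_source) {
    if (is.null(a$source) != is.null(b$source)) return(FALSE)
    if (!is.null(a$source) && !identical(unclass(a$source), unclass(b$source))) return(FALSE)
  }
  TRUE
}

#' Serialize / deserialize a document
#'
#' A stable JSON form used by the index's stored-field files; round-trips
#' field-for-field with value order preserved.
#' @param doc a document.
#' @return `doc_to_list`: a plain list; `doc_from_list`: a document.
#' @export
doc_to_list <- function(doc) {
  list(doc_id = doc$doc_id, content_type = doc$content_type,
       fields = lapply(doc$fields, function(v) {
         v <- unlist(v, use.names = FALSE)
         list(kind = if (is.numeric(v)) "n" else "s", values = as.character(v))
       }),
       source = if (!is.null(doc$source)) unclass(doc$source))
}

#' @rdname doc_to_list
#' @param x a list produced by `doc_to_list` (possibly via JSON).
#' @export
doc_from_list <- function(x) {
  fields <- lapply(x$fields, function(f) {
    if (identical(f$kind, "n")) as.numeric(unlist(f$values)) else as.character(unlist(f$values))
  })
  src <- if (!is.null(x$source)) {
    source_location(x$source$path, x$source$offset, x$source$length)
  }
  structure(list(doc_id = x$doc_id, content_type = x$content_type,
                 fields = fields, source = src),
            class = "document")
}
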